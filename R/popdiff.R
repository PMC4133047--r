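# Population-level differentiation: Weir-Cockerham FST, classical MDS,
# BIONJ trees and locus-bootstrap edge support.

# Per-population per-SNP summaries: sample size (individuals with data),
# allele-2 frequency and observed heterozygote frequency. These are
# sufficient statistics for the Weir-Cockerham variance components, and
# resampling loci from them makes bootstrap replicates cheap.
popSnpSummaries <- function(g) {
  d <- dosage(g)
  pops <- populations(g)
  labels <- unique(pops)
  n <- p <- h <- matrix(NA_real_, nrow = length(labels), ncol = nrow(d),
                        dimnames = list(labels, rownames(d)))
  for (pop in labels) {
    sub <- d[, pops == pop, drop = FALSE]
    ok <- !is.na(sub)
    n[pop, ] <- rowSums(ok)
    p[pop, ] <- rowSums(sub, na.rm = TRUE) / (2 * rowSums(ok))
    h[pop, ] <- rowSums(sub == 1L, na.rm = TRUE) / rowSums(ok)
  }
  maf <- {
    tot <- rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
    pmin(tot, 1 - tot)
  }
  list(n = n, p = p, h = h, maf = maf)
}

# Weir-Cockerham (1984) variance components a, b, c for two populations at a
# vector of SNPs. Negative components are kept raw (not truncated) before
# the ratio-of-sums combination.
wcComponents <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

pairFstFromSummaries <- function(sm, popA, popB, snpIdx) {
  n1 <- sm$n[popA, snpIdx]; n2 <- sm$n[popB, snpIdx]
  ok <- n1 >= 2 & n2 >= 2
  if (!any(ok)) stop("no usable SNPs for population pair")
  w <- wcComponents(n1[ok], n2[ok], sm$p[popA, snpIdx][ok], sm$p[popB, snpIdx][ok],
                    sm$h[popA, snpIdx][ok], sm$h[popB, snpIdx][ok])
  sum(w$a) / sum(w$a + w$b + w$c)
}

#' Multilocus Weir-Cockerham FST between two populations
#'
#' The Weir-Cockerham (1984) theta estimator, combined across loci as the
#' ratio of summed variance components (a over a+b+c). SNPs are filtered to
#' minor allele frequency above \code{minMAF} in the whole sample, and a SNP
#' is used only if both populations have at least two individuals with data.
#' Negative per-locus components are kept raw before summation.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param popA,popB population labels.
#' @param minMAF whole-sample minor-allele-frequency filter.
#' @return The multilocus theta (may be marginally negative).
#' @export
pairwiseFst <- function(g, popA, popB, minMAF = 0.05) {
  sm <- popSnpSummaries(g)
  snpIdx <- which(!is.na(sm$maf) & sm$maf > minMAF)
  if (!length(snpIdx)) stop("no SNP passes the MAF filter")
  pairFstFromSummaries(sm, popA, popB, snpIdx)
}

#' Pairwise FST matrix across populations
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param popNames populations to include (default: all, in order of
#'   appearance).
#' @param minMAF whole-sample minor-allele-frequency filter.
#' @return A \linkS4class{PopDistance} with flavor \code{"FST"}.
#' @export
fstMatrix <- function(g, popNames = NULL, minMAF = 0.05) {
  sm <- popSnpSummaries(g)
  if (is.null(popNames)) popNames <- rownames(sm$n)
  if (length(popNames) < 2L) stop("need at least 2 populations")
  snpIdx <- which(!is.na(sm$maf) & sm$maf > minMAF)
  if (!length(snpIdx)) stop("no SNP passes the MAF filter")
  fstMatrixFromSummaries(sm, popNames, snpIdx)
}

fstMatrixFromSummaries <- function(sm, popNames, snpIdx) {
  k <- length(popNames)
  m <- matrix(0, k, k, dimnames = list(popNames, popNames))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    v <- pairFstFromSummaries(sm, popNames[i], popNames[j], snpIdx)
    m[i, j] <- m[j, i] <- v
  }
  new("PopDistance", distance = m, flavor = "FST")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Metric MDS of a symmetric dissimilarity matrix: eigendecomposition of the
#' double-centred squared-distance matrix, coordinates scaled by the square
#' root of the eigenvalues. A negative eigenvalue among the requested
#' dimensions is an error (deeper negative eigenvalues are reported via
#' message only). Fidelity is the Spearman correlation between configuration
#' Euclidean distances and the input dissimilarities.
#'
#' @param d a \linkS4class{PopDistance} or symmetric matrix.
#' @param dims number of output dimensions.
#' @return An \linkS4class{MDSConfig}.
#' @export
classicalMDS <- function(d, dims = 2) {
  m <- if (is(d, "PopDistance")) distanceMatrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-9))
    stop("input must be a symmetric square matrix")
  fit <- stats::cmdscale(m, k = dims, eig = TRUE)
  if (any(fit$eig[seq_len(dims)] < 0))
    stop("negative eigenvalue among requested dimensions")
  if (any(fit$eig < -1e-9))
    message("negative eigenvalues beyond requested dimensions (non-Euclidean input)")
  pts <- fit$points
  rownames(pts) <- rownames(m)
  # rank correlation is undefined for constant inputs (e.g. equilateral
  # configurations); report NA silently in that degenerate case
  rho <- suppressWarnings(
    stats::cor(stats::as.dist(m)[TRUE], stats::dist(pts)[TRUE],
               method = "spearman"))
  new("MDSConfig", points = pts, eig = fit$eig[seq_len(dims)], rho = rho)
}

#' BIONJ tree from a distance matrix
#'
#' Variance-weighted neighbour joining (Gascuel's BIONJ) on a population
#' dissimilarity matrix. Negative branch lengths are clamped to zero with a
#' message.
#'
#' @param d a \linkS4class{PopDistance} or symmetric matrix with >= 3 labels.
#' @return An \code{ape} \code{phylo} object (unrooted).
#' @export
bionjTree <- function(d) {
  m <- if (is(d, "PopDistance")) distanceMatrix(d) else as.matrix(d)
  if (nrow(m) < 3L) stop("need at least 3 labels")
  tree <- ape::bionj(m)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sprintf("%d negative branch length(s) clamped to 0", sum(neg)))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Locus-bootstrap support for a BIONJ tree
#'
#' Builds the tree from the full FST matrix, then resamples SNPs (those
#' passing the MAF filter) with replacement \code{nBoot} times, recomputing
#' the FST matrix and BIONJ tree for each replicate. Each internal edge of
#' the reference tree is annotated with the number of replicate trees
#' containing the same leaf bipartition.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param popNames populations to include.
#' @param nBoot number of bootstrap replicates.
#' @param seed integer seed.
#' @param minMAF whole-sample minor-allele-frequency filter.
#' @return The reference tree with bipartition support counts in
#'   \code{node.label} and the count vector in attribute
#'   \code{"bootstrapSupport"}.
#' @export
bootstrapSupport <- function(g, popNames = NULL, nBoot = 1000, seed = 1,
                             minMAF = 0.05) {
  if (nBoot < 1) stop("nBoot must be at least 1")
  sm <- popSnpSummaries(g)
  if (is.null(popNames)) popNames <- rownames(sm$n)
  snpIdx <- which(!is.na(sm$maf) & sm$maf > minMAF)
  ref <- bionjTree(fstMatrixFromSummaries(sm, popNames, snpIdx))
  set.seed(seed)
  boots <- vector("list", nBoot)
  for (b in seq_len(nBoot)) {
    idx <- sample(snpIdx, length(snpIdx), replace = TRUE)
    boots[[b]] <- suppressMessages(
      bionjTree(fstMatrixFromSummaries(sm, popNames, idx)))
  }
  support <- ape::prop.clades(ref, boots, rooted = FALSE)
  support[is.na(support)] <- 0L
  ref$node.label <- as.character(support)
  attr(ref, "bootstrapSupport") <- support
  ref
}
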