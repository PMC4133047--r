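# Individual-level structure: allele-sharing dissimilarities, balanced
# geographic resampling MDS, Procrustes alignment and the between-group
# permutation test.

#' Allele-sharing dissimilarity matrix between individuals
#'
#' For each pair, per-SNP allele sharing from dosages is 1, 1/2 or 0 for
#' |x - y| = 0, 1, 2; ASD is one minus the mean sharing over SNPs where both
#' individuals have non-missing genotypes.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @return A \linkS4class{PopDistance} with flavor \code{"ASD"}, labelled by
#'   individual identifiers.
#' @export
asdMatrix <- function(g) {
  d <- dosage(g)
  n <- ncol(d)
  if (n < 2L) stop("need at least 2 individuals")
  ok <- !is.na(d)
  X0 <- (ok & d == 0L) + 0; X1 <- (ok & d == 1L) + 0; X2 <- (ok & d == 2L) + 0
  # sum over SNPs of |x - y| decomposed by dosage-category cross terms
  absdiff <- crossprod(X0, X1) + crossprod(X1, X0) +
    crossprod(X1, X2) + crossprod(X2, X1) +
    2 * (crossprod(X0, X2) + crossprod(X2, X0))
  overlap <- crossprod(ok + 0)
  if (any(overlap[upper.tri(overlap)] == 0))
    stop("pair of individuals with no overlapping genotyped SNPs")
  asd <- absdiff / (2 * overlap)
  diag(asd) <- 0
  dimnames(asd) <- list(colnames(d), colnames(d))
  new("PopDistance", distance = (asd + t(asd)) / 2, flavor = "ASD")
}

#' Group populations by gaps in distance from the origin
#'
#' Populations listed as special groups are set aside first (one group
#' each); the remainder are ordered by increasing waypoint distance from the
#' origin and chained: two successive populations whose distance difference
#' is below \code{d} fall in the same group (transitively, so a group can
#' span more than \code{d} end to end). Populations flagged
#' \code{exclude_from_grouping} are dropped.
#'
#' @param pops population table with \code{population}, \code{distance_km}
#'   and optionally \code{special_group}, \code{exclude_from_grouping}.
#' @param d threshold gap in km (> 0).
#' @param special special_group tags set aside as their own groups.
#' @return list with \code{assignment} (named integer vector population ->
#'   group id; special groups get the lowest ids), \code{P} (ordered
#'   non-special populations), \code{D} (successive distance differences).
#' @export
buildGroups <- function(pops, d, special = c("indigenous_NW", "ASW", "MXL")) {
  if (d <= 0) stop("d must be positive")
  if ("exclude_from_grouping" %in% names(pops))
    pops <- pops[!pops$exclude_from_grouping, , drop = FALSE]
  assignment <- integer(0)
  gid <- 0L
  if ("special_group" %in% names(pops)) {
    for (sp in special) {
      members <- pops$population[pops$special_group == sp]
      if (length(members)) {
        gid <- gid + 1L
        assignment[members] <- gid
      }
    }
    rest <- pops[!pops$special_group %in% special, , drop = FALSE]
  } else rest <- pops
  rest <- rest[order(rest$distance_km), , drop = FALSE]
  P <- rest$population
  D <- diff(rest$distance_km)
  if (length(P)) {
    gid <- gid + 1L
    assignment[P[1]] <- gid
    for (j in seq_along(D)) {
      if (D[j] >= d) gid <- gid + 1L
      assignment[P[j + 1L]] <- gid
    }
  }
  list(assignment = assignment, P = P, D = D, d = d)
}

#' Balanced-resampling MDS of an ASD matrix
#'
#' Repeatedly samples up to \code{nPerGroup} individuals without replacement
#' from each population group, runs classical MDS on the corresponding ASD
#' sub-matrix, and keeps the replicate whose two-dimensional configuration
#' best preserves the input dissimilarities (highest Spearman rho; ties go
#' to the first replicate).
#'
#' @param asd \linkS4class{PopDistance} (flavor ASD) over individuals.
#' @param scheme grouping from \code{\link{buildGroups}}.
#' @param indivPops named character vector individual id -> population.
#' @param nPerGroup sample size per group (groups smaller than this are
#'   taken whole).
#' @param replicates number of sampling replicates.
#' @param seed integer seed.
#' @param dims MDS dimensions.
#' @return list with \code{mds} (best \linkS4class{MDSConfig}), \code{ids}
#'   (sampled individuals of the best replicate), \code{rho}, and \code{log}
#'   (data.frame replicate/rho).
#' @export
resampledMDS <- function(asd, scheme, indivPops, nPerGroup = 82,
                         replicates = 1000, seed = 1, dims = 2) {
  m <- distanceMatrix(asd)
  ids <- rownames(m)
  grp <- scheme$assignment[indivPops[ids]]
  names(grp) <- ids
  keep <- !is.na(grp)
  byGroup <- split(ids[keep], grp[keep])
  if (any(lengths(byGroup) == 0L)) stop("empty population group")
  set.seed(seed)
  best <- NULL; bestRho <- -Inf; bestIds <- NULL
  logTab <- data.frame(replicate = seq_len(replicates), rho = NA_real_)
  for (r in seq_len(replicates)) {
    sel <- unlist(lapply(byGroup, function(g)
      if (length(g) <= nPerGroup) g else sample(g, nPerGroup)), use.names = FALSE)
    cfg <- classicalMDS(m[sel, sel], dims = dims)
    logTab$rho[r] <- mdsRho(cfg)
    if (mdsRho(cfg) > bestRho) {
      bestRho <- mdsRho(cfg); best <- cfg; bestIds <- sel
    }
  }
  list(mds = best, ids = bestIds, rho = bestRho, log = logTab)
}

#' Procrustes alignment of two MDS configurations
#'
#' Least-squares superimposition (translation, isotropic scaling, rotation
#' and reflection) of the moving configuration onto the reference, computed
#' on the label intersection. Both configurations are first centred and
#' scaled to unit sum of squares, so the minimised squared distance D lies
#' in [0,1] and the similarity statistic is t0 = sqrt(1 - D).
#'
#' @param reference,moving \linkS4class{MDSConfig} objects or coordinate
#'   matrices with rownames.
#' @return list with \code{coords} (the transformed moving configuration),
#'   \code{t0}, \code{D} and \code{labels} (the shared labels used).
#' @export
procrustesAlign <- function(reference, moving) {
  X <- if (is(reference, "MDSConfig")) mdsPoints(reference) else as.matrix(reference)
  Y <- if (is(moving, "MDSConfig")) mdsPoints(moving) else as.matrix(moving)
  shared <- intersect(rownames(X), rownames(Y))
  if (length(shared) < 3L) stop("need at least 3 shared labels")
  X <- X[shared, , drop = FALSE]; Y <- Y[shared, , drop = FALSE]
  if (sum(scale(X, scale = FALSE)^2) == 0 || sum(scale(Y, scale = FALSE)^2) == 0)
    stop("degenerate (all-coincident) configuration")
  fit <- vegan::procrustes(X, Y, symmetric = TRUE)
  D <- fit$ss
  t0 <- sqrt(max(0, 1 - D))
  coords <- fit$Yrot
  rownames(coords) <- shared
  list(coords = coords, t0 = t0, D = D, labels = shared)
}

#' Permutation test for separation of two groups on an MDS plot
#'
#' The statistic L0 is the mean two-dimensional Euclidean distance over all
#' between-group pairs. The null distribution is obtained by permuting the
#' group labels over the pooled individuals; the p-value is the fraction of
#' permuted L0 values greater than or equal to the observed one (reported as
#' "< 1/nPerm" when no permutation reaches it).
#'
#' @param config \linkS4class{MDSConfig} or coordinate matrix with rownames.
#' @param groupA,groupB disjoint character vectors of labels.
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list with \code{l0}, \code{sdBetween} (SD of between-group pair
#'   distances), \code{nPerm}, \code{p} and \code{pDisplay}.
#' @export
l0Test <- function(config, groupA, groupB, nPerm = 1000, seed = 1) {
  pts <- if (is(config, "MDSConfig")) mdsPoints(config) else as.matrix(config)
  if (length(groupA) == 0L || length(groupB) == 0L) stop("empty group")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  pool <- c(groupA, groupB)
  stopifnot(all(pool %in% rownames(pts)))
  D <- as.matrix(stats::dist(pts[pool, , drop = FALSE]))
  nA <- length(groupA)
  idxA <- seq_len(nA); idxB <- (nA + 1L):length(pool)
  l0 <- mean(D[idxA, idxB])
  sdBetween <- stats::sd(D[idxA, idxB])
  set.seed(seed)
  perm <- numeric(nPerm)
  for (r in seq_len(nPerm)) {
    s <- sample.int(length(pool), nA)
    perm[r] <- mean(D[s, -s])
  }
  p <- mean(perm >= l0)
  list(l0 = l0, sdBetween = sdBetween, nPerm = nPerm, p = p,
       pDisplay = if (p == 0) sprintf("< %g", 1 / nPerm) else format(p))
}
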