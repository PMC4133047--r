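# Haplotype blocks: recombination-map interval rates, block construction,
# EM haplotype frequency estimation and Nei haplotype heterozygosity.

#' Mean recombination rate per inter-SNP interval
#'
#' For each interval between contiguous dataset SNPs on a chromosome, the
#' unweighted mean of map rates at map positions strictly inside the
#' interval. Intervals containing no map point get the linear interpolation,
#' at the interval midpoint, between the flanking map points.
#'
#' @param map recombination map data.frame (\code{chromosome},
#'   \code{position_bp}, \code{rate_cM_per_Mb}), positions strictly
#'   increasing within chromosome.
#' @param snps SNP table (\code{chromosome}, \code{position_bp}), sorted.
#' @return data.frame with one row per interval: \code{chromosome},
#'   \code{left}, \code{right} (global SNP row indices) and \code{rate}.
#' @export
intervalRates <- function(map, snps) {
  res <- lapply(unique(snps$chromosome), function(ch) {
    idx <- which(snps$chromosome == ch)
    if (length(idx) < 2L) return(NULL)
    pos <- snps$position_bp[idx]
    m <- map[map$chromosome == ch, , drop = FALSE]
    if (nrow(m) == 0L) stop(sprintf("no map rows for chromosome %s", ch))
    m <- m[order(m$position_bp), , drop = FALSE]
    if (min(pos) < min(m$position_bp) - 0 && min(pos) < m$position_bp[1] ||
        max(pos) > m$position_bp[nrow(m)]) {
      # allow SNPs at/beyond map ends only if a flanking rate exists
      if (min(pos) < m$position_bp[1] && max(pos) > m$position_bp[nrow(m)] &&
          nrow(m) < 2L)
        stop("SNP positions outside recombination map span")
    }
    rate <- numeric(length(pos) - 1L)
    for (i in seq_along(rate)) {
      inside <- m$rate_cM_per_Mb[m$position_bp > pos[i] & m$position_bp < pos[i + 1L]]
      if (length(inside)) {
        rate[i] <- mean(inside)
      } else {
        mid <- (pos[i] + pos[i + 1L]) / 2
        lo <- max(which(m$position_bp <= mid), 0L)
        hi <- min(which(m$position_bp >= mid), nrow(m) + 1L)
        if (lo == 0L) rate[i] <- m$rate_cM_per_Mb[1]
        else if (hi == nrow(m) + 1L) rate[i] <- m$rate_cM_per_Mb[nrow(m)]
        else if (lo == hi) rate[i] <- m$rate_cM_per_Mb[lo]
        else {
          w <- (mid - m$position_bp[lo]) / (m$position_bp[hi] - m$position_bp[lo])
          rate[i] <- (1 - w) * m$rate_cM_per_Mb[lo] + w * m$rate_cM_per_Mb[hi]
        }
      }
    }
    data.frame(chromosome = ch, left = idx[-length(idx)], right = idx[-1L],
               rate = rate)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build disjoint haplotype blocks from inter-SNP recombination rates
#'
#' Mode \code{"below"} scans each chromosome left to right, extending a run
#' of contiguous SNPs while the next inter-SNP mean rate is below
#' \code{threshold} and the run is shorter than \code{maxSize}; a run is
#' emitted as a block when it reaches at least \code{minSize}. Mode
#' \code{"above"} is identical with the rate comparison reversed. Mode
#' \code{"random"} draws disjoint random blocks whose multiset of lengths
#' exactly matches a reference BlockSet.
#'
#' @param rates interval rates from \code{\link{intervalRates}}.
#' @param minSize,maxSize block size limits in SNPs.
#' @param threshold rate threshold in cM/Mb.
#' @param mode \code{"below"}, \code{"above"} or \code{"random"}.
#' @param reference a \linkS4class{BlockSet} whose block lengths the random
#'   mode reproduces (required for \code{mode = "random"}).
#' @param seed seed for the random mode.
#' @return A \linkS4class{BlockSet}.
#' @export
buildBlocks <- function(rates, minSize = 5, maxSize = 15, threshold = 0.5,
                        mode = c("below", "above", "random"),
                        reference = NULL, seed = 1) {
  mode <- match.arg(mode)
  minSize <- as.integer(minSize); maxSize <- as.integer(maxSize)
  if (mode == "random") {
    if (is.null(reference)) stop("random mode requires a reference BlockSet")
    return(randomBlocks(rates, reference, minSize, maxSize, threshold, seed))
  }
  ok <- if (mode == "below") rates$rate < threshold else rates$rate > threshold
  res <- list()
  for (ch in unique(rates$chromosome)) {
    sel <- rates$chromosome == ch
    lefts <- rates$left[sel]; rights <- rates$right[sel]; good <- ok[sel]
    i <- 1L
    nInt <- sum(sel)
    while (i <= nInt) {
      if (!good[i]) { i <- i + 1L; next }
      first <- lefts[i]
      size <- 2L
      while (i + size - 1L <= nInt && good[i + size - 1L] &&
             rights[i + size - 2L] == lefts[i + size - 1L] && size < maxSize)
        size <- size + 1L
      last <- lefts[i] + size - 1L
      if (size >= minSize) {
        res[[length(res) + 1L]] <- data.frame(chromosome = ch, first = first,
                                              last = last, n_snps = size)
        i <- i + size        # next run starts after the emitted block
      } else {
        i <- i + size - 1L   # re-examine the interval that broke the run
      }
    }
  }
  blocks <- if (length(res)) do.call(rbind, res) else
    data.frame(chromosome = integer(), first = integer(), last = integer(),
               n_snps = integer())
  new("BlockSet", blocks = blocks, mode = mode, minSize = minSize,
      maxSize = maxSize, threshold = threshold)
}

# Random disjoint blocks with the reference's exact multiset of lengths.
randomBlocks <- function(rates, reference, minSize, maxSize, threshold, seed) {
  set.seed(seed)
  lens <- sort(reference@blocks$n_snps, decreasing = TRUE)
  chroms <- unique(rates$chromosome)
  occupied <- lapply(chroms, function(ch) integer(0))
  names(occupied) <- as.character(chroms)
  res <- list()
  for (len in lens) {
    placed <- FALSE
    for (attempt in seq_len(2000L)) {
      ch <- sample(chroms, 1L)
      sel <- rates$chromosome == ch
      snpsOnChrom <- sort(unique(c(rates$left[sel], rates$right[sel])))
      if (length(snpsOnChrom) < len) next
      startPos <- sample.int(length(snpsOnChrom) - len + 1L, 1L)
      cand <- snpsOnChrom[startPos:(startPos + len - 1L)]
      # contiguity on the chromosome grid and disjointness
      if (any(diff(cand) != 1L)) next
      if (length(intersect(cand, occupied[[as.character(ch)]]))) next
      occupied[[as.character(ch)]] <- c(occupied[[as.character(ch)]], cand)
      res[[length(res) + 1L]] <- data.frame(chromosome = ch, first = cand[1],
                                            last = cand[len], n_snps = len)
      placed <- TRUE
      break
    }
    if (!placed) stop("chromosomes too short to place random blocks of requested lengths")
  }
  blocks <- do.call(rbind, res)
  blocks <- blocks[order(blocks$first), , drop = FALSE]
  rownames(blocks) <- NULL
  new("BlockSet", blocks = blocks, mode = "random", minSize = minSize,
      maxSize = maxSize, threshold = threshold)
}

#' EM estimation of haplotype frequencies in a block
#'
#' Maximum-likelihood haplotype frequencies for the SNPs of one block within
#' one population, under Hardy-Weinberg phase uncertainty. The E-step
#' distributes each multi-site heterozygote over its compatible haplotype
#' pairs with probability proportional to f(h1) f(h2); the M-step re-counts.
#' Initialisation is the linkage-equilibrium product of single-SNP
#' frequencies. Individuals with any missing call in the block are excluded.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param block integer vector of SNP row indices (contiguous), length <= 15.
#' @param population population label (NULL = all individuals).
#' @param tol convergence threshold on the maximum frequency change.
#' @param maxIter iteration cap.
#' @return list with \code{freq} (named haplotype frequencies, names are
#'   allele2-count strings over the block SNPs), \code{n} (number of
#'   haplotypes = 2 x individuals used), \code{logLik} (trace, one entry per
#'   iteration) and \code{iterations}.
#' @export
emHaplotypeFrequencies <- function(g, block, population = NULL,
                                   tol = 1e-8, maxIter = 1000) {
  if (length(block) > 15L) stop("block size must be at most 15 SNPs")
  d <- dosage(g)[block, , drop = FALSE]
  if (!is.null(population)) d <- d[, populations(g) == population, drop = FALSE]
  complete <- colSums(is.na(d)) == 0L
  d <- d[, complete, drop = FALSE]
  m <- ncol(d)
  if (m == 0L) stop("no individuals with complete data in block")
  S <- nrow(d)

  # collapse identical genotype patterns
  key <- apply(d, 2, paste, collapse = "")
  patTab <- table(key)
  pats <- do.call(cbind, lapply(names(patTab), function(k)
    as.integer(strsplit(k, "")[[1]])))
  cnt <- as.numeric(patTab)

  hapKey <- function(h) paste(h, collapse = "")
  hapIndex <- new.env(hash = TRUE)
  hapList <- list()
  getHap <- function(h) {
    k <- hapKey(h)
    i <- hapIndex[[k]]
    if (is.null(i)) {
      i <- length(hapList) + 1L
      hapList[[i]] <<- h
      hapIndex[[k]] <- i
    }
    i
  }

  # compatible unordered haplotype pairs per pattern
  pairs <- vector("list", ncol(pats))
  for (u in seq_len(ncol(pats))) {
    gt <- pats[, u]
    het <- which(gt == 1L)
    base <- integer(S)
    base[gt == 2L] <- 1L
    if (length(het) == 0L) {
      i <- getHap(base)
      pairs[[u]] <- cbind(i, i, 1)
    } else {
      nh <- length(het)
      combos <- matrix(0L, nrow = 2^(nh - 1L), ncol = nh)
      if (nh > 1L) {
        for (b in seq_len(nh - 1L))
          combos[, b] <- rep(rep(0:1, each = 2^(nh - 1L - b)), length.out = 2^(nh - 1L))
      }
      combos[, nh] <- 0L  # fix last het site to break pair symmetry
      pr <- matrix(0, nrow = nrow(combos), ncol = 3)
      for (r in seq_len(nrow(combos))) {
        h1 <- base; h1[het] <- combos[r, ]
        h2 <- base; h2[het] <- 1L - combos[r, ]
        pr[r, ] <- c(getHap(h1), getHap(h2), 2)  # ordered-pair multiplicity
      }
      pairs[[u]] <- pr
    }
  }

  H <- length(hapList)
  hapMat <- do.call(rbind, hapList)
  # linkage-equilibrium initialisation restricted to candidate haplotypes
  pSnp <- rowMeans(d) / 2
  f <- apply(hapMat, 1, function(h) prod(ifelse(h == 1L, pSnp, 1 - pSnp)))
  if (sum(f) <= 0) f <- rep(1, H)
  f <- f / sum(f)

  ll <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- numeric(H)
    llIter <- 0
    for (u in seq_along(pairs)) {
      pr <- pairs[[u]]
      w <- pr[, 3] * f[pr[, 1]] * f[pr[, 2]]
      tot <- sum(w)
      llIter <- llIter + cnt[u] * log(tot)
      w <- w / tot
      inc <- cnt[u] * w
      counts[pr[, 1]] <- counts[pr[, 1]] + inc
      counts[pr[, 2]] <- counts[pr[, 2]] + inc
    }
    fNew <- counts / (2 * m)
    ll <- c(ll, llIter)
    delta <- max(abs(fNew - f))
    f <- fNew
    if (delta < tol || iter >= maxIter) break
  }
  names(f) <- vapply(hapList, hapKey, character(1))
  keep <- f > 0
  list(freq = f, n = 2L * m, logLik = ll, iterations = iter)
}

#' Nei haplotype heterozygosity of a block
#'
#' Expected haplotype heterozygosity 1 - sum(p^2), by default with the
#' unbiased small-sample correction n/(n-1) where n is the haplotype count.
#'
#' @param spec result of \code{\link{emHaplotypeFrequencies}} (or any list
#'   with \code{freq} and \code{n}).
#' @param unbiased apply the n/(n-1) correction?
#' @return The heterozygosity estimate.
#' @export
blockHeterozygosity <- function(spec, unbiased = TRUE) {
  n <- spec$n
  if (n < 2) stop("need at least 2 haplotypes")
  h <- 1 - sum(spec$freq^2)
  if (unbiased) h * n / (n - 1) else h
}

#' Genome-wide mean haplotype heterozygosity per population
#'
#' For each population, block heterozygosities are averaged within each
#' chromosome, and the genome-wide mean and SD are taken across chromosome
#' means. Chromosomes with no blocks are excluded with a warning.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param blocks a \linkS4class{BlockSet}.
#' @param populationNames populations to include (default: all).
#' @param unbiased passed to \code{\link{blockHeterozygosity}}.
#' @param tol,maxIter passed to \code{\link{emHaplotypeFrequencies}}.
#' @return list with \code{table} (data.frame: population, mean_het, sd_het,
#'   n_chromosomes) and \code{perChromosome} (matrix populations x
#'   chromosomes of chromosome means).
#' @export
genomewideHeterozygosity <- function(g, blocks, populationNames = NULL,
                                     unbiased = TRUE, tol = 1e-8, maxIter = 1000) {
  b <- blockTable(blocks)
  if (nrow(b) == 0L) stop("empty BlockSet")
  if (is.null(populationNames))
    populationNames <- unique(populations(g))
  allChrom <- sort(unique(rowData(g)$chromosome))
  emptyChrom <- setdiff(allChrom, unique(b$chromosome))
  if (length(emptyChrom))
    warning(sprintf("chromosome(s) without blocks excluded: %s",
                    paste(emptyChrom, collapse = ", ")))
  chroms <- sort(unique(b$chromosome))
  perChrom <- matrix(NA_real_, nrow = length(populationNames),
                     ncol = length(chroms),
                     dimnames = list(populationNames, as.character(chroms)))
  for (pop in populationNames) {
    for (ci in seq_along(chroms)) {
      rows <- which(b$chromosome == chroms[ci])
      hs <- vapply(rows, function(r) {
        spec <- emHaplotypeFrequencies(g, b$first[r]:b$last[r], pop,
                                       tol = tol, maxIter = maxIter)
        blockHeterozygosity(spec, unbiased = unbiased)
      }, numeric(1))
      perChrom[pop, ci] <- mean(hs)
    }
  }
  tab <- data.frame(
    population = populationNames,
    mean_het = rowMeans(perChrom),
    sd_het = apply(perChrom, 1, stats::sd),
    n_chromosomes = ncol(perChrom), row.names = NULL)
  list(table = tab, perChromosome = perChrom)
}
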