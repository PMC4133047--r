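# Synthetic-data module: serial-founder source chains, colonist sources,
# pulse-admixed populations, recombination maps and a complete study-style
# fixture with known ground truth.

#' Simulate allele frequencies for a serial-founder chain and colonist sources
#'
#' Root frequencies are Uniform(0.05, 0.95). Each population along the route
#' drifts from its predecessor under the Balding-Nichols model: p' ~
#' Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance F p(1-p).
#' Drift compounds along the chain, so heterozygosity declines with position
#' on the route (the serial-founder pattern). Colonist sources drift directly
#' from the root with their own F.
#'
#' @param nSnps number of SNPs.
#' @param route character vector of route population labels, ordered from the
#'   origin outwards.
#' @param driftF Balding-Nichols F per route step, in (0,1).
#' @param colonists named numeric vector: colonist label -> F from the root.
#' @param seed integer seed.
#' @return matrix (populations x SNPs) of allele-2 frequencies, with the root
#'   frequencies in attribute \code{"root"}.
#' @export
simulateSourceFrequencies <- function(nSnps, route, driftF = 0.02,
                                      colonists = NULL, seed = 1) {
  if (driftF <= 0 || driftF >= 1) stop("driftF must lie in (0,1)")
  if (!is.null(colonists) && any(colonists <= 0 | colonists >= 1))
    stop("colonist F values must lie in (0,1)")
  set.seed(seed)
  root <- stats::runif(nSnps, 0.05, 0.95)
  labels <- c(route, names(colonists))
  out <- matrix(NA_real_, nrow = length(labels), ncol = nSnps,
                dimnames = list(labels, NULL))
  p <- root
  for (pop in route) {
    p <- bnDrift(p, driftF)
    out[pop, ] <- p
  }
  for (pop in names(colonists)) out[pop, ] <- bnDrift(root, colonists[[pop]])
  attr(out, "root") <- root
  out
}

# One Balding-Nichols drift step; F -> 0 returns the parent frequencies.
bnDrift <- function(p, F) {
  if (F < 1e-12) return(p)
  p <- clamp(p, 1e-9, 1 - 1e-9)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate individual ancestry fractions after a single admixture pulse
#'
#' Monte-Carlo pedigree under the pulse model: founders of the hybrid
#' population carry one-hot source labels drawn i.i.d. with probabilities
#' \code{s}; first-generation hybrids average two founder labels, and each
#' subsequent generation draws two parents uniformly at random from the
#' previous hybrid generation and averages their ancestry vectors. Under
#' random mating the per-source variance of the ancestry fraction H halves
#' each generation: Var(H_g) = s(1-s)/2^g.
#'
#' @param n number of individuals returned (the final generation).
#' @param s numeric vector of source contributions summing to 1 (named).
#' @param g generations since the pulse (>= 1).
#' @param seed integer seed.
#' @param pedigreeSize size of intermediate generations; the default keeps a
#'   finite pedigree so small-sample behaviour of downstream estimators is
#'   visible. The final generation has size \code{n}.
#' @return matrix n x K of ancestry fractions, rows summing to 1.
#' @export
simulateAdmixtureFractions <- function(n, s, g, seed = 1, pedigreeSize = 500) {
  if (n < 2) stop("n must be at least 2")
  if (g < 1) stop("g must be at least 1")
  if (any(s < 0) || abs(sum(s) - 1) > 1e-9) stop("s must be nonnegative and sum to 1")
  set.seed(seed)
  K <- length(s)
  N <- max(n, pedigreeSize)
  gen <- function(size) {
    # one-hot labels for two founding parents per individual
    m <- matrix(0, nrow = size, ncol = K)
    f <- matrix(0, nrow = size, ncol = K)
    m[cbind(seq_len(size), sample.int(K, size, replace = TRUE, prob = s))] <- 1
    f[cbind(seq_len(size), sample.int(K, size, replace = TRUE, prob = s))] <- 1
    (m + f) / 2
  }
  H <- gen(N)
  if (g >= 2) for (t in 2:g) {
    size <- if (t == g) n else N
    mom <- sample.int(nrow(H), size, replace = TRUE)
    dad <- sample.int(nrow(H), size, replace = TRUE)
    H <- (H[mom, , drop = FALSE] + H[dad, , drop = FALSE]) / 2
  } else if (n != N) {
    H <- H[seq_len(n), , drop = FALSE]
  }
  if (nrow(H) > n) H <- H[seq_len(n), , drop = FALSE]
  colnames(H) <- names(s)
  H
}

#' Simulate unlinked genotypes given source frequencies and ancestry truth
#'
#' Each individual's per-SNP allele-2 frequency is the ancestry-weighted
#' mixture of source frequencies; dosage is Binomial(2, .), and entries are
#' masked missing i.i.d. at \code{missingRate}.
#'
#' @param freqs matrix sources x SNPs of allele-2 frequencies.
#' @param truth matrix individuals x sources of ancestry fractions (rows sum
#'   to 1); column names must match \code{rownames(freqs)}.
#' @param populations character vector of population labels per individual.
#' @param missingRate i.i.d. missing-data rate in [0,1).
#' @param seed integer seed.
#' @param snps optional SNP metadata (as in \code{\link{GenotypeData}}).
#' @param ids optional individual identifiers.
#' @return A \linkS4class{GenotypeData}.
#' @export
simulateGenotypes <- function(freqs, truth, populations, missingRate = 0,
                              seed = 1, snps = NULL, ids = NULL) {
  if (any(freqs < 0 | freqs > 1)) stop("allele frequencies must lie in [0,1]")
  if (!is.null(colnames(truth)) && !is.null(rownames(freqs)))
    truth <- truth[, rownames(freqs), drop = FALSE]
  set.seed(seed)
  P <- truth %*% freqs                     # individuals x SNPs
  n <- nrow(P); L <- ncol(P)
  d <- matrix(stats::rbinom(n * L, 2L, t(P)), nrow = L, ncol = n)
  if (missingRate > 0)
    d[stats::runif(n * L) < missingRate] <- NA_integer_
  if (is.null(snps)) snps <- syntheticSnpTable(L)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(n))
  GenotypeData(d, snps, data.frame(id = ids, population = populations))
}

syntheticSnpTable <- function(L, chromosomes = 1L, prefix = "snp") {
  perChrom <- ceiling(L / length(chromosomes))
  chrom <- rep(chromosomes, each = perChrom)[seq_len(L)]
  pos <- unlist(lapply(table(chrom)[as.character(unique(chrom))],
                       function(k) seq_len(k) * 10000L), use.names = FALSE)
  data.frame(id = sprintf("%s%05d", prefix, seq_len(L)),
             chromosome = chrom, position_bp = pos,
             allele1 = "A", allele2 = "G")
}

#' Simulate a recombination map with planted low-recombination runs
#'
#' Produces one map row per inter-SNP interval (at the interval midpoint):
#' intervals inside a planted run get \code{lowRate}, all others
#' \code{highRate}. Planted runs are separated by at least one high-rate
#' interval, so a block builder thresholding at a rate between the two
#' recovers exactly the planted runs.
#'
#' @param snps SNP table (\code{id}, \code{chromosome}, \code{position_bp}).
#' @param runs data.frame with columns \code{chromosome}, \code{first},
#'   \code{last}: global SNP indices (rows of \code{snps}) of each planted
#'   run. Alternatively NULL for a uniform map at \code{highRate}.
#' @param lowRate,highRate rates in cM/Mb for intervals inside/outside runs.
#' @return data.frame (\code{chromosome}, \code{position_bp},
#'   \code{rate_cM_per_Mb}) with the planted runs in attribute
#'   \code{"planted"}.
#' @export
simulateRecombinationMap <- function(snps, runs = NULL, lowRate = 0.1,
                                     highRate = 2.0) {
  if (nrow(snps) < 20) stop("need at least 20 SNPs")
  out <- lapply(unique(snps$chromosome), function(ch) {
    idx <- which(snps$chromosome == ch)
    if (length(idx) < 2L) return(NULL)
    pos <- snps$position_bp[idx]
    mid <- (pos[-1] + pos[-length(pos)]) / 2
    rate <- rep(highRate, length(mid))
    if (!is.null(runs)) {
      rr <- runs[runs$chromosome == ch, , drop = FALSE]
      for (k in seq_len(nrow(rr))) {
        lo <- match(rr$first[k], idx); hi <- match(rr$last[k], idx)
        if (is.na(lo) || is.na(hi)) stop("planted run outside chromosome")
        if (hi > lo) rate[lo:(hi - 1L)] <- lowRate
      }
    }
    data.frame(chromosome = ch, position_bp = as.integer(round(mid)),
               rate_cM_per_Mb = rate)
  })
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  attr(map, "planted") <- runs
  map
}

# Plant disjoint runs of the given lengths, distributed round-robin across
# chromosomes and placed left to right with a one-SNP high-rate gap between
# consecutive runs. Indices are global over the concatenated SNP grid.
planRuns <- function(nSnpsPerChrom, runLengths) {
  nSnpsPerChrom <- as.integer(nSnpsPerChrom)
  runLengths <- as.integer(runLengths)
  nChrom <- length(nSnpsPerChrom)
  offset <- c(0L, cumsum(nSnpsPerChrom))[seq_len(nChrom)]
  at <- rep(1L, nChrom)
  res <- list()
  ci <- 1L
  for (len in runLengths) {
    tried <- 0L
    while (at[ci] + len - 1L > nSnpsPerChrom[ci] && tried < nChrom) {
      ci <- ci %% nChrom + 1L
      tried <- tried + 1L
    }
    if (tried == nChrom) stop("chromosomes too short for requested planted runs")
    res[[length(res) + 1L]] <- data.frame(
      chromosome = ci, first = offset[ci] + at[ci],
      last = offset[ci] + at[ci] + len - 1L)
    at[ci] <- at[ci] + len + 1L
    ci <- ci %% nChrom + 1L
  }
  out <- do.call(rbind, res)
  out[order(out$first), , drop = FALSE]
}

# --- block-level haplotype machinery -------------------------------------

# Root pool: m distinct haplotypes over `size` SNPs with Dirichlet(1) root
# frequencies. Population pools share the haplotype universe; frequencies
# drift by a Dirichlet analogue of Balding-Nichols resampling, which lowers
# haplotype diversity along the chain and raises it under admixture mixing.
makeBlockPool <- function(size, poolSize = 12) {
  repeat {
    haps <- matrix(stats::rbinom(poolSize * size, 1L, 0.5), nrow = poolSize)
    if (!anyDuplicated(apply(haps, 1, paste, collapse = ""))) break
  }
  list(haps = haps, rootFreq = as.numeric(rdirichlet(1, rep(1, poolSize))))
}

dirichletDrift <- function(freq, F) {
  if (F < 1e-12) return(freq)
  as.numeric(rdirichlet(1, pmax(freq, 1e-9) * (1 - F) / F))
}

# Draw 2n haplotypes for n individuals: individual i's haplotype comes from
# source k with probability H[i, k], then from that source's pool
# frequencies. Returns a dosage matrix (blockSize x n).
drawBlockGenotypes <- function(pool, poolFreqs, H) {
  n <- nrow(H)
  K <- ncol(H)
  pickHap <- function() {
    src <- apply(H, 1, function(h) sample.int(K, 1L, prob = h))
    vapply(src, function(k)
      sample.int(nrow(pool$haps), 1L, prob = poolFreqs[[k]]), integer(1))
  }
  h1 <- pool$haps[pickHap(), , drop = FALSE]
  h2 <- pool$haps[pickHap(), , drop = FALSE]
  t(h1 + h2)
}

#' Generate a complete synthetic study fixture
#'
#' Builds a dataset with the structure the analysis pipeline assumes: a
#' serial-founder chain of route populations with heterozygosity declining
#' along a geographic route; two differentiated colonist sources; and
#' pulse-admixed populations ("coastal"-like and "interior"-like) with known
#' per-individual ancestry fractions, formed g generations ago from the two
#' colonists plus the last route population as the indigenous source. SNPs
#' inside planted low-recombination runs are drawn from block-level
#' haplotype pools (so EM haplotype estimation sees non-trivial diversity);
#' the remaining SNPs are unlinked. Deterministic given the seed.
#'
#' @param nRoutePops number of route populations (>= 6).
#' @param nSnps number of unlinked SNPs.
#' @param blockLengths integer vector of planted block lengths (5-15 SNPs).
#' @param nChromosomes number of chromosomes to spread SNPs over.
#' @param driftF per-step route drift.
#' @param colonistF named vector of colonist drifts from the root.
#' @param admixed data.frame describing admixed populations: \code{label},
#'   \code{sA}, \code{sB} (colonist fractions; remainder is indigenous),
#'   \code{g} (generations since the pulse), \code{n} individuals,
#'   \code{group} ("coastal" or "interior").
#' @param nPerRoutePop,nPerColonist individuals per route/colonist population.
#' @param poolSize haplotypes per block pool.
#' @param missingRate i.i.d. genotype missingness.
#' @param seed master seed; stage seeds are derived from it.
#' @return list with \code{genotypes} (\linkS4class{GenotypeData}),
#'   \code{populationTable}, \code{map} (recombination map with planted runs),
#'   \code{truth} (individuals x 3 ancestry fractions), \code{blocks}
#'   (planted run table) and \code{sourceFreqs}.
#' @export
makeStudyFixture <- function(nRoutePops = 10, nSnps = 3000,
                             blockLengths = rep(c(5L, 6L, 7L, 8L), times = 6),
                             nChromosomes = 3,
                             driftF = 0.02,
                             colonistF = c(ColonistA = 0.12, ColonistB = 0.12),
                             admixed = data.frame(
                               label = c("Coast1", "Coast2", "Int1", "Int2"),
                               sA = c(0.30, 0.30, 0.15, 0.15),
                               sB = c(0.05, 0.05, 0.10, 0.10),
                               g = c(3L, 3L, 2L, 2L),
                               n = c(24L, 24L, 24L, 24L),
                               group = c("coastal", "coastal", "interior", "interior")),
                             nPerRoutePop = 20, nPerColonist = 24,
                             poolSize = 12, missingRate = 0.002, seed = 1) {
  if (nRoutePops < 6) stop("need at least 6 route populations")
  route <- sprintf("Route%02d", seq_len(nRoutePops))
  indigenous <- route[nRoutePops - 1L]   # penultimate route population

  # Unlinked SNP frequencies along the chain and for colonists.
  freqs <- simulateSourceFrequencies(nSnps, route, driftF, colonistF,
                                     seed = deriveSeed(seed, "freqs"))

  # Individuals and ancestry truth over (ColonistA, ColonistB, Indigenous).
  srcNames <- c(names(colonistF), "Indigenous")
  pops <- c(rep(route, each = nPerRoutePop),
            rep(names(colonistF), each = nPerColonist))
  truth <- matrix(0, nrow = length(pops), ncol = 3,
                  dimnames = list(NULL, srcNames))
  truth[pops %in% route, "Indigenous"] <- 1
  truth[pops == names(colonistF)[1], 1] <- 1
  truth[pops == names(colonistF)[2], 2] <- 1
  for (k in seq_len(nrow(admixed))) {
    s <- c(admixed$sA[k], admixed$sB[k])
    s <- c(s, 1 - sum(s))
    H <- simulateAdmixtureFractions(admixed$n[k], setNames(s, srcNames),
                                    admixed$g[k],
                                    seed = deriveSeed(seed, paste0("pulse_", admixed$label[k])))
    truth <- rbind(truth, H)
    pops <- c(pops, rep(admixed$label[k], admixed$n[k]))
  }

  # Per-population mixing over the three admixture sources for unlinked SNPs:
  # route population members draw from their own drifted frequencies, so the
  # serial-founder decline is present; admixed individuals mix the sources.
  srcFreqRows <- rbind(freqs[names(colonistF)[1], ], freqs[names(colonistF)[2], ],
                       freqs[indigenous, ])
  rownames(srcFreqRows) <- srcNames
  n <- length(pops)
  P <- matrix(NA_real_, nrow = n, ncol = nSnps)
  isRoute <- pops %in% route
  P[isRoute, ] <- freqs[pops[isRoute], , drop = FALSE]
  P[!isRoute, ] <- truth[!isRoute, , drop = FALSE] %*% srcFreqRows

  set.seed(deriveSeed(seed, "genotypes"))
  dosUnlinked <- matrix(stats::rbinom(n * nSnps, 2L, t(P)), nrow = nSnps, ncol = n)

  # Block SNPs from haplotype pools, planted on a recombination map.
  nBlockSnps <- sum(blockLengths)
  totalSnps <- nSnps + nBlockSnps
  perChrom <- rep(ceiling(totalSnps / nChromosomes), nChromosomes)
  perChrom[nChromosomes] <- totalSnps - sum(perChrom[-nChromosomes])
  snps <- data.frame(id = sprintf("snp%05d", seq_len(totalSnps)),
                     chromosome = rep(seq_len(nChromosomes), perChrom),
                     position_bp = unlist(lapply(perChrom, function(k) seq_len(k) * 20000L)),
                     allele1 = "A", allele2 = "G")
  runs <- planRuns(perChrom, blockLengths)
  map <- simulateRecombinationMap(snps, runs)

  set.seed(deriveSeed(seed, "pools"))
  allPops <- c(route, names(colonistF), admixed$label)
  dosBlocks <- matrix(NA_integer_, nrow = nBlockSnps, ncol = n)
  rowAt <- 1L
  for (b in seq_len(nrow(runs))) {
    size <- runs$last[b] - runs$first[b] + 1L
    pool <- makeBlockPool(size, poolSize)
    # drift pool frequencies along the chain and to the colonists
    pf <- list()
    f <- pool$rootFreq
    for (pop in route) { f <- dirichletDrift(f, driftF); pf[[pop]] <- f }
    for (pop in names(colonistF)) pf[[pop]] <- dirichletDrift(pool$rootFreq, colonistF[[pop]])
    srcPF <- list(pf[[names(colonistF)[1]]], pf[[names(colonistF)[2]]], pf[[indigenous]])
    for (pop in allPops) {
      sel <- pops == pop
      H <- if (pop %in% admixed$label) truth[sel, , drop = FALSE]
           else matrix(1, nrow = sum(sel), ncol = 1)
      fr <- if (pop %in% admixed$label) srcPF else list(pf[[pop]])
      dosBlocks[rowAt:(rowAt + size - 1L), sel] <-
        drawBlockGenotypes(pool, fr, H)
    }
    rowAt <- rowAt + size
  }

  # Interleave: block SNPs occupy the planted run rows, unlinked SNPs fill
  # the remaining rows (in order).
  blockRows <- unlist(mapply(seq, runs$first, runs$last, SIMPLIFY = FALSE))
  dos <- matrix(NA_integer_, nrow = totalSnps, ncol = n)
  dos[blockRows, ] <- dosBlocks
  dos[-blockRows, ] <- dosUnlinked
  if (missingRate > 0) {
    set.seed(deriveSeed(seed, "missing"))
    dos[stats::runif(length(dos)) < missingRate] <- NA_integer_
  }

  ids <- sprintf("ind%04d", seq_len(n))
  rownames(truth) <- ids
  g <- GenotypeData(dos, snps, data.frame(id = ids, population = pops))

  popTable <- fixturePopulationTable(route, names(colonistF), admixed)
  list(genotypes = g, populationTable = popTable, map = map, truth = truth,
       blocks = runs, sourceFreqs = srcFreqRows, admixed = admixed)
}

# Coordinates along an eastward path from the origin, so waypoint distance
# increases monotonically along the route; colonists placed off-route;
# admixed populations near the far end of the route.
fixturePopulationTable <- function(route, colonists, admixed) {
  nR <- length(route)
  lon <- seq(38.74, 170, length.out = nR)
  lat <- seq(9.03, 55, length.out = nR)
  tab <- data.frame(
    population = c(route, colonists, admixed$label),
    region = c(rep("route", nR), rep("colonist", length(colonists)),
               rep("northwest", nrow(admixed))),
    latitude = c(lat, 48, 35, rep(54, nrow(admixed))),
    longitude = c(lon, 10, 115, seq(-130, -120, length.out = nrow(admixed))),
    special_group = c(rep("none", nR + length(colonists)),
                      rep("indigenous_NW", nrow(admixed))),
    exclude_from_regression = c(rep(FALSE, nR),
                                rep(TRUE, length(colonists) + nrow(admixed))),
    exclude_from_grouping = FALSE)
  tab
}

#' Write a study fixture to disk
#'
#' Writes the PED/MAP pair, recombination-map TSV, population-table TSV and
#' ancestry-truth TSV for a fixture produced by \code{\link{makeStudyFixture}}.
#'
#' @param fixture result of \code{\link{makeStudyFixture}}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
writeStudyFixture <- function(fixture, dir, prefix = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- writePedMap(fixture$genotypes, file.path(dir, prefix))
  mapPath <- file.path(dir, paste0(prefix, "_recomb_map.tsv"))
  writeTsv(fixture$map, mapPath)
  popPath <- file.path(dir, paste0(prefix, "_populations.tsv"))
  writeTsv(fixture$populationTable, popPath)
  truthPath <- file.path(dir, paste0(prefix, "_truth.tsv"))
  writeTsv(data.frame(id = rownames(fixture$truth), fixture$truth), truthPath)
  invisible(c(paths, recomb_map = mapPath, populations = popPath, truth = truthPath))
}
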