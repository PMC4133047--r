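# PED/MAP input-output, QC filtering, dataset merging and LD pruning.

#' Read a PED/MAP pair into a GenotypeData object
#'
#' Reads whitespace-delimited PLINK text files. Dosage is coded as the count
#' of \code{allele2}, the lexicographically larger allele observed at the
#' SNP, unless overridden via \code{allele2}. A \code{"0 0"} allele pair is a
#' missing genotype. The PED family ID column is taken as the population.
#'
#' @param pedPath,mapPath paths to the .ped and .map files.
#' @param allele2 optional named character vector (names = SNP ids) forcing
#'   the counted allele at given SNPs.
#' @return A \linkS4class{GenotypeData}.
#' @export
readPedMap <- function(pedPath, mapPath, allele2 = NULL) {
  stopifnot(file.exists(pedPath), file.exists(mapPath))
  map <- utils::read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stop("MAP file must have 4 columns (chrom, id, cM, bp)")
  names(map)[1:4] <- c("chromosome", "id", "cm", "position_bp")
  L <- nrow(map)
  if (anyDuplicated(map$id)) stop("duplicate SNP identifiers in MAP file")

  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nTok <- lengths(toks)
  bad <- which(nTok != 6L + 2L * L)
  if (length(bad))
    stop(sprintf("malformed PED line %d: %d fields, expected %d",
                 bad[1], nTok[bad[1]], 6L + 2L * L))
  n <- length(toks)
  tokM <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  fam <- tokM[, 1]; iid <- tokM[, 2]
  a1 <- tokM[, 6L + 2L * seq_len(L) - 1L, drop = FALSE]  # n x L
  a2 <- tokM[, 6L + 2L * seq_len(L), drop = FALSE]
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("half-missing genotype at SNP %s, PED line %d", map$id[w[2]], w[1]))
  }

  dos <- matrix(NA_integer_, nrow = L, ncol = n)
  al1 <- al2 <- character(L)
  valid <- c("A", "C", "G", "T")
  for (j in seq_len(L)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[obs != "0"]
    u <- sort(unique(obs))
    if (!all(u %in% valid))
      stop(sprintf("invalid allele '%s' at SNP %s", setdiff(u, valid)[1], map$id[j]))
    if (length(u) > 2L)
      stop(sprintf("more than 2 alleles at SNP %s: %s", map$id[j], paste(u, collapse = "/")))
    if (length(u) == 0L) u <- c("A", "G")  # fully missing column; arbitrary labels
    ref2 <- if (!is.null(allele2) && map$id[j] %in% names(allele2))
      allele2[[map$id[j]]] else u[length(u)]
    ref1 <- setdiff(u, ref2)
    if (length(ref1) == 0L)  # monomorphic: placeholder other allele
      ref1 <- setdiff(valid, ref2)[1]
    d <- (a1[, j] == ref2) + (a2[, j] == ref2)
    d[a1[, j] == "0"] <- NA_integer_
    dos[j, ] <- as.integer(d)
    al1[j] <- ref1[1]; al2[j] <- ref2
  }

  GenotypeData(
    dosage = dos,
    snps = data.frame(id = map$id, chromosome = map$chromosome,
                      position_bp = map$position_bp, allele1 = al1, allele2 = al2),
    individuals = data.frame(id = iid, population = fam))
}

#' Write a GenotypeData object as a PED/MAP pair
#'
#' Deterministic column order (SNPs as stored, sorted by chromosome and
#' position); heterozygotes written as \code{allele1 allele2}; missing
#' genotypes as \code{"0 0"}. Round-trips through \code{\link{readPedMap}}.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param prefix output path prefix; writes \code{<prefix>.ped} and
#'   \code{<prefix>.map}.
#' @return Invisibly, the two file paths.
#' @export
writePedMap <- function(g, prefix) {
  stopifnot(is(g, "GenotypeData"))
  si <- snpInfo(g)
  mapPath <- paste0(prefix, ".map")
  pedPath <- paste0(prefix, ".ped")
  dir.create(dirname(mapPath), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(si$chromosome, si$id, 0, si$position_bp),
    mapPath, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  d <- dosage(g)
  L <- nrow(d); n <- ncol(d)
  g1 <- matrix(si$allele1, nrow = L, ncol = n)
  g2 <- matrix(si$allele1, nrow = L, ncol = n)
  het <- !is.na(d) & d == 1L; hom2 <- !is.na(d) & d == 2L; mis <- is.na(d)
  a2m <- matrix(si$allele2, nrow = L, ncol = n)
  g2[het] <- a2m[het]
  g1[hom2] <- a2m[hom2]; g2[hom2] <- a2m[hom2]
  g1[mis] <- "0"; g2[mis] <- "0"
  inter <- matrix("", nrow = 2L * L, ncol = n)
  inter[seq(1, 2 * L, 2), ] <- g1
  inter[seq(2, 2 * L, 2), ] <- g2
  ii <- indivInfo(g)
  rows <- vapply(seq_len(n), function(i)
    paste(c(ii$population[i], ii$id[i], "0", "0", "0", "-9", inter[, i]),
          collapse = " "), character(1))
  writeLines(rows, pedPath)
  invisible(c(ped = pedPath, map = mapPath))
}

#' Merge two genotype datasets with strand reconciliation
#'
#' Restricts both datasets to the intersection of SNP identifiers, flips the
#' second dataset's alleles (complement) and/or dosage orientation where its
#' coding disagrees with the first, drops SNPs with irreconcilable allele
#' pairs (with a warning count), and concatenates individuals. SNPs with
#' strand-ambiguous A/T or C/G alleles cannot be checked for strand and are
#' kept under the same-strand assumption by default.
#'
#' @param a,b \linkS4class{GenotypeData} objects (QC-filtered).
#' @param ambiguous \code{"keep"} (default; assume same strand, count
#'   reported via message) or \code{"drop"}.
#' @return A merged \linkS4class{GenotypeData} on \code{a}'s allele coding.
#' @export
mergeGenotypes <- function(a, b, ambiguous = c("keep", "drop")) {
  ambiguous <- match.arg(ambiguous)
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) == 0L) stop("no SNPs shared between datasets")
  a <- a[shared, ]; b <- b[shared, ]
  ra <- rowData(a); rb <- rowData(b)
  da <- dosage(a); db <- dosage(b)

  ambig <- isStrandAmbiguous(ra$allele1, ra$allele2)
  nDrop <- 0L
  keep <- rep(TRUE, length(shared))
  for (j in seq_along(shared)) {
    setA <- c(ra$allele1[j], ra$allele2[j])
    setB <- c(rb$allele1[j], rb$allele2[j])
    if (setequal(setA, setB)) {
      if (rb$allele2[j] != ra$allele2[j]) db[j, ] <- 2L - db[j, ]
    } else if (setequal(setA, complementBase(setB))) {
      if (complementBase(rb$allele2[j]) != ra$allele2[j]) db[j, ] <- 2L - db[j, ]
    } else {
      keep[j] <- FALSE
      nDrop <- nDrop + 1L
    }
  }
  if (nDrop) warning(sprintf("%d SNP(s) with irreconcilable alleles excluded", nDrop))
  if (ambiguous == "drop") {
    keep <- keep & !ambig
  } else if (any(ambig)) {
    message(sprintf("%d strand-ambiguous (A/T or C/G) SNP(s) kept assuming same strand",
                    sum(ambig)))
  }
  if (!any(keep)) stop("no reconcilable shared SNPs")

  ia <- indivInfo(a); ib <- indivInfo(b)
  GenotypeData(
    dosage = cbind(da[keep, , drop = FALSE], db[keep, , drop = FALSE]),
    snps = snpInfo(a)[keep, ],
    individuals = rbind(ia, ib))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the allele counts, the p-value is
#' the total probability of heterozygote counts whose conditional probability
#' does not exceed that of the observed count.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return The exact p-value.
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0L) return(1)
  nA <- 2L * nAA + nAa
  rare <- min(nA, 2L * n - nA)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(nAa = h | allele counts) up to a constant
  lp <- vapply(hets, function(h) {
    hom1 <- (rare - h) / 2
    hom2 <- n - h - hom1
    h * log(2) - lfactorial(hom1) - lfactorial(h) - lfactorial(hom2)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(min(nAa, rare), hets)]
  sum(p[p <= obs + 1e-12])
}

#' Quality-control filtering of a genotype dataset
#'
#' Removes SNPs failing, in order: per-SNP missingness above
#' \code{maxMissing}; monomorphic in the sample; minor allele frequency below
#' \code{minMAF}; Hardy-Weinberg disequilibrium (exact test per population,
#' removed if the minimum p-value is below \code{hweAlpha}). Each removed SNP
#' is attributed to the first filter it fails, so filter counts plus the
#' retained count equal the input count. Optionally removes individuals with
#' missingness above \code{maxMissingIndiv} first.
#'
#' @param g a \linkS4class{GenotypeData}.
#' @param maxMissing maximum tolerated fraction of missing genotypes per SNP.
#' @param dropMonomorphic remove SNPs with a single observed allele?
#' @param minMAF minor-allele-frequency floor (0 disables).
#' @param hweAlpha HWE significance threshold (0 disables; applied per
#'   population).
#' @param maxMissingIndiv per-individual missingness cap (1 disables).
#' @return list with \code{genotypes} (filtered \linkS4class{GenotypeData})
#'   and \code{report} (data.frame of per-filter removal counts).
#' @export
qcFilter <- function(g, maxMissing = 0.10, dropMonomorphic = TRUE,
                     minMAF = 0, hweAlpha = 0, maxMissingIndiv = 1) {
  d <- dosage(g)
  nIndiv0 <- ncol(d)
  indivMiss <- colMeans(is.na(d))
  keepInd <- indivMiss <= maxMissingIndiv
  if (!all(keepInd)) {
    g <- g[, keepInd]
    d <- dosage(g)
  }
  nSnps <- nrow(d)
  miss <- rowMeans(is.na(d))
  p <- rowMeans(d, na.rm = TRUE) / 2
  failMiss <- miss > maxMissing
  failMono <- dropMonomorphic & (is.nan(p) | p == 0 | p == 1)
  failMAF <- (minMAF > 0) & !is.nan(p) & (pmin(p, 1 - p) < minMAF)
  failHWE <- rep(FALSE, nSnps)
  if (hweAlpha > 0) {
    pops <- populations(g)
    cand <- which(!(failMiss | failMono | failMAF))
    for (j in cand) {
      pmin_ <- 1
      for (pp in unique(pops)) {
        x <- d[j, pops == pp]; x <- x[!is.na(x)]
        if (length(x) < 2L) next
        pv <- hweExactTest(sum(x == 0L), sum(x == 1L), sum(x == 2L))
        pmin_ <- min(pmin_, pv)
      }
      failHWE[j] <- pmin_ < hweAlpha
    }
  }
  reason <- rep("retained", nSnps)
  reason[failHWE] <- "hwe"
  reason[failMAF] <- "maf"
  reason[failMono] <- "monomorphic"
  reason[failMiss] <- "missingness"
  keep <- reason == "retained"
  if (!any(keep)) stop("all SNPs removed by QC filters")
  report <- data.frame(
    filter = c("missingness", "monomorphic", "maf", "hwe",
               "individuals_removed", "retained"),
    count = c(sum(reason == "missingness"), sum(reason == "monomorphic"),
              sum(reason == "maf"), sum(reason == "hwe"),
              nIndiv0 - sum(keepInd), sum(keep)))
  list(genotypes = g[keep, ], report = report)
}

#' Sliding-window LD pruning
#'
#' Greedy pruning of SNPs in high linkage disequilibrium, per chromosome:
#' within each window of \code{window} retained SNPs, while any pair has
#' squared dosage correlation above \code{r2Max} (computed over
#' pairwise-complete individuals), the member of the currently worst pair
#' with the larger missingness is removed (ties broken towards the larger
#' column index); the window then advances by \code{step} SNPs.
#'
#' @param g a \linkS4class{GenotypeData} with SNPs sorted by position.
#' @param window window size in SNPs (>= 2).
#' @param step window increment in SNPs.
#' @param r2Max maximum tolerated squared correlation.
#' @return The pruned \linkS4class{GenotypeData}.
#' @export
ldPrune <- function(g, window = 50, step = 10, r2Max = 0.1) {
  if (window < 2L) stop("window must be at least 2")
  d <- dosage(g)
  miss <- rowMeans(is.na(d))
  chrom <- rowData(g)$chromosome
  keep <- rep(TRUE, nrow(d))
  for (ch in unique(chrom)) {
    # Repeat full windowed passes until a pass removes nothing, so that no
    # within-window pair of the returned set exceeds r2Max.
    repeat {
      changed <- FALSE
      start <- 1L
      repeat {
        cur <- which(chrom == ch & keep)
        if (start > length(cur) - 1L) break
        win <- cur[start:min(start + window - 1L, length(cur))]
        if (length(win) >= 2L) {
          repeat {
            m <- t(d[win, , drop = FALSE])
            r2 <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))^2
            r2[!is.finite(r2)] <- 0
            diag(r2) <- 0
            if (max(r2) <= r2Max) break
            w <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
            pair <- win[sort(w)]
            drop <- if (miss[pair[1]] > miss[pair[2]]) pair[1]
                    else if (miss[pair[2]] > miss[pair[1]]) pair[2]
                    else max(pair)
            keep[drop] <- FALSE
            changed <- TRUE
            win <- setdiff(win, drop)
            if (length(win) < 2L) break
          }
        }
        start <- start + step
      }
      if (!changed) break
    }
  }
  g[keep, ]
}
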