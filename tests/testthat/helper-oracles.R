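# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive each quantity through a different code path
# (scalar loops, enumeration, brute-force grids) than the implementation.

# Small GenotypeData builder for hand-constructed dosage matrices.
makeGeno <- function(dos, pops, chrom = NULL, pos = NULL,
                     allele1 = "A", allele2 = "G", ids = NULL) {
  dos <- as.matrix(dos)
  L <- nrow(dos)
  GenotypeData(
    dosage = dos,
    snps = data.frame(id = sprintf("s%03d", seq_len(L)),
                      chromosome = chrom %||% rep(1L, L),
                      position_bp = pos %||% (seq_len(L) * 1000L),
                      allele1 = allele1, allele2 = allele2),
    individuals = data.frame(id = ids %||% sprintf("i%03d", seq_len(ncol(dos))),
                             population = pops))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Textbook Weir & Cockerham (1984) theta for two populations, written as a
# plain scalar loop over loci following the published component formulas.
wcThetaOracle <- function(dosA, dosB) {
  sa <- sb <- sc <- 0
  for (l in seq_len(nrow(dosA))) {
    xA <- dosA[l, ]; xA <- xA[!is.na(xA)]
    xB <- dosB[l, ]; xB <- xB[!is.na(xB)]
    n1 <- length(xA); n2 <- length(xB)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(xA) / (2 * n1); p2 <- sum(xB) / (2 * n2)
    h1 <- mean(xA == 1); h2 <- mean(xB == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    CV2 <- ((n1 - nbar)^2 + (n2 - nbar)^2) / (r - 1) / nbar^2  # squared CV of sizes
    nc <- nbar * (1 - CV2 / r)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar / (r - 1)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    sa <- sa + a; sb <- sb + b; sc <- sc + cc
  }
  sa / (sa + sb + sc)
}

# HWE exact p-value by direct enumeration with exact probabilities
# (factorials, no logs): conditional distribution of the heterozygote count
# given allele counts.
hweEnumOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  probs <- c()
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  for (h in hets) {
    m1 <- (nA - h) / 2; m2 <- (na - h) / 2
    probs <- c(probs, 2^h * factorial(n) /
                 (factorial(m1) * factorial(h) * factorial(m2)) *
                 factorial(nA) * factorial(na) / factorial(2 * n))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(nAa, hets)]
  sum(probs[probs <= obs + 1e-12])
}

# Brute-force Procrustes similarity: both configurations centred and scaled
# to unit sum of squares; maximise the cross-covariance over a fine rotation
# grid with and without reflection. t0 equals the maximal <X, Y R>. For a
# 2-D rotation R(theta), <X, Y R> = a cos(theta) + b sin(theta) with
# coefficients read off the 2x2 cross-product M = Y'X, so the grid scan is
# a vectorised evaluation over the angle vector.
procrustesGridOracle <- function(X, Y, nGrid = 360000) {
  norm2 <- function(M) { M <- scale(M, scale = FALSE); M / sqrt(sum(M^2)) }
  X <- norm2(X); Y <- norm2(Y)
  th <- seq(0, 2 * pi, length.out = nGrid)
  best <- -Inf
  for (refl in c(1, -1)) {
    M <- t(Y %*% diag(c(1, refl))) %*% X
    a <- M[1, 1] + M[2, 2]
    b <- M[1, 2] - M[2, 1]
    best <- max(best, max(a * cos(th) + b * sin(th)))
  }
  best
}

# Exhaustive permutation search for the SSC (reference for the assignment
# solver).
sscExhaustive <- function(Q1, Q2) {
  n <- nrow(Q1); K <- ncol(Q1)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- -Inf
  for (p in perms(seq_len(K))) {
    s <- 1 - sqrt(sum((Q1 - Q2[, p, drop = FALSE])^2)) / sqrt(2 * n)
    best <- max(best, s)
  }
  best
}

# Expected intervals of a greedy left-to-right tiling of m contiguous
# low-rate SNPs into blocks of size [minS, maxS].
greedyTilingOracle <- function(m, minS = 5, maxS = 15) {
  sizes <- integer(0)
  while (m >= minS) {
    s <- min(maxS, m)
    sizes <- c(sizes, as.integer(s))
    m <- m - s
  }
  sizes
}
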