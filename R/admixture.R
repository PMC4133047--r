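# Individual ancestry estimation by EM under the binomial admixture
# likelihood, the symmetric similarity coefficient between runs, and
# grouping of replicate runs into modes.

# Shared E-step machinery. Dosages are pre-split once into x0 (missing ->
# 0) and y0 = (2 - dosage) with missing -> 0, so every EM iteration is pure
# matrix arithmetic: under the binomial admixture likelihood the expected
# per-individual log-likelihood is sum x log P + (2 - x) log(1 - P) with
# P = Q F, and the E-step posterior allele origins give the standard
# multiplicative Q and F updates.
admixPrep <- function(X) {
  ok <- !is.na(X)
  x0 <- X; x0[!ok] <- 0
  y0 <- (2 - X); y0[!ok] <- 0
  list(x0 = x0, y0 = y0, nLoci = rowSums(ok))
}

admixLogLik <- function(prep, P) {
  sum(prep$x0 * log(P) + prep$y0 * log1p(-P))
}

# One EM sweep: returns updated Q (always) and F (if updateF). The Q and F
# updates share the E-step computed at the current (Q, F).
emSweep <- function(prep, Q, F_, updateF = FALSE) {
  P <- clamp(Q %*% F_, 1e-12, 1 - 1e-12)
  A1 <- prep$x0 / P
  A2 <- prep$y0 / (1 - P)
  Qnew <- Q * (A1 %*% t(F_) + A2 %*% t(1 - F_)) / (2 * prep$nLoci)
  Qnew <- Qnew / rowSums(Qnew)
  if (updateF) {
    num <- (t(Q) %*% A1) * F_
    den <- num + (t(Q) %*% A2) * (1 - F_)
    Fnew <- num / den
    Fnew[den == 0] <- 0.5
  } else Fnew <- F_
  list(Q = Qnew, F_ = Fnew, logLik = admixLogLik(prep, P))
}

#' Supervised estimation of individual ancestry proportions
#'
#' Given fixed source allele frequencies, maximises each individual's
#' binomial admixture log-likelihood over the membership simplex by EM
#' (monotone in the likelihood). Frequencies are clamped away from 0 and 1
#' to keep the likelihood finite at fixed alleles.
#'
#' @param g a \linkS4class{GenotypeData} (SNPs must match the columns of
#'   \code{sourceFreqs}).
#' @param sourceFreqs matrix K x SNPs of allele-2 frequencies (rownames =
#'   source labels).
#' @param tol convergence threshold on the log-likelihood increase.
#' @param maxIter iteration cap.
#' @param freqClamp clamp bound for the source frequencies; the default
#'   keeps them in [1/(2n), 1 - 1/(2n)] with n the number of individuals.
#' @return An \linkS4class{AncestryEstimate} with method "supervised".
#' @export
estimateAncestrySupervised <- function(g, sourceFreqs, tol = 1e-4,
                                       maxIter = 5000, freqClamp = NULL) {
  X <- t(dosage(g))
  if (any(rowSums(!is.na(X)) == 0L)) stop("individual with all genotypes missing")
  K <- nrow(sourceFreqs)
  n <- nrow(X)
  if (is.null(freqClamp)) freqClamp <- 1 / (2 * max(n, 2))
  F_ <- clamp(as.matrix(sourceFreqs), freqClamp, 1 - freqClamp)
  prep <- admixPrep(X)
  if (K == 1L) {
    Q <- matrix(1, n, 1, dimnames = list(rownames(X), rownames(sourceFreqs)))
    return(new("AncestryEstimate", Q = Q, freq = F_,
               logLik = admixLogLik(prep, clamp(Q %*% F_, 1e-12, 1 - 1e-12)),
               seed = NA_integer_, method = "supervised"))
  }
  Q <- matrix(1 / K, n, K)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    sw <- emSweep(prep, Q, F_, updateF = FALSE)
    Q <- sw$Q
    if (sw$logLik - ll < tol && it > 1L) { ll <- sw$logLik; break }
    ll <- sw$logLik
  }
  dimnames(Q) <- list(rownames(X), rownames(sourceFreqs))
  new("AncestryEstimate", Q = Q, freq = F_, logLik = ll,
      seed = NA_integer_, method = "supervised")
}

#' Unsupervised estimation of ancestry proportions and source frequencies
#'
#' Joint EM on memberships Q and source frequencies F under the binomial
#' admixture likelihood (the model-based clustering likelihood of ancestry
#' software), from a random Dirichlet/Uniform initialisation. Terminates
#' when the log-likelihood increase falls below \code{tol}.
#'
#' @param g a \linkS4class{GenotypeData} (LD-pruned input recommended).
#' @param K number of clusters (>= 2).
#' @param seed integer seed for the initialisation.
#' @param tol log-likelihood increase termination threshold.
#' @param maxIter iteration cap.
#' @return An \linkS4class{AncestryEstimate} with method "unsupervised".
#' @export
estimateAncestryUnsupervised <- function(g, K, seed = 1, tol = 1e-4,
                                         maxIter = 5000) {
  if (K < 2) stop("K must be at least 2 (use the supervised estimator for K = 1)")
  X <- t(dosage(g))
  n <- nrow(X); L <- ncol(X)
  if (K > n) stop("K exceeds the number of individuals")
  if (any(rowSums(!is.na(X)) == 0L)) stop("individual with all genotypes missing")
  set.seed(seed)
  Q <- rdirichlet(n, rep(1, K))
  F_ <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
  fc <- 1 / (2 * n)
  prep <- admixPrep(X)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    sw <- emSweep(prep, Q, F_, updateF = TRUE)
    Q <- sw$Q
    F_ <- clamp(sw$F_, fc, 1 - fc)
    if (sw$logLik - ll < tol && it > 1L) { ll <- sw$logLik; break }
    ll <- sw$logLik
  }
  dimnames(Q) <- list(rownames(X), paste0("cluster", seq_len(K)))
  rownames(F_) <- colnames(Q)
  new("AncestryEstimate", Q = Q, freq = F_, logLik = ll,
      seed = as.integer(seed), method = "unsupervised")
}

# Exact maximum-weight column assignment by bitmask dynamic programming.
# S[j, k]: score of assigning column j of the second matrix to column k of
# the first. Returns perm with aligned column k = perm[k].
bestAssignment <- function(S) {
  K <- nrow(S)
  if (K > 20L) stop("assignment supported up to K = 20")
  nMask <- bitwShiftL(1L, K)
  best <- rep(-Inf, nMask); best[1L] <- 0
  choice <- matrix(NA_integer_, nMask, K)
  for (mask in 0:(nMask - 1L)) {
    if (!is.finite(best[mask + 1L])) next
    k <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(K - 1L))) != 0L) + 1L  # next column of Q1
    if (k > K) next
    for (j in seq_len(K)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      nm <- bitwOr(mask, bit)
      v <- best[mask + 1L] + S[j, k]
      if (v > best[nm + 1L]) {
        best[nm + 1L] <- v
        choice[nm + 1L, ] <- choice[mask + 1L, ]
        choice[nm + 1L, k] <- j
      }
    }
  }
  list(value = best[nMask], perm = choice[nMask, ])
}

#' Symmetric similarity coefficient between two membership matrices
#'
#' SSC = max over cluster-column permutations of
#' 1 - ||Q1 - Q2 P||_F / sqrt(2 n), which is 1 exactly when the two runs
#' agree up to cluster relabelling. The optimal permutation is found
#' exactly (the Frobenius objective reduces to a linear assignment over the
#' column cross-products).
#'
#' @param q1,q2 \linkS4class{AncestryEstimate} objects or n x K matrices
#'   with equal dimensions.
#' @return list with \code{similarity} and \code{permutation} (align column
#'   k of \code{q1} with column \code{permutation[k]} of \code{q2}).
#' @export
ssc <- function(q1, q2) {
  Q1 <- if (is(q1, "AncestryEstimate")) membershipQ(q1) else as.matrix(q1)
  Q2 <- if (is(q2, "AncestryEstimate")) membershipQ(q2) else as.matrix(q2)
  if (!all(dim(Q1) == dim(Q2))) stop("membership matrices must have equal dimensions")
  n <- nrow(Q1)
  S <- crossprod(Q2, Q1)   # S[j, k] = <Q2[, j], Q1[, k]>
  res <- bestAssignment(S)
  fro2 <- sum(Q1^2) + sum(Q2^2) - 2 * res$value
  sim <- 1 - sqrt(max(0, fro2)) / sqrt(2 * n)
  list(similarity = sim, permutation = res$perm)
}

#' Group replicate ancestry runs into modes
#'
#' Single-linkage grouping of runs on the relation SSC > threshold. Within
#' each mode, every run is aligned to the mode's first run by its optimal
#' column permutation, memberships are averaged elementwise, and rows are
#' renormalised to absorb floating-point drift. Modes are ordered by size
#' (largest first, ties by first run index).
#'
#' @param runs list of \linkS4class{AncestryEstimate} objects (or matrices)
#'   with common dimensions.
#' @param threshold SSC threshold for the same-mode relation.
#' @return A \linkS4class{ModeSet}.
#' @export
groupModes <- function(runs, threshold = 0.9) {
  if (length(runs) < 1L) stop("need at least one run")
  Qs <- lapply(runs, function(r)
    if (is(r, "AncestryEstimate")) membershipQ(r) else as.matrix(r))
  R <- length(Qs)
  sscMat <- diag(1, R)
  perms <- vector("list", R * R)
  dim(perms) <- c(R, R)
  for (i in seq_len(R)) for (j in seq_len(R)) if (i < j) {
    s <- ssc(Qs[[i]], Qs[[j]])
    sscMat[i, j] <- sscMat[j, i] <- s$similarity
    perms[[i, j]] <- s$permutation
  }
  # union-find single linkage
  parent <- seq_len(R)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(R)) for (j in seq_len(R)) if (i < j && sscMat[i, j] > threshold)
    parent[find(j)] <- find(i)
  comp <- vapply(seq_len(R), find, integer(1))
  modes <- split(seq_len(R), comp)
  modes <- modes[order(-lengths(modes), vapply(modes, min, integer(1)))]
  names(modes) <- NULL

  averagedQ <- vector("list", length(modes))
  permList <- vector("list", length(modes))
  for (m in seq_along(modes)) {
    ids <- modes[[m]]
    refId <- ids[1]
    acc <- Qs[[refId]]
    pl <- list(seq_len(ncol(acc)))
    if (length(ids) > 1L) for (id in ids[-1]) {
      p <- ssc(Qs[[refId]], Qs[[id]])$permutation
      acc <- acc + Qs[[id]][, p, drop = FALSE]
      pl[[length(pl) + 1L]] <- p
    }
    acc <- acc / length(ids)
    acc <- acc / rowSums(acc)
    averagedQ[[m]] <- acc
    permList[[m]] <- pl
  }
  new("ModeSet", modes = modes, averagedQ = averagedQ,
      permutations = permList, ssc = sscMat, threshold = threshold)
}
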