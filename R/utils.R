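# Internal utilities shared across modules.

#' Derive a stage-specific seed from a master seed
#'
#' One master seed drives the whole pipeline; each stochastic stage gets its
#' own reproducible stream by hashing the stage name into an offset. The
#' result always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage.
#' @return An integer seed.
#' @export
deriveSeed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 31 + v) %% 2147483647
  as.integer((abs(master) + h) %% 2147483647)
}

# Dirichlet draws via independent gammas; rows sum to one.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, ] <- 1 / k
  x / rowSums(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# DNA complement for strand flips at merge time.
complementBase <- function(x) {
  m <- c(A = "T", C = "G", G = "C", T = "A")
  unname(m[x])
}

isStrandAmbiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Sample variance with a toggle between the unbiased (n-1) and the
# maximum-likelihood (n) denominator.
sampleVariance <- function(x, unbiased = TRUE) {
  n <- length(x)
  v <- stats::var(x)
  if (unbiased) v else v * (n - 1) / n
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
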