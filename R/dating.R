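# Moment-based dating of a single admixture pulse from the mean and
# variance of individual ancestry fractions.

#' Moment estimator of time since a single admixture pulse
#'
#' Under a single founding pulse followed by closed random mating, the
#' variance of the individual ancestry fraction from a source halves each
#' generation: Var(H_g) = mu (1 - mu) / 2^g. Inverting with sample moments
#' gives g_hat = log2( mu_hat (1 - mu_hat) / s2_hat ). The estimate counts
#' generations before the birth of the sampled individuals, so the age in
#' years adds one generation: YBP = (g_hat + 1) x generation time.
#'
#' @param memberships numeric vector of per-individual ancestry fractions
#'   (membership proportions) for one source, length >= 2.
#' @param generationYears generation time in years (default 25).
#' @param unbiased use the unbiased (n-1) sample variance?
#' @return One-row data.frame: \code{n}, \code{mu}, \code{sigma2},
#'   \code{g_hat}, \code{ybp}, \code{flag} ("ok", or "inconsistent with
#'   post-founding mating" when the variance exceeds the founding-pulse
#'   bound mu(1-mu), which makes g_hat negative).
#' @export
admixtureTimeMoments <- function(memberships, generationYears = 25,
                                 unbiased = TRUE) {
  x <- memberships[!is.na(memberships)]
  if (length(x) < 2L) stop("need at least 2 membership values")
  mu <- mean(x)
  if (mu <= 0 || mu >= 1) stop("mean membership must lie strictly in (0,1)")
  s2 <- sampleVariance(x, unbiased = unbiased)
  if (s2 == 0) stop("zero variance of memberships: time since admixture undefined")
  g <- log2(mu * (1 - mu) / s2)
  flag <- if (g < 0) "inconsistent with post-founding mating" else "ok"
  data.frame(n = length(x), mu = mu, sigma2 = s2, g_hat = g,
             ybp = (g + 1) * generationYears, flag = flag,
             stringsAsFactors = FALSE)
}

# Map ancestry clusters to named sources at one K: each source is assigned
# the (unused) cluster column with the highest mean membership among its
# reference individuals, greedily from the best-supported source; a source
# whose best remaining column has mean reference membership below minMean is
# treated as absent at this K.
identifySourceClusters <- function(Q, sourceRefs, minMean = 0.5) {
  means <- sapply(sourceRefs, function(ids) {
    ids <- intersect(ids, rownames(Q))
    if (!length(ids)) return(rep(NA_real_, ncol(Q)))
    colMeans(Q[ids, , drop = FALSE])
  })                                   # K x nSources
  out <- setNames(rep(NA_integer_, length(sourceRefs)), names(sourceRefs))
  used <- integer(0)
  ord <- order(-apply(means, 2, max, na.rm = TRUE))
  for (s in ord) {
    m <- means[, s]
    m[used] <- -Inf
    j <- which.max(m)
    if (is.finite(m[j]) && m[j] >= minMean) {
      out[s] <- j
      used <- c(used, j)
    }
  }
  out
}

#' Admixture-time report across pooled groups, sources and K
#'
#' For each pooled group of populations and each source, computes the moment
#' estimate of the admixture pulse time at every K, using membership
#' proportions in the cluster identified with that source (the cluster with
#' maximal mean membership among designated reference individuals). Pooling
#' concatenates the member populations' membership vectors before taking
#' moments. A summary row gives the mean and SD of YBP across K per
#' group/source.
#'
#' @param qPerK named list (names = K values) of membership matrices with
#'   individual rownames (e.g. mode-averaged Q from \code{\link{groupModes}}).
#' @param groups named list: group label -> character vector of population
#'   labels pooled into that group.
#' @param sourceRefs named list: source label -> reference individual ids
#'   used to identify the source's cluster at each K.
#' @param indivPops named character vector individual id -> population.
#' @param generationYears generation time in years.
#' @param unbiased use the unbiased sample variance?
#' @param minMean minimum mean reference membership for a source cluster to
#'   count as present at a given K.
#' @return list with \code{perK} (data.frame: group, source, K, n, mu,
#'   sigma2, g_hat, ybp, flag) and \code{summary} (data.frame: group,
#'   source, mean_ybp, sd_ybp, n_K).
#' @export
datingReport <- function(qPerK, groups, sourceRefs, indivPops,
                         generationYears = 25, unbiased = TRUE,
                         minMean = 0.5) {
  rows <- list()
  for (kName in names(qPerK)) {
    Q <- qPerK[[kName]]
    cl <- identifySourceClusters(Q, sourceRefs, minMean = minMean)
    for (src in names(cl)) {
      if (is.na(cl[src])) {
        message(sprintf("source '%s' absent at K = %s; skipped", src, kName))
        next
      }
      for (grp in names(groups)) {
        ids <- rownames(Q)[indivPops[rownames(Q)] %in% groups[[grp]]]
        if (length(ids) < 2L) next
        est <- admixtureTimeMoments(Q[ids, cl[src]], generationYears, unbiased)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(group = grp, source = src, K = as.integer(kName)), est)
      }
    }
  }
  perK <- do.call(rbind, rows)
  if (is.null(perK)) return(list(perK = NULL, summary = NULL))
  summary <- do.call(rbind, lapply(split(perK, perK[c("group", "source")], drop = TRUE),
    function(s) data.frame(group = s$group[1], source = s$source[1],
                           mean_ybp = mean(s$ybp), sd_ybp = stats::sd(s$ybp),
                           n_K = nrow(s))))
  rownames(summary) <- NULL
  list(perK = perK, summary = summary)
}
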