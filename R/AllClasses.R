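#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' GenotypeData: diploid SNP genotypes with marker and sample metadata
#'
#' Container for a diploid SNP panel, extending
#' \linkS4class{SummarizedExperiment}. The single \code{"dosage"} assay holds
#' the count of the reference-orientation second allele (\code{allele2}) per
#' SNP (rows) and individual (columns), coded 0/1/2 with \code{NA} for
#' missing genotypes. \code{rowData} carries \code{chromosome},
#' \code{position_bp}, \code{allele1} and \code{allele2}; \code{colData}
#' carries \code{population}.
#'
#' @seealso \code{\link{GenotypeData}} for the constructor,
#'   \code{\link{dosage}}, \code{\link{snpInfo}}, \code{\link{indivInfo}}.
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
  }
  rd <- rowData(object)
  need <- c("chromosome", "position_bp", "allele1", "allele2")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  else {
    if (any(rd$allele1 == rd$allele2))
      msg <- c(msg, "allele1 and allele2 must differ at every SNP")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicate SNP identifiers")
  }
  if (!"population" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'population'")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate individual identifiers")
  if (length(msg)) msg else TRUE
})

#' BlockSet: disjoint haplotype blocks over a SNP panel
#'
#' A set of non-overlapping runs of contiguous SNPs (5-15 by default) used as
#' haplotype blocks. Indices refer to rows of the \linkS4class{GenotypeData}
#' object the blocks were built on (SNPs sorted by chromosome and position).
#'
#' @slot blocks data.frame with columns \code{chromosome}, \code{first},
#'   \code{last} (global SNP row indices, inclusive) and \code{n_snps}.
#' @slot mode one of \code{"below"}, \code{"above"}, \code{"random"}: blocks
#'   where inter-SNP recombination is below/above the threshold, or random
#'   length-matched blocks.
#' @slot minSize,maxSize admissible block sizes in SNPs.
#' @slot threshold recombination-rate threshold in cM/Mb.
#' @export
setClass("BlockSet", representation(
  blocks = "data.frame", mode = "character",
  minSize = "integer", maxSize = "integer", threshold = "numeric"
))

setValidity("BlockSet", function(object) {
  b <- object@blocks
  msg <- character()
  if (!all(c("chromosome", "first", "last", "n_snps") %in% colnames(b)))
    return("blocks needs columns chromosome, first, last, n_snps")
  if (nrow(b)) {
    if (any(b$n_snps != b$last - b$first + 1L))
      msg <- c(msg, "n_snps inconsistent with first/last")
    if (any(b$n_snps < object@minSize | b$n_snps > object@maxSize))
      msg <- c(msg, "block size outside [minSize, maxSize]")
    o <- order(b$first)
    if (any(b$first[o][-1] <= b$last[o][-nrow(b)]))
      msg <- c(msg, "blocks overlap")
  }
  if (length(msg)) msg else TRUE
})

#' PopDistance: labelled symmetric dissimilarity matrix
#'
#' Symmetric zero-diagonal matrix of pairwise dissimilarities between
#' populations or individuals. \code{flavor} records the statistic:
#' Weir-Cockerham \code{"FST"} (entries may be marginally negative and are
#' kept raw), allele-sharing \code{"ASD"}, or \code{"Euclidean"}.
#'
#' @slot distance numeric matrix with matching dimnames.
#' @slot flavor character scalar.
#' @export
setClass("PopDistance", representation(distance = "matrix", flavor = "character"))

setValidity("PopDistance", function(object) {
  d <- object@distance
  msg <- character()
  if (nrow(d) != ncol(d)) return("matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    msg <- c(msg, "dimnames must be present and identical")
  if (any(abs(d - t(d)) > 1e-12, na.rm = TRUE)) msg <- c(msg, "matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (!object@flavor %in% c("FST", "ASD", "Euclidean"))
    msg <- c(msg, "flavor must be FST, ASD or Euclidean")
  if (object@flavor != "FST" && any(d < -1e-12, na.rm = TRUE))
    msg <- c(msg, "negative entries only allowed for FST")
  if (length(msg)) msg else TRUE
})

#' MDSConfig: a classical multidimensional scaling solution
#'
#' Coordinates from metric (Torgerson) MDS of a dissimilarity matrix,
#' together with the retained eigenvalues and the Spearman fidelity rho
#' between configuration distances and the input dissimilarities.
#'
#' @slot points numeric matrix (objects x dimensions), column-centred.
#' @slot eig numeric, eigenvalues of the retained dimensions.
#' @slot rho Spearman correlation between configuration Euclidean distances
#'   and input dissimilarities over the lower triangle.
#' @export
setClass("MDSConfig", representation(points = "matrix", eig = "numeric", rho = "numeric"))

setValidity("MDSConfig", function(object) {
  if (max(abs(colMeans(object@points))) > 1e-9) "coordinates must be centred" else TRUE
})

#' AncestryEstimate: membership proportions from one estimation run
#'
#' Result of one EM run estimating individual ancestry proportions under the
#' binomial admixture likelihood. \code{Q} is individuals x K with rows on
#' the simplex; \code{freq} holds the K x L source allele frequencies (the
#' fixed panel for supervised runs, the estimate for unsupervised runs).
#'
#' @slot Q numeric matrix, individuals x K.
#' @slot freq numeric matrix, K x SNPs.
#' @slot logLik numeric, final log-likelihood.
#' @slot seed integer seed used for initialisation (NA for supervised runs).
#' @slot method "supervised" or "unsupervised".
#' @export
setClass("AncestryEstimate", representation(
  Q = "matrix", freq = "matrix", logLik = "numeric",
  seed = "integer", method = "character"
))

setValidity("AncestryEstimate", function(object) {
  msg <- character()
  if (any(object@Q < -1e-9 | object@Q > 1 + 1e-9)) msg <- c(msg, "Q entries must lie in [0,1]")
  if (any(abs(rowSums(object@Q) - 1) > 1e-6)) msg <- c(msg, "Q rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' ModeSet: replicate ancestry runs grouped into modes
#'
#' Partition of replicate ancestry-estimation runs into modes by
#' single-linkage grouping on the symmetric similarity coefficient (SSC),
#' with per-mode column alignment and the mode-averaged membership matrix.
#'
#' @slot modes list of integer vectors of run indices, largest mode first.
#' @slot averagedQ list of mode-averaged membership matrices (rows renormalised).
#' @slot permutations list (per mode) of column permutations aligning each
#'   member run to the mode's first run.
#' @slot ssc symmetric matrix of pairwise SSC values across runs.
#' @slot threshold SSC threshold defining the same-mode relation.
#' @export
setClass("ModeSet", representation(
  modes = "list", averagedQ = "list", permutations = "list",
  ssc = "matrix", threshold = "numeric"
))

setValidity("ModeSet", function(object) {
  s <- object@ssc
  msg <- character()
  if (nrow(s) != ncol(s) || any(abs(s - t(s)) > 1e-9)) msg <- c(msg, "ssc must be symmetric")
  if (any(abs(diag(s) - 1) > 1e-9)) msg <- c(msg, "ssc diagonal must be 1")
  got <- sort(unlist(object@modes))
  if (!identical(got, seq_len(nrow(s)))) msg <- c(msg, "modes must partition the runs")
  if (length(msg)) msg else TRUE
})
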