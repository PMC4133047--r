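#' Construct a GenotypeData object
#'
#' @param dosage integer/numeric matrix, SNPs x individuals, entries 0/1/2 or
#'   NA (count of \code{allele2}).
#' @param snps data.frame with one row per SNP: \code{id}, \code{chromosome}
#'   (1-22), \code{position_bp} (1-based), \code{allele1}, \code{allele2}.
#' @param individuals data.frame with one row per individual: \code{id},
#'   \code{population}.
#' @param sort sort SNPs by (chromosome, position)? Default TRUE.
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' g <- GenotypeData(
#'   dosage = matrix(c(0L, 1L, 2L, NA), 2, 2),
#'   snps = data.frame(id = c("rs1", "rs2"), chromosome = 1,
#'                     position_bp = c(100, 200),
#'                     allele1 = "A", allele2 = "G"),
#'   individuals = data.frame(id = c("i1", "i2"), population = "pop1"))
#' dosage(g)
#' @export
GenotypeData <- function(dosage, snps, individuals, sort = TRUE) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == nrow(snps), ncol(dosage) == nrow(individuals))
  rownames(dosage) <- snps$id
  colnames(dosage) <- individuals$id
  rd <- DataFrame(chromosome = as.integer(snps$chromosome),
                  position_bp = as.integer(snps$position_bp),
                  allele1 = as.character(snps$allele1),
                  allele2 = as.character(snps$allele2),
                  row.names = snps$id)
  cd <- DataFrame(population = as.character(individuals$population),
                  row.names = individuals$id)
  se <- SummarizedExperiment(assays = list(dosage = dosage), rowData = rd, colData = cd)
  obj <- new("GenotypeData", se)
  if (sort) {
    o <- order(rowData(obj)$chromosome, rowData(obj)$position_bp)
    obj <- obj[o, ]
  }
  validObject(obj)
  obj
}

#' @rdname GenotypeData
#' @param object,x a GenotypeData object.
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))

#' @rdname GenotypeData
#' @export
setMethod("dosage", "GenotypeData", function(object)
  SummarizedExperiment::assay(object, "dosage"))

#' @rdname GenotypeData
#' @export
snpInfo <- function(x) {
  rd <- rowData(x)
  data.frame(id = rownames(x), chromosome = rd$chromosome,
             position_bp = rd$position_bp, allele1 = rd$allele1,
             allele2 = rd$allele2, row.names = NULL)
}

#' @rdname GenotypeData
#' @export
indivInfo <- function(x) {
  data.frame(id = colnames(x), population = colData(x)$population,
             row.names = NULL)
}

#' @rdname GenotypeData
#' @export
populations <- function(x) setNames(colData(x)$population, colnames(x))

setMethod("show", "GenotypeData", function(object) {
  d <- dosage(object)
  cat("GenotypeData:", nrow(object), "SNPs x", ncol(object), "individuals\n")
  cat("  populations:", paste(unique(colData(object)$population), collapse = ", "), "\n")
  cat("  chromosomes:", paste(sort(unique(rowData(object)$chromosome)), collapse = ", "), "\n")
  cat(sprintf("  missing: %.4f\n", mean(is.na(d))))
})

setMethod("show", "PopDistance", function(object) {
  cat(sprintf("PopDistance (%s): %d x %d\n", object@flavor,
              nrow(object@distance), ncol(object@distance)))
})

setMethod("show", "BlockSet", function(object) {
  cat(sprintf("BlockSet (mode '%s'): %d blocks, sizes %d-%d, threshold %g cM/Mb\n",
              object@mode, nrow(object@blocks), object@minSize, object@maxSize,
              object@threshold))
})

setMethod("show", "MDSConfig", function(object) {
  cat(sprintf("MDSConfig: %d points in %d dimensions, Spearman rho = %.4f\n",
              nrow(object@points), ncol(object@points), object@rho))
})

setMethod("show", "AncestryEstimate", function(object) {
  cat(sprintf("AncestryEstimate (%s): n = %d, K = %d, logLik = %.2f\n",
              object@method, nrow(object@Q), ncol(object@Q), object@logLik))
})

setMethod("show", "ModeSet", function(object) {
  cat(sprintf("ModeSet: %d runs in %d mode(s) at SSC > %.2f; mode sizes: %s\n",
              nrow(object@ssc), length(object@modes), object@threshold,
              paste(lengths(object@modes), collapse = ", ")))
})

#' Accessors for analysis result classes
#'
#' \code{distanceMatrix} returns the raw symmetric matrix of a
#' \linkS4class{PopDistance}; \code{blockTable} the block data.frame of a
#' \linkS4class{BlockSet}; \code{mdsPoints} and \code{mdsRho} the coordinates
#' and fidelity of an \linkS4class{MDSConfig}; \code{membershipQ} the Q
#' matrix of an \linkS4class{AncestryEstimate}; \code{modeMembership} the
#' averaged Q of one mode of a \linkS4class{ModeSet}.
#'
#' @param x the object.
#' @param mode mode index (1 = largest mode).
#' @name accessors
NULL

#' @rdname accessors
#' @export
distanceMatrix <- function(x) x@distance

#' @rdname accessors
#' @export
distanceFlavor <- function(x) x@flavor

#' @rdname accessors
#' @export
blockTable <- function(x) x@blocks

#' @rdname accessors
#' @export
mdsPoints <- function(x) x@points

#' @rdname accessors
#' @export
mdsRho <- function(x) x@rho

#' @rdname accessors
#' @export
mdsEigenvalues <- function(x) x@eig

#' @rdname accessors
#' @export
membershipQ <- function(x) x@Q

#' @rdname accessors
#' @export
sourceFrequencies <- function(x) x@freq

#' @rdname accessors
#' @export
runLogLik <- function(x) x@logLik

#' @rdname accessors
#' @export
modeMembership <- function(x, mode = 1L) x@averagedQ[[mode]]

#' @rdname accessors
#' @export
modeRuns <- function(x) x@modes

#' @rdname accessors
#' @export
sscMatrix <- function(x) x@ssc
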