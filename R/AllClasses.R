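#' @import methods
NULL

.CODING_TAGS <- c("rare1", "common1", "mixed", "unknown")

.validCoding <- function(coding) {
  length(coding) == 1L &&
    (coding %in% .CODING_TAGS || grepl("^vcf:.+", coding))
}

#' GenotypeMatrix: a biallelic genotype matrix
#'
#' Container for a genotype matrix with Individuals in rows and SNPs in
#' columns. Entries are 0/1 in binary (haploid/inbred) mode or 0/1/2 in
#' diploid mode, with no missing values. Row and column names carry the
#' Individual and SNP identifiers and must be unique. The \code{coding} tag
#' records the per-SNP polarity convention: \code{"rare1"} (minor allele
#' coded 1), \code{"common1"}, \code{"mixed"}, \code{"vcf:<id>"} (allele of
#' the reference Individual coded 0), or \code{"unknown"}.
#'
#' @slot values integer matrix, Individuals x SNPs.
#' @slot coding character(1) coding tag.
#' @slot ploidyMode \code{"binary"} or \code{"diploid"}.
#'
#' @seealso [GenotypeMatrix()] for the constructor,
#'   [recodeGenotypes()], [transformGenotypes()], [snpPca()].
#' @export
setClass("GenotypeMatrix",
  representation(values = "matrix", coding = "character",
                 ploidyMode = "character"))

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if (nrow(v) < 2L || ncol(v) < 2L)
    msgs <- c(msgs, "matrix must have at least 2 Individuals and 2 SNPs")
  if (anyNA(v))
    msgs <- c(msgs, "missing values are not allowed")
  allowed <- if (identical(object@ploidyMode, "diploid")) 0:2 else 0:1
  if (!anyNA(v) && !all(v %in% allowed))
    msgs <- c(msgs, sprintf("entries must be in {%s} for %s mode",
                            paste(allowed, collapse = ","), object@ploidyMode))
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "Individual and SNP identifiers are required")
  else {
    if (anyDuplicated(rownames(v)))
      msgs <- c(msgs, "duplicated Individual identifiers")
    if (anyDuplicated(colnames(v)))
      msgs <- c(msgs, "duplicated SNP identifiers")
  }
  if (!.validCoding(object@coding))
    msgs <- c(msgs, "invalid coding tag")
  if (!object@ploidyMode %in% c("binary", "diploid"))
    msgs <- c(msgs, "ploidyMode must be 'binary' or 'diploid'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param values numeric/integer matrix, Individuals in rows, SNPs in columns.
#' @param individualIds,snpIds optional identifier vectors; taken from
#'   dimnames when absent, generated (\code{ind0001...}, \code{snp0001...})
#'   when those are missing too.
#' @param coding coding tag (see [GenotypeMatrix-class]).
#' @param ploidyMode \code{"binary"}, \code{"diploid"}, or \code{"auto"}
#'   (diploid iff any entry equals 2).
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0, 1, 1, 0, 1, 1), nrow = 3))
#' dim(gm)
#' @export
GenotypeMatrix <- function(values, individualIds = NULL, snpIds = NULL,
                           coding = "unknown", ploidyMode = "auto") {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("genotype values must be numeric")
  storage.mode(values) <- "integer"
  if (is.null(individualIds))
    individualIds <- rownames(values)
  if (is.null(snpIds))
    snpIds <- colnames(values)
  if (is.null(individualIds))
    individualIds <- sprintf("ind%04d", seq_len(nrow(values)))
  if (is.null(snpIds))
    snpIds <- sprintf("snp%04d", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(individualIds), as.character(snpIds))
  if (identical(ploidyMode, "auto"))
    ploidyMode <- if (any(values == 2L, na.rm = TRUE)) "diploid" else "binary"
  new("GenotypeMatrix", values = values, coding = coding,
      ploidyMode = ploidyMode)
}

#' TransformedGenotypes: a centered/standardized genotype matrix
#'
#' Result of applying one of the six PCA transforms to a [GenotypeMatrix-class].
#' Retains the grand mean, the per-Individual and per-SNP means, and (for
#' standardized variants) the per-axis standard deviations, so that the
#' original matrix and the AMMI decomposition can be reconstructed.
#'
#' @slot values numeric matrix, same shape and dimnames as the source.
#' @slot variant one of the six variant tags (see [pcaVariants()]).
#' @slot grandMean numeric(1).
#' @slot individualMeans,snpMeans per-axis means of the source matrix.
#' @slot individualSds,snpSds per-axis standard deviations (n-1 denominator);
#'   length zero unless the variant standardizes that axis.
#' @export
setClass("TransformedGenotypes",
  representation(values = "matrix", variant = "character",
                 grandMean = "numeric",
                 individualMeans = "numeric", snpMeans = "numeric",
                 individualSds = "numeric", snpSds = "numeric"))

#' SnpPca: an SVD decomposition of a transformed genotype matrix
#'
#' Holds the top-\code{k} singular values, unit eigenvectors for both axes,
#' per-component sums of squares (the squared singular values) and Gollob
#' degrees of freedom, and the residual SS/df closing the decomposed source.
#' Scores in the default symmetric convention are
#' \code{sqrt(lambda) * eigenvector} on both axes, so an Individual score
#' times a SNP score estimates that cell's interaction directly.
#'
#' @slot variant variant tag of the transform that was decomposed.
#' @slot singularValues numeric(k), descending.
#' @slot individualVectors R x k unit left singular vectors.
#' @slot snpVectors C x k unit right singular vectors.
#' @slot componentSS squared singular values.
#' @slot componentDf Gollob df per component.
#' @slot residualSS,residualDf remainder closing the source SS/df.
#' @slot totalSS total SS of the transformed matrix.
#' @slot grandMean,individualMeans,snpMeans means of the source genotype
#'   matrix (carried for AMMI and reconstruction).
#' @seealso [snpPca()], [scores()], [reconstructComponents()]
#' @export
setClass("SnpPca",
  representation(variant = "character", singularValues = "numeric",
                 individualVectors = "matrix", snpVectors = "matrix",
                 componentSS = "numeric", componentDf = "numeric",
                 residualSS = "numeric", residualDf = "numeric",
                 totalSS = "numeric", grandMean = "numeric",
                 individualMeans = "numeric", snpMeans = "numeric"))

setValidity("SnpPca", function(object) {
  msgs <- character(0)
  sv <- object@singularValues
  if (length(sv) && any(diff(sv) > 1e-8))
    msgs <- c(msgs, "singular values must be descending")
  if (length(sv) && any(sv < -1e-12))
    msgs <- c(msgs, "singular values must be nonnegative")
  if (ncol(object@individualVectors) != length(sv) ||
      ncol(object@snpVectors) != length(sv))
    msgs <- c(msgs, "eigenvector matrices must have one column per component")
  if (length(msgs)) msgs else TRUE
})

#' AmmiFit: additive main effects and multiplicative interaction model
#'
#' Grand mean plus Individual and SNP main effects, with the
#' SNP-by-Individual interaction decomposed by DC-PCA. The interaction
#' component is identical to [snpPca()] with the double-centered variant, so
#' AMMI and DC-PCA share one ANOVA table; AMMI simply retains the main
#' effects that DC-PCA discards.
#'
#' @slot grandMean numeric(1).
#' @slot individualMeans,snpMeans per-axis means.
#' @slot interaction a [SnpPca-class] of the double-centered matrix.
#' @seealso [fitAmmi()], [ammi1Coordinates()]
#' @export
setClass("AmmiFit",
  representation(grandMean = "numeric", individualMeans = "numeric",
                 snpMeans = "numeric", interaction = "SnpPca"))

#' GenotypeCa: correspondence analysis of a genotype matrix
#'
#' Nontrivial singular values (at most 1, descending) and standard
#' coordinates for the first \code{k} axes of correspondence analysis
#' (reciprocal averaging) of a nonnegative matrix, computed from the
#' standardized residuals of the independence model so that the trivial
#' margin axis is excluded by construction.
#'
#' @slot singularValues numeric(k) in (0, 1].
#' @slot individualCoords R x k row standard coordinates.
#' @slot snpCoords C x k column standard coordinates.
#' @slot method \code{"svd"} or \code{"power"}.
#' @seealso [caDecompose()], [arrangeByCa1()]
#' @export
setClass("GenotypeCa",
  representation(singularValues = "numeric", individualCoords = "matrix",
                 snpCoords = "matrix", method = "character"))

setValidity("GenotypeCa", function(object) {
  sv <- object@singularValues
  if (length(sv) && any(sv > 1 + 1e-8))
    return("CA singular values cannot exceed 1")
  if (length(sv) && any(diff(sv) > 1e-8))
    return("singular values must be descending")
  TRUE
})

#' ArrangedGenotypes: a CA1-arranged genotype matrix
#'
#' A genotype matrix together with row and column permutations obtained by
#' ranking first-axis correspondence-analysis scores, which concentrates
#' large values along the matrix diagonal when the data are structured by a
#' single dominant gradient, plus a diagonal-concentration statistic in
#' [-1, 1].
#'
#' @slot source the [GenotypeMatrix-class] that was arranged.
#' @slot individualOrder,snpOrder integer permutations (display order).
#' @slot concentration numeric(1) diagonal-concentration statistic.
#' @seealso [arrangeByCa1()], [diagonalConcentration()]
#' @export
setClass("ArrangedGenotypes",
  representation(source = "GenotypeMatrix", individualOrder = "integer",
                 snpOrder = "integer", concentration = "numeric"))

setValidity("ArrangedGenotypes", function(object) {
  msgs <- character(0)
  if (!setequal(object@individualOrder, seq_len(nrow(object@source@values))))
    msgs <- c(msgs, "individualOrder is not a permutation of the rows")
  if (!setequal(object@snpOrder, seq_len(ncol(object@source@values))))
    msgs <- c(msgs, "snpOrder is not a permutation of the columns")
  if (length(msgs)) msgs else TRUE
})

#' BiplotSpec: a device-independent biplot description
#'
#' Point coordinates for both panels of a biplot (Individuals and SNPs),
#' axis labels carrying the percent of source SS captured, the
#' equal-axis-scale contract, and reference lines (the origin crosshair for
#' component-vs-component plots, the grand-mean vertical for AMMI1).
#'
#' @slot points data.frame with columns id, panel, x, y, group.
#' @slot xlab,ylab axis labels.
#' @slot equalScale logical(1): must both axes use the same data-units-per-
#'   length scale when rendered?
#' @slot layout \code{"single_panel"} or \code{"two_panel"}.
#' @slot refLines data.frame with columns axis ("h"/"v") and value.
#' @slot palette named character vector mapping group to color.
#' @seealso [buildBiplot()], [plotBiplot()]
#' @export
setClass("BiplotSpec",
  representation(points = "data.frame", xlab = "character",
                 ylab = "character", equalScale = "logical",
                 layout = "character", refLines = "data.frame",
                 palette = "character"))
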