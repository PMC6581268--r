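#' Genotype values
#'
#' Accessors for the central classes. \code{genotypeValues} returns the raw
#' integer matrix, \code{individualIds}/\code{snpIds} the axis identifiers,
#' \code{coding} the polarity tag and \code{ploidyMode} the value-set mode.
#'
#' @param x a snppca object.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypeValues", function(x) standardGeneric("genotypeValues"))

#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("coding", function(x) standardGeneric("coding"))

#' @rdname accessors
#' @export
setGeneric("coding<-", function(x, value) standardGeneric("coding<-"))

#' @rdname accessors
#' @export
setGeneric("ploidyMode", function(x) standardGeneric("ploidyMode"))

#' Component scores
#'
#' Extract scaled component scores from a decomposition. The default
#' \code{"symmetric_sqrt"} scaling multiplies the unit eigenvectors of both
#' axes by \code{sqrt(lambda)}, so products of an Individual score and a SNP
#' score estimate interactions directly. \code{"axis_principal"} multiplies
#' the requested axis by \code{lambda} (distance-preserving for a monoplot
#' of that axis) and leaves the other axis as unit eigenvectors.
#'
#' @param x a [SnpPca-class] (or [AmmiFit-class], which delegates to its
#'   interaction decomposition).
#' @param axis \code{"individuals"} or \code{"snps"}.
#' @param scaling \code{"symmetric_sqrt"} (default) or \code{"axis_principal"}.
#' @param ... passed on to methods.
#' @return numeric matrix, items x components.
#' @export
setGeneric("scores",
  function(x, axis = c("individuals", "snps"),
           scaling = c("symmetric_sqrt", "axis_principal"), ...)
    standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))
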