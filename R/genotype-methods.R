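#' @rdname accessors
#' @export
setMethod("genotypeValues", "GenotypeMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("coding", "GenotypeMatrix", function(x) x@coding)

#' @rdname accessors
#' @export
setReplaceMethod("coding", "GenotypeMatrix", function(x, value) {
  x@coding <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("ploidyMode", "GenotypeMatrix", function(x) x@ploidyMode)

#' @describeIn GenotypeMatrix dimensions (Individuals, SNPs).
#' @param x a GenotypeMatrix.
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@values))

#' @describeIn GenotypeMatrix dimnames (Individual ids, SNP ids).
#' @export
setMethod("dimnames", "GenotypeMatrix", function(x) dimnames(x@values))

#' @describeIn GenotypeMatrix subset Individuals (i) and SNPs (j); drops
#'   the coding tag to "unknown" when subsetting SNPs of a vcf-coded matrix
#'   whose reference Individual is removed.
#' @param i,j,drop row/column index and ignored drop flag.
#' @param ... unused.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  cod <- x@coding
  if (grepl("^vcf:", cod) && !sub("^vcf:", "", cod) %in% rownames(v))
    cod <- "unknown"
  new("GenotypeMatrix", values = v, coding = cod, ploidyMode = x@ploidyMode)
})

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("GenotypeMatrix: %d Individuals x %d SNPs\n", d[1L], d[2L]))
  cat(sprintf("  coding: %s | ploidy mode: %s\n",
              object@coding, object@ploidyMode))
  cat(sprintf("  grand mean: %.5f\n", mean(object@values)))
})

setMethod("show", "TransformedGenotypes", function(object) {
  d <- dim(object@values)
  cat(sprintf("TransformedGenotypes (%s): %d x %d\n",
              object@variant, d[1L], d[2L]))
  cat(sprintf("  total SS: %.3f\n", sum(object@values^2)))
})

setMethod("show", "SnpPca", function(object) {
  k <- length(object@singularValues)
  cat(sprintf("SnpPca (%s): %d components retained\n", object@variant, k))
  pct <- 100 * object@componentSS / object@totalSS
  lab <- if (object@variant == "double_centered") "IPC" else "PC"
  for (n in seq_len(min(k, 5L)))
    cat(sprintf("  %s%d: SS %.3f (%.1f%%), df %d\n", lab, n,
                object@componentSS[n], pct[n], object@componentDf[n]))
  if (k > 5L) cat(sprintf("  ... %d more\n", k - 5L))
  cat(sprintf("  residual SS %.3f, df %d\n",
              object@residualSS, object@residualDf))
})

setMethod("show", "AmmiFit", function(object) {
  cat(sprintf("AmmiFit: grand mean %.5f\n", object@grandMean))
  cat(sprintf("  Individual means in [%.5f, %.5f]\n",
              min(object@individualMeans), max(object@individualMeans)))
  cat(sprintf("  SNP means in [%.5f, %.5f]\n",
              min(object@snpMeans), max(object@snpMeans)))
  cat(sprintf("  interaction: %d IPCs retained\n",
              length(object@interaction@singularValues)))
})

setMethod("show", "GenotypeCa", function(object) {
  cat(sprintf("GenotypeCa (%s): %d nontrivial axes\n", object@method,
              length(object@singularValues)))
  cat("  singular values:",
      paste(sprintf("%.5f", object@singularValues), collapse = " "), "\n")
})

setMethod("show", "ArrangedGenotypes", function(object) {
  d <- dim(object@source@values)
  cat(sprintf("ArrangedGenotypes: %d x %d, diagonal concentration %.4f\n",
              d[1L], d[2L], object@concentration))
})

#' @rdname accessors
#' @export
setMethod("singularValues", "SnpPca", function(x) x@singularValues)

#' @rdname accessors
#' @export
setMethod("singularValues", "GenotypeCa", function(x) x@singularValues)

#' Arranged genotype values
#'
#' The genotype matrix of an [ArrangedGenotypes-class] with its rows and
#' columns permuted into CA1 display order.
#'
#' @param x an ArrangedGenotypes object.
#' @return integer matrix in display order.
#' @export
arrangedValues <- function(x) {
  stopifnot(is(x, "ArrangedGenotypes"))
  x@source@values[x@individualOrder, x@snpOrder, drop = FALSE]
}
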