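#' Fit the AMMI model
#'
#' Additive Main effects and Multiplicative Interaction: the grand mean and
#' both sets of main effects are retained additively, and the
#' SNP-by-Individual interaction matrix (the double-centered data) is
#' decomposed by PCA. The interaction decomposition is identical to DC-PCA
#' of the same matrix, so AMMI and DC-PCA share one ANOVA table; the
#' difference is only that AMMI keeps the main effects that DC-PCA
#' discards.
#'
#' @param x a [GenotypeMatrix-class] or numeric matrix.
#' @param k number of interaction components to retain (default 2).
#' @return An [AmmiFit-class].
#' @examples
#' gm <- GenotypeMatrix(matrix(c(1, 0, 0, 1), 2,
#'                      dimnames = list(c("a", "b"), c("s1", "s2"))))
#' fit <- fitAmmi(gm, k = 1)
#' ammi1Coordinates(fit)$individuals
#' @export
fitAmmi <- function(x, k = 2L) {
  v <- .valuesOf(x)
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("AMMI needs at least a 2 x 2 layout")
  res <- snpPca(v, "double_centered", k = k)
  new("AmmiFit", grandMean = mean(v), individualMeans = rowMeans(v),
      snpMeans = colMeans(v), interaction = res)
}

#' Fitted values of an AMMI model
#'
#' \code{mu + (mu_r - mu) + (mu_c - mu) + sum_{n<=k} lambda_n gamma_rn
#' delta_cn}: the additive main effects plus the rank-k interaction
#' estimate.
#'
#' @param object an [AmmiFit-class].
#' @param k number of interaction components to use (default all retained).
#' @param ... unused.
#' @return numeric matrix of fitted values.
#' @export
setMethod("fitted", "AmmiFit", function(object, k = NULL, ...) {
  if (is.null(k)) k <- length(object@interaction@singularValues)
  add <- outer(object@individualMeans, object@snpMeans, function(r, c)
    r + c) - object@grandMean
  add + reconstructComponents(object@interaction, k)
})

#' AMMI1 biplot coordinates
#'
#' The AMMI1 biplot shows the main effects on its abscissa and IPC1 on its
#' ordinate. Individuals are plotted at (their mean frequency of the allele
#' coded 1, their IPC1 score); SNPs likewise; a vertical reference line sits
#' at the grand mean. The abscissa captures 100 percent of both main
#' effects and none of the interaction; the ordinate captures the largest
#' possible share of the S-by-I interaction SS (IPC1 is the least-squares
#' rank-1 solution). An Individual and a SNP whose IPC1 scores share a sign
#' interact positively. The two axes carry different kinds of information
#' and are exempt from the equal-scale rule.
#'
#' @param model an [AmmiFit-class] with at least one retained component.
#' @param abscissa \code{"means"} (default, matching the mean-frequency
#'   axis) or \code{"deviations"} (main effects as deviations from the
#'   grand mean).
#' @return list with data.frames \code{individuals} and \code{snps}
#'   (columns id, abscissa, ordinate), \code{grandMean} (reference line
#'   position; 0 for deviations), and \code{ordinatePctSxI} (percent of
#'   interaction SS captured by IPC1).
#' @export
ammi1Coordinates <- function(model, abscissa = c("means", "deviations")) {
  stopifnot(is(model, "AmmiFit"))
  abscissa <- match.arg(abscissa)
  res <- model@interaction
  if (length(res@singularValues) < 1L)
    stop("AMMI1 needs at least one retained interaction component")
  indScore <- scores(res, "individuals")[, 1L]
  snpScore <- scores(res, "snps")[, 1L]
  shiftR <- if (abscissa == "means") 0 else model@grandMean
  list(
    individuals = data.frame(id = names(model@individualMeans),
                             abscissa = unname(model@individualMeans) - shiftR,
                             ordinate = unname(indScore),
                             stringsAsFactors = FALSE),
    snps = data.frame(id = names(model@snpMeans),
                      abscissa = unname(model@snpMeans) - shiftR,
                      ordinate = unname(snpScore),
                      stringsAsFactors = FALSE),
    grandMean = if (abscissa == "means") model@grandMean else 0,
    ordinatePctSxI = 100 * res@componentSS[1L] / res@totalSS)
}
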