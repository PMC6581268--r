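#' The six PCA variant tags
#'
#' The variants differ only in the transform applied before SVD:
#' \code{snp_centered} removes per-SNP (column) means; \code{individual_centered}
#' removes per-Individual (row) means; \code{double_centered} removes both and
#' restores the grand mean, leaving the pure SNP-by-Individual interaction
#' (DC-PCA, the recommended default); \code{snp_standardized} and
#' \code{individual_standardized} additionally scale the centered axis to unit
#' variance (n-1 denominator); \code{grand_mean_centered} subtracts only the
#' grand mean.
#'
#' @return character vector of the six variant tags.
#' @export
pcaVariants <- function() {
  c("snp_centered", "individual_centered", "double_centered",
    "snp_standardized", "individual_standardized", "grand_mean_centered")
}

.checkVariant <- function(variant) {
  if (!variant %in% pcaVariants())
    stop("unknown PCA variant: ", variant, "; see pcaVariants()")
  variant
}

#' Apply a centering/standardization transform
#'
#' Produces the matrix that a given PCA variant decomposes, retaining the
#' source means (and standard deviations, for standardized variants) for
#' reconstruction and AMMI.
#'
#' @param x a [GenotypeMatrix-class] or numeric matrix.
#' @param variant one of [pcaVariants()].
#' @return A [TransformedGenotypes-class].
#' @examples
#' gm <- GenotypeMatrix(diag(2))
#' transformGenotypes(gm, "double_centered")
#' @export
transformGenotypes <- function(x, variant = "double_centered") {
  .checkVariant(variant)
  v <- if (is(x, "GenotypeMatrix")) x@values else as.matrix(x)
  storage.mode(v) <- "double"
  mu <- mean(v)
  rm_ <- rowMeans(v)
  cm_ <- colMeans(v)
  rsd <- numeric(0)
  csd <- numeric(0)
  tv <- switch(variant,
    snp_centered = sweep(v, 2L, cm_),
    individual_centered = sweep(v, 1L, rm_),
    double_centered = v - outer(rm_, rep(1, ncol(v))) -
      outer(rep(1, nrow(v)), cm_) + mu,
    grand_mean_centered = v - mu,
    snp_standardized = {
      ctr <- sweep(v, 2L, cm_)
      csd <- apply(v, 2L, stats::sd)
      if (any(csd == 0)) {
        bad <- colnames(v)[csd == 0]
        stop("zero-variance SNP(s) cannot be standardized: ",
             paste(utils::head(bad, 5L), collapse = ", "))
      }
      sweep(ctr, 2L, csd, "/")
    },
    individual_standardized = {
      ctr <- sweep(v, 1L, rm_)
      rsd <- apply(v, 1L, stats::sd)
      if (any(rsd == 0)) {
        bad <- rownames(v)[rsd == 0]
        stop("zero-variance Individual(s) cannot be standardized: ",
             paste(utils::head(bad, 5L), collapse = ", "))
      }
      sweep(ctr, 1L, rsd, "/")
    })
  new("TransformedGenotypes", values = tv, variant = variant,
      grandMean = mu, individualMeans = rm_, snpMeans = cm_,
      individualSds = rsd, snpSds = csd)
}

#' Gollob degrees of freedom for multiplicative components
#'
#' Degrees of freedom assigned to the k-th multiplicative term of a two-way
#' decomposition with p SNPs and n Individuals: \code{p + n - 1 - 2k} after
#' double centering, \code{p + n - 2k} after single centering or
#' standardization, and \code{p + n + 1 - 2k} after grand-mean centering.
#'
#' @param p number of SNPs.
#' @param n number of Individuals.
#' @param k component index (1-based).
#' @param variant one of [pcaVariants()].
#' @return integer df.
#' @examples
#' componentDf(1341, 635, 1, "double_centered")  # 1973
#' @export
componentDf <- function(p, n, k, variant = "double_centered") {
  .checkVariant(variant)
  stopifnot(k >= 1)
  adj <- switch(variant,
    double_centered = -1L,
    grand_mean_centered = 1L,
    0L)
  df <- p + n + adj - 2L * k
  if (any(df <= 0))
    stop("component index too large: nonpositive degrees of freedom")
  as.integer(df)
}

# rank bound of the transformed matrix: each centered axis loses one
.rankBound <- function(R, C, variant) {
  switch(variant,
    double_centered = min(R - 1L, C - 1L),
    snp_centered = ,
    snp_standardized = min(R - 1L, C),
    individual_centered = ,
    individual_standardized = min(R, C - 1L),
    grand_mean_centered = min(R, C))
}

# joint sign convention: largest-magnitude SNP eigenvector entry positive
.alignSigns <- function(u, v) {
  for (n in seq_len(ncol(v))) {
    j <- which.max(abs(v[, n]))
    if (v[j, n] < 0) {
      v[, n] <- -v[, n]
      u[, n] <- -u[, n]
    }
  }
  list(u = u, v = v)
}

# source df of the decomposed transform (what the component dfs partition)
.sourceDf <- function(R, C, variant) {
  switch(variant,
    double_centered = (R - 1L) * (C - 1L),
    snp_centered = ,
    snp_standardized = (R - 1L) * C,
    individual_centered = ,
    individual_standardized = R * (C - 1L),
    grand_mean_centered = R * C - 1L)
}

#' Decompose a transformed genotype matrix by SVD
#'
#' Runs the singular value decomposition of the transform a PCA variant
#' prescribes and packages the top \code{k} components with their sums of
#' squares (squared singular values), Gollob degrees of freedom, and the
#' residual closing the source. The sign of each component is fixed by
#' making the largest-magnitude SNP eigenvector entry positive (polarity is
#' mathematically arbitrary; a fixed convention keeps figures comparable).
#'
#' @param x a [GenotypeMatrix-class], numeric matrix, or
#'   [TransformedGenotypes-class].
#' @param variant one of [pcaVariants()]; ignored when \code{x} is already
#'   transformed.
#' @param k number of components to retain (default 2; capped at the rank
#'   bound of the transform).
#' @return A [SnpPca-class].
#' @examples
#' gm <- GenotypeMatrix(matrix(c(1, 0, 0, 1), 2,
#'                      dimnames = list(c("a", "b"), c("s1", "s2"))))
#' res <- snpPca(gm, "double_centered", k = 1)
#' singularValues(res)       # 1
#' scores(res, "individuals")
#' @export
snpPca <- function(x, variant = "double_centered", k = 2L) {
  if (is(x, "TransformedGenotypes")) {
    tm <- x
    variant <- tm@variant
  } else {
    .checkVariant(variant)
    tm <- transformGenotypes(x, variant)
  }
  v <- tm@values
  R <- nrow(v); C <- ncol(v)
  bound <- .rankBound(R, C, variant)
  if (k > bound)
    stop(sprintf("k = %d exceeds the rank bound %d for variant %s",
                 k, bound, variant))
  componentDf(C, R, k, variant)  # errors if df would be nonpositive
  dec <- svd(v, nu = k, nv = k)
  sv <- dec$d[seq_len(k)]
  al <- .alignSigns(dec$u, dec$v)
  u <- al$u; w <- al$v
  rownames(u) <- rownames(v); rownames(w) <- colnames(v)
  compName <- if (variant == "double_centered") "IPC" else "PC"
  colnames(u) <- colnames(w) <- paste0(compName, seq_len(k))
  totalSS <- sum(v^2)
  compSS <- sv^2
  compDf <- componentDf(C, R, seq_len(k), variant)
  srcDf <- .sourceDf(R, C, variant)
  new("SnpPca", variant = variant, singularValues = sv,
      individualVectors = u, snpVectors = w,
      componentSS = compSS, componentDf = as.numeric(compDf),
      residualSS = totalSS - sum(compSS),
      residualDf = srcDf - sum(compDf),
      totalSS = totalSS, grandMean = tm@grandMean,
      individualMeans = tm@individualMeans, snpMeans = tm@snpMeans)
}

#' @rdname scores
#' @export
setMethod("scores", "SnpPca",
  function(x, axis = c("individuals", "snps"),
           scaling = c("symmetric_sqrt", "axis_principal"), ...) {
    axis <- match.arg(axis)
    scaling <- match.arg(scaling)
    vec <- if (axis == "individuals") x@individualVectors else x@snpVectors
    mult <- switch(scaling,
      symmetric_sqrt = sqrt(x@singularValues),
      axis_principal = x@singularValues)
    sweep(vec, 2L, mult, "*")
  })

#' @rdname scores
#' @export
setMethod("scores", "AmmiFit",
  function(x, axis = c("individuals", "snps"),
           scaling = c("symmetric_sqrt", "axis_principal"), ...) {
    scores(x@interaction, axis = axis, scaling = scaling, ...)
  })

#' Reconstruct expected values from retained components
#'
#' Returns \code{sum_{n<=k} lambda_n gamma_n delta_n'}, the rank-k matrix of
#' expected values of the decomposed transform. At the full rank bound this
#' reproduces the transformed matrix to machine precision; \code{k = 0}
#' gives the zero matrix.
#'
#' @param res a [SnpPca-class].
#' @param k number of components to use (default all retained).
#' @return numeric matrix, Individuals x SNPs.
#' @export
reconstructComponents <- function(res, k = length(res@singularValues)) {
  stopifnot(is(res, "SnpPca"))
  if (k > length(res@singularValues))
    stop("k exceeds the number of retained components")
  out <- matrix(0, nrow(res@individualVectors), nrow(res@snpVectors),
                dimnames = list(rownames(res@individualVectors),
                                rownames(res@snpVectors)))
  for (n in seq_len(k))
    out <- out + res@singularValues[n] *
      tcrossprod(res@individualVectors[, n], res@snpVectors[, n])
  out
}
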