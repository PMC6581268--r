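.valuesOf <- function(x) {
  if (is(x, "GenotypeMatrix")) {
    v <- x@values
    storage.mode(v) <- "double"
    v
  } else if (is(x, "TransformedGenotypes")) x@values
  else as.matrix(x)
}

# orthogonal decomposition about the grand mean
.threeSourceSS <- function(v) {
  R <- nrow(v); C <- ncol(v)
  mu <- mean(v)
  rm_ <- rowMeans(v); cm_ <- colMeans(v)
  ssS <- R * sum((cm_ - mu)^2)
  ssI <- C * sum((rm_ - mu)^2)
  tot <- sum((v - mu)^2)
  list(total = tot, snps = ssS, individuals = ssI,
       sxi = tot - ssS - ssI, grand = mu)
}

.anovaTable <- function(source, df, ss, level) {
  out <- data.frame(source = source, df = df, ss = ss,
                    stringsAsFactors = FALSE)
  attr(out, "level") <- level
  class(out) <- c("snppcaAnova", "data.frame")
  out
}

#' Three-source ANOVA of a genotype matrix
#'
#' Partitions the corrected total sum of squares of a two-way
#' SNPs-by-Individuals layout into the three orthogonal sources: SNP main
#' effects (df C-1), Individual main effects (df R-1), and SNP-by-Individual
#' interaction (df (R-1)(C-1)). These sources are uncorrelated, so knowing
#' one gives no information on the others.
#'
#' @param x a [GenotypeMatrix-class] or numeric matrix.
#' @return data.frame of class \code{"snppcaAnova"} with rows Total, SNPs,
#'   Individuals, SxI and columns source, df, ss.
#' @examples
#' threeSourceAnova(matrix(c(1, 0, 0, 1), 2))
#' @export
threeSourceAnova <- function(x) {
  v <- .valuesOf(x)
  R <- nrow(v); C <- ncol(v)
  if (R < 2L || C < 2L)
    stop("three-source ANOVA needs at least a 2 x 2 layout")
  p <- .threeSourceSS(v)
  .anovaTable(
    source = c("Total", "SNPs", "Individuals", "SxI"),
    df = c(R * C - 1, C - 1, R - 1, (R - 1) * (C - 1)),
    ss = c(p$total, p$snps, p$individuals, p$sxi),
    level = c(0L, 1L, 1L, 1L))
}

#' ANOVA table for DC-PCA
#'
#' The three-source table with the S-by-I interaction further partitioned
#' into the first \code{k} interaction principal components (SS equal to the
#' squared singular values of the double-centered matrix, Gollob df
#' \code{p + n - 1 - 2k}) followed by the residual that closes the S-by-I
#' subtotal. AMMI shares this table exactly.
#'
#' @param x a [GenotypeMatrix-class] or numeric matrix.
#' @param k number of IPCs to list (default 7; capped at the rank bound).
#' @return data.frame of class \code{"snppcaAnova"}.
#' @export
dcPcaAnova <- function(x, k = 7L) {
  v <- .valuesOf(x)
  R <- nrow(v); C <- ncol(v)
  k <- as.integer(min(k, .rankBound(R, C, "double_centered")))
  base <- threeSourceAnova(v)
  res <- snpPca(v, "double_centered", k = k)
  .anovaTable(
    source = c(base$source, paste0("IPC", seq_len(k)), "Residual"),
    df = c(base$df, res@componentDf, res@residualDf),
    ss = c(base$ss, res@componentSS, res@residualSS),
    level = c(attr(base, "level"), rep(2L, k), 2L))
}

# which portion columns a variant's augmented table carries
.portionSources <- function(variant) {
  switch(variant,
    snp_centered = ,
    snp_standardized = c("Individuals", "SxI"),
    individual_centered = ,
    individual_standardized = c("SNPs", "SxI"),
    grand_mean_centered = c("SNPs", "Individuals", "SxI"),
    character(0))
}

# portion split of one matrix (a rank-1 component or the residual) into the
# sources a variant retains; portions sum exactly to sum(m^2)
.portionSplit <- function(m, sources) {
  gm <- mean(m)
  ssS <- nrow(m) * sum((colMeans(m) - gm)^2)
  ssI <- ncol(m) * sum((rowMeans(m) - gm)^2)
  tot <- sum(m^2)
  out <- numeric(length(sources))
  names(out) <- sources
  if ("SNPs" %in% sources) out["SNPs"] <- ssS
  if ("Individuals" %in% sources) out["Individuals"] <- ssI
  out["SxI"] <- tot - sum(out[names(out) != "SxI"])
  out
}

#' Augmented ANOVA table for a PCA variant
#'
#' For PCA variants other than DC-PCA, each principal component mixes main
#' and interaction effects. The augmented table quantifies that mixture: for
#' each PC the rank-1 matrix of expected values (the outer product of its
#' Individual and SNP score vectors) is itself subjected to ANOVA, and the
#' PC's SS is split into the portions due to the main effects the variant
#' retains and to S-by-I interaction. The residual matrix (source minus all
#' retained rank-1 matrices) is partitioned the same way, so for the singly
#' centered and standardized variants the portion columns sum exactly to the
#' source SS by the orthogonality of the singular vectors. For the
#' grand-mean-centered variant the SxI portion also absorbs each component's
#' (analytically small) grand-mean term, so column closure there is
#' approximate. Portion columns of components need not decrease
#' monotonically even though the component SSs do.
#'
#' For \code{variant = "double_centered"} the plain [dcPcaAnova()] table is
#' returned: DC-PCA components contain pure interaction, so there is nothing
#' to augment. Standardized variants report the decomposition rows in
#' standardized units (their own consistent scale).
#'
#' @param x a [GenotypeMatrix-class] or numeric matrix.
#' @param variant one of [pcaVariants()].
#' @param k number of components to list (default 7; capped at rank bound).
#' @return data.frame of class \code{c("snppcaAugmentedAnova",
#'   "snppcaAnova")} with portion columns after \code{ss}.
#' @export
augmentedAnova <- function(x, variant, k = 7L) {
  .checkVariant(variant)
  if (variant == "double_centered")
    return(dcPcaAnova(x, k))
  v <- .valuesOf(x)
  R <- nrow(v); C <- ncol(v)
  k <- as.integer(min(k, .rankBound(R, C, variant)))
  sources <- .portionSources(variant)
  tm <- transformGenotypes(v, variant)
  res <- snpPca(tm, k = k)
  raw <- .threeSourceSS(v)

  compName <- if (variant == "double_centered") "IPC" else "PC"
  portions <- matrix(0, nrow = k + 1L, ncol = length(sources),
                     dimnames = list(NULL, sources))
  approx <- matrix(0, R, C)
  for (n in seq_len(k)) {
    mn <- res@singularValues[n] *
      tcrossprod(res@individualVectors[, n], res@snpVectors[, n])
    portions[n, ] <- .portionSplit(mn, sources)
    approx <- approx + mn
  }
  portions[k + 1L, ] <- .portionSplit(tm@values - approx, sources)

  combinedName <- switch(variant,
    snp_centered = , snp_standardized = "I&SxI",
    individual_centered = , individual_standardized = "S&SxI",
    grand_mean_centered = "All")
  srcDf <- .sourceDf(R, C, variant)
  compDf <- res@componentDf

  if (variant %in% c("snp_centered", "individual_centered")) {
    removedName <- if (variant == "snp_centered") "SNPs" else "Individuals"
    removedDf <- if (variant == "snp_centered") C - 1L else R - 1L
    removedSS <- if (variant == "snp_centered") raw$snps else raw$individuals
    combinedSS <- raw$total - removedSS
    src <- c("Total", removedName, combinedName,
             paste0(compName, seq_len(k)), "Residual")
    df <- c(R * C - 1, removedDf, srcDf, compDf, srcDf - sum(compDf))
    ss <- c(raw$total, removedSS, combinedSS, res@componentSS, res@residualSS)
    lev <- c(0L, 1L, 1L, rep(2L, k), 2L)
    srcPortion <- rbind(NA, NA,
      .portionSplit(tm@values, sources))
    port <- rbind(srcPortion, portions)
  } else if (variant == "grand_mean_centered") {
    src <- c("Total", paste0(compName, seq_len(k)), "Residual")
    df <- c(srcDf, compDf, srcDf - sum(compDf))
    ss <- c(res@totalSS, res@componentSS, res@residualSS)
    lev <- c(0L, rep(1L, k), 1L)
    port <- rbind(.portionSplit(tm@values, sources), portions)
  } else {
    # standardized variants: decomposition in standardized units
    src <- c(combinedName, paste0(compName, seq_len(k)), "Residual")
    df <- c(srcDf, compDf, srcDf - sum(compDf))
    ss <- c(res@totalSS, res@componentSS, res@residualSS)
    lev <- c(0L, rep(1L, k), 1L)
    port <- rbind(.portionSplit(tm@values, sources), portions)
  }

  out <- .anovaTable(src, df, ss, lev)
  for (s in sources) out[[s]] <- port[, s]
  attr(out, "variant") <- variant
  attr(out, "k") <- k
  attr(out, "portionSources") <- sources
  class(out) <- c("snppcaAugmentedAnova", class(out))
  out
}

#' Classify what kind of information each PC carries
#'
#' Labels each component of an augmented ANOVA table as
#' \code{"main_dominated"}, \code{"interaction_dominated"}, or
#' \code{"mixed"}. A component is mixed when its minority portion exceeds
#' \code{mixedThreshold} of the component SS (default 0.2; a PC that is,
#' say, 31 percent main effects and 69 percent interaction is mixed).
#'
#' @param aug result of [augmentedAnova()].
#' @param mixedThreshold minority-share cutoff in (0, 0.5).
#' @return data.frame with columns component, mainShare, interactionShare,
#'   outcome.
#' @export
classifyPcOutcomes <- function(aug, mixedThreshold = 0.2) {
  stopifnot(inherits(aug, "snppcaAugmentedAnova"))
  sources <- attr(aug, "portionSources")
  mains <- setdiff(sources, "SxI")
  rows <- grepl("^I?PC[0-9]+$", aug$source)
  mainSS <- rowSums(aug[rows, mains, drop = FALSE])
  intSS <- aug[rows, "SxI"]
  tot <- mainSS + intSS
  mainShare <- mainSS / tot
  outcome <- ifelse(pmin(mainShare, 1 - mainShare) > mixedThreshold, "mixed",
             ifelse(mainShare > 0.5, "main_dominated",
                    "interaction_dominated"))
  data.frame(component = aug$source[rows], mainShare = mainShare,
             interactionShare = 1 - mainShare, outcome = outcome,
             stringsAsFactors = FALSE)
}

#' @export
print.snppcaAnova <- function(x, digits = 3, ...) {
  lev <- attr(x, "level")
  indent <- strrep("  ", lev)
  extra <- setdiff(names(x), c("source", "df", "ss"))
  hdr <- sprintf("%-24s %10s %14s", "Source", "df", "SS")
  if (length(extra))
    hdr <- paste0(hdr, paste(sprintf(" %14s", extra), collapse = ""))
  cat(hdr, "\n")
  for (i in seq_len(nrow(x))) {
    line <- sprintf("%-24s %10d %14.3f",
                    paste0(indent[i], x$source[i]), x$df[i], x$ss[i])
    for (s in extra)
      line <- paste0(line, if (is.na(x[[s]][i])) sprintf(" %14s", "")
                     else sprintf(" %14.3f", x[[s]][i]))
    cat(line, "\n")
  }
  invisible(x)
}

#' Export an ANOVA table
#'
#' Writes the table as TSV (full precision) or JSON.
#'
#' @param tab a \code{"snppcaAnova"} data.frame.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writeAnovaTable <- function(tab, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  else
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA)
  invisible(path)
}
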