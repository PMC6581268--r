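#' Build a biplot specification
#'
#' Assembles the device-independent description of a biplot: point
#' coordinates for both axes of the decomposition, axis labels carrying
#' each component's percent of the decomposed source SS, the origin
#' crosshair (for component-vs-component plots) or grand-mean vertical
#' (AMMI1), group colors, and the equal-axis-scale contract. Component
#' plots must be rendered with the same data-units-per-length scale on both
#' axes; AMMI1 axes carry different kinds of information and are exempt.
#'
#' @param result a [SnpPca-class] or [AmmiFit-class].
#' @param axes for a SnpPca: integer pair of component indices (default
#'   \code{c(1, 2)}). For an AmmiFit the AMMI1 axes (main effects vs IPC1)
#'   are implied.
#' @param individualGroups,snpGroups optional group assignments used to
#'   color the two panels.
#' @param palette optional named color vector; defaults from
#'   [groupPalette()].
#' @param layout \code{"auto"} (two panels above 2000 points, single panel
#'   with distinct markers otherwise), \code{"single_panel"}, or
#'   \code{"two_panel"}.
#' @return A [BiplotSpec-class].
#' @export
buildBiplot <- function(result, axes = c(1L, 2L), individualGroups = NULL,
                        snpGroups = NULL, palette = NULL,
                        layout = c("auto", "single_panel", "two_panel")) {
  layout <- match.arg(layout)
  if (is(result, "AmmiFit")) {
    co <- ammi1Coordinates(result)
    pts <- rbind(
      data.frame(co$individuals, panel = "individuals",
                 stringsAsFactors = FALSE),
      data.frame(co$snps, panel = "snps", stringsAsFactors = FALSE))
    names(pts)[names(pts) == "abscissa"] <- "x"
    names(pts)[names(pts) == "ordinate"] <- "y"
    xlab <- "Main effects (mean frequency of allele 1)"
    ylab <- sprintf("IPC1 (%.1f%% of SxI)", co$ordinatePctSxI)
    refLines <- data.frame(axis = c("v", "h"),
                           value = c(co$grandMean, 0),
                           stringsAsFactors = FALSE)
    equalScale <- FALSE
  } else if (is(result, "SnpPca")) {
    stopifnot(length(axes) == 2L)
    if (max(axes) > length(result@singularValues))
      stop("requested components are not retained in the decomposition")
    si <- scores(result, "individuals")
    ss <- scores(result, "snps")
    pts <- rbind(
      data.frame(id = rownames(si), x = si[, axes[1L]], y = si[, axes[2L]],
                 panel = "individuals", stringsAsFactors = FALSE),
      data.frame(id = rownames(ss), x = ss[, axes[1L]], y = ss[, axes[2L]],
                 panel = "snps", stringsAsFactors = FALSE))
    pct <- 100 * result@componentSS / result@totalSS
    nm <- colnames(result@individualVectors)
    src <- if (result@variant == "double_centered") "SxI" else "source"
    xlab <- sprintf("%s (%.1f%% of %s)", nm[axes[1L]], pct[axes[1L]], src)
    ylab <- sprintf("%s (%.1f%% of %s)", nm[axes[2L]], pct[axes[2L]], src)
    refLines <- data.frame(axis = c("v", "h"), value = c(0, 0),
                           stringsAsFactors = FALSE)
    equalScale <- TRUE
  } else stop("result must be a SnpPca or AmmiFit")
  rownames(pts) <- NULL

  pts$group <- "all"
  for (ga in list(individualGroups, snpGroups)) {
    if (is.null(ga)) next
    ax <- attr(ga, "axis")
    m <- match(pts$id[pts$panel == ax], ga$id)
    if (anyNA(m))
      stop("group assignment does not cover the ", ax, " axis")
    pts$group[pts$panel == ax] <- ga$label[m]
  }
  if (is.null(palette))
    palette <- groupPalette(sort(unique(pts$group)), "expert")
  if (layout == "auto")
    layout <- if (nrow(pts) > 2000L) "two_panel" else "single_panel"
  new("BiplotSpec", points = pts, xlab = xlab, ylab = ylab,
      equalScale = equalScale, layout = layout, refLines = refLines,
      palette = palette)
}

#' Audit the axis-scale ratio of a rendered PCA graph
#'
#' PCA component axes must share one scale: the ratio of the larger to the
#' smaller data-units-per-length scale should be 1. The audit classifies a
#' rendering as \code{"correct"} (ratio at most 1.01), \code{"slight"}
#' (at most 1.1), \code{"faulty"} (at most 2), or \code{"substantial"}
#' (above 2).
#'
#' @param xExtent,yExtent data-unit extents of the two axes.
#' @param xLength,yLength rendered physical lengths (any common unit).
#' @return list with \code{ratio} and \code{class}.
#' @examples
#' axisScaleRatio(4, 4, 10, 4)$class  # ordinate stretched 2.5x
#' @export
axisScaleRatio <- function(xExtent, yExtent, xLength, yLength) {
  if (xExtent <= 0 || yExtent <= 0 || xLength <= 0 || yLength <= 0)
    stop("axis extents and lengths must be positive")
  sx <- xExtent / xLength
  sy <- yExtent / yLength
  ratio <- max(sx, sy) / min(sx, sy)
  cls <- if (ratio <= 1.01) "correct" else if (ratio <= 1.1) "slight"
    else if (ratio <= 2) "faulty" else "substantial"
  list(ratio = ratio, class = cls)
}

#' Render a biplot specification
#'
#' Draws the biplot with base graphics. Component-vs-component plots are
#' drawn with \code{asp = 1} to honor the equal-scale contract; AMMI1 axes
#' scale independently. Only ids listed in \code{labelIds} are labeled.
#'
#' @param spec a [BiplotSpec-class].
#' @param file optional output path (".svg" or ".png"); plots to the
#'   current device when NULL.
#' @param labelIds ids to annotate (default none).
#' @param cex point expansion (default 0.6).
#' @return \code{spec}, invisibly.
#' @export
plotBiplot <- function(spec, file = NULL, labelIds = character(0),
                       cex = 0.6) {
  stopifnot(is(spec, "BiplotSpec"))
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 10, height = 5)
    else grDevices::png(file, width = 1200, height = 600, res = 120)
    on.exit(grDevices::dev.off())
  }
  panels <- if (spec@layout == "two_panel")
    list("individuals", "snps") else list(c("individuals", "snps"))
  oldPar <- graphics::par(mfrow = c(1L, length(panels)))
  on.exit(graphics::par(oldPar), add = TRUE)
  asp <- if (spec@equalScale) 1 else NA
  for (panel in panels) {
    pts <- spec@points[spec@points$panel %in% panel, ]
    col <- spec@palette[pts$group]
    col[is.na(col)] <- "grey40"
    pch <- ifelse(pts$panel == "individuals", 17L, 16L)
    graphics::plot(pts$x, pts$y, col = col, pch = pch, cex = cex, asp = asp,
                   xlab = spec@xlab, ylab = spec@ylab,
                   main = paste(panel, collapse = " + "))
    for (i in seq_len(nrow(spec@refLines))) {
      if (spec@refLines$axis[i] == "v")
        graphics::abline(v = spec@refLines$value[i], lty = 2L)
      else graphics::abline(h = spec@refLines$value[i], lty = 2L)
    }
    lab <- pts[pts$id %in% labelIds, ]
    if (nrow(lab))
      graphics::text(lab$x, lab$y, lab$id, pos = 3L, cex = 0.7)
  }
  invisible(spec)
}

#' Export biplot coordinates as TSV
#'
#' @param spec a [BiplotSpec-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBiplotCoordinates <- function(spec, path) {
  utils::write.table(spec@points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Render a CA1-arranged matrix as a two-tone heatmap
#'
#' Displays the arranged genotype matrix with value 1 dark and value 0
#' light, first display row at the top, so diagonal concentration of the
#' rare allele reads top-left to bottom-right.
#'
#' @param am an [ArrangedGenotypes-class].
#' @param file optional ".png"/".svg" output path.
#' @param dark,light the two tile colors.
#' @return the arranged matrix, invisibly.
#' @export
plotArrangedMatrix <- function(am, file = NULL,
                               dark = "darkblue", light = "lightsteelblue1") {
  v <- arrangedValues(am)
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 8, height = 5)
    else grDevices::png(file, width = 1000, height = 650, res = 120)
    on.exit(grDevices::dev.off())
  }
  graphics::image(x = seq_len(ncol(v)), y = seq_len(nrow(v)),
                  z = t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                  col = c(light, dark), xlab = "SNPs (CA1 order)",
                  ylab = "Individuals (CA1 order)", useRaster = TRUE,
                  main = sprintf("diagonal concentration %.3f",
                                 am@concentration))
  invisible(v)
}
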