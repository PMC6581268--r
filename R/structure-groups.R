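#' Transfer expert Individual groups to SNPs
#'
#' Classifies every SNP into the Individual group in which its rare allele
#' (the allele coded 1 under rare1 coding) is at the highest frequency,
#' giving both biplot panels one coherent, biologically unified color
#' scheme. Frequency ties between groups are resolved in favor of the
#' largest group, then by lexicographic group name, and are recorded in the
#' \code{"ties"} attribute.
#'
#' @param x a binary [GenotypeMatrix-class], preferably rare1-coded (a
#'   warning is issued otherwise).
#' @param groups group assignment over Individuals (see
#'   [groupAssignment()]); every Individual must be labeled and every group
#'   non-empty.
#' @return A group assignment data.frame over SNPs with attribute
#'   \code{"ties"} listing tied SNP ids.
#' @export
snpGroupsFromIndividualGroups <- function(x, groups) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (!identical(x@coding, "rare1"))
    warning("SNP group transfer is defined for rare1 coding ",
            "(current coding: ", x@coding, ")")
  v <- x@values
  ids <- rownames(v)
  if (!all(ids %in% groups$id))
    stop("unlabeled Individual(s): ",
         paste(utils::head(setdiff(ids, groups$id), 5L), collapse = ", "))
  lab <- stats::setNames(groups$label, groups$id)[ids]
  groupNames <- sort(unique(lab))
  sizes <- table(lab)
  if (any(sizes == 0)) stop("empty group")
  # within-group allele-1 frequency per SNP: groups x SNPs
  freq <- do.call(rbind, lapply(groupNames, function(g)
    colMeans(v[lab == g, , drop = FALSE])))
  rownames(freq) <- groupNames
  # argmax with largest-membership-then-lexicographic tie break
  ord <- order(-as.vector(sizes[groupNames]), groupNames)
  prefOrder <- groupNames[ord]
  best <- apply(freq, 2L, max)
  isTie <- colSums(sweep(freq, 2L, best, "==")) > 1L
  assigned <- vapply(seq_len(ncol(freq)), function(j) {
    winners <- groupNames[freq[, j] == best[j]]
    prefOrder[prefOrder %in% winners][1L]
  }, character(1))
  out <- groupAssignment(colnames(v), assigned, axis = "snps")
  attr(out, "ties") <- colnames(v)[isTie]
  out
}

#' Contiguous quantile groups along an order
#'
#' Splits an ordered axis (typically CA1 display order) into \code{k}
#' contiguous groups of size \code{floor(N/k)}, with the remainder appended
#' to the last group (so 1341 items in 5 groups gives 268, 268, 268, 268,
#' 269). Group labels are \code{"Q1"}..\code{"Qk"} in order.
#'
#' @param order character or integer vector of item ids in display order.
#' @param k number of groups (2 <= k <= N).
#' @param axis \code{"individuals"} or \code{"snps"}.
#' @return A group assignment data.frame in the given order.
#' @examples
#' table(quantileGroupsByOrder(paste0("i", 1:10), 3)$label)  # 3 3 4
#' @export
quantileGroupsByOrder <- function(order, k,
                                  axis = c("individuals", "snps")) {
  axis <- match.arg(axis)
  N <- length(order)
  if (k < 2L || k > N) stop("k must be between 2 and the number of items")
  sizes <- rep(N %/% k, k)
  sizes[k] <- sizes[k] + N %% k
  labels <- rep(paste0("Q", seq_len(k)), times = sizes)
  groupAssignment(as.character(order), labels, axis = axis)
}

#' Default palettes for group schemes
#'
#' \code{"expert"}: green/blue/red for three expert groups;
#' \code{"ca1_quantile"}: dark-green, light-green, black, pink, red for
#' five CA1-order groups (recycled or truncated for other k).
#'
#' @param groups character vector of group names, in display order.
#' @param provenance \code{"expert"} or \code{"ca1_quantile"}.
#' @return named character vector group -> color.
#' @export
groupPalette <- function(groups, provenance = c("expert", "ca1_quantile")) {
  provenance <- match.arg(provenance)
  base <- switch(provenance,
    expert = c("green3", "blue", "red"),
    ca1_quantile = c("darkgreen", "palegreen3", "black", "pink", "red"))
  cols <- rep_len(base, length(groups))
  stats::setNames(cols, groups)
}

#' Report items whose expert label disagrees with their CA1 neighborhood
#'
#' For each item, compares its expert group label with the majority expert
#' label among its \code{2 * window} nearest neighbors in CA1 display
#' order. Items that disagree are candidate classification anomalies worth
#' expert review (the automated order may reveal that an item's genome-wide
#' profile matches a different group than its recorded label). Reporting
#' only; no labels are changed.
#'
#' @param order vector of item ids in CA1 display order.
#' @param expert expert group assignment for the same items.
#' @param window neighbors considered on each side (default 10).
#' @param ignore group labels exempt from the check (e.g. a heterogeneous
#'   diversity group not expected to cluster).
#' @return data.frame with columns id, expertLabel, neighborhoodLabel.
#' @export
anomalyReport <- function(order, expert, window = 10L, ignore = character(0)) {
  lab <- stats::setNames(expert$label, expert$id)[as.character(order)]
  N <- length(order)
  rows <- lapply(seq_len(N), function(i) {
    if (lab[i] %in% ignore) return(NULL)
    nb <- setdiff(max(1L, i - window):min(N, i + window), i)
    nbLab <- lab[nb]
    nbLab <- nbLab[!nbLab %in% ignore]
    if (!length(nbLab)) return(NULL)
    counts <- sort(table(nbLab), decreasing = TRUE)
    major <- names(counts)[1L]
    if (major != lab[i])
      data.frame(id = as.character(order[i]), expertLabel = unname(lab[i]),
                 neighborhoodLabel = major, stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(0), expertLabel = character(0),
                      neighborhoodLabel = character(0))
  out
}
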