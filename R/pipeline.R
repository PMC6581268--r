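#' Run the full analysis pipeline
#'
#' Single entry point wiring the modules together with the recommended
#' defaults: recode to rare1, decompose with DC-PCA, and build a biplot. A
#' run manifest (JSON) records every choice that must be reported for a PCA
#' of SNP data to be reproducible — the graph kind, the SNP coding, and the
#' PCA variant — together with the package version, the input checksum, and
#' the seed.
#'
#' @param input path to a genotype matrix, or a [GenotypeMatrix-class].
#' @param outDir output directory (created if needed).
#' @param dialect,orientation passed to [readGenotypeMatrix()].
#' @param scheme recoding scheme (default \code{"rare1"}); \code{NULL}
#'   keeps the input coding.
#' @param referenceId reference Individual for \code{scheme = "vcf_ref"}.
#' @param variant PCA variant (default \code{"double_centered"}).
#' @param k components to retain (default 7, capped at the rank bound).
#' @param individualGroups optional path to an Individual group TSV.
#' @param ammi1 also fit AMMI and emit AMMI1 coordinates (default TRUE).
#' @param arrange also compute the CA1-arranged matrix (default FALSE; CA
#'   of large matrices costs a full SVD).
#' @param seed integer seed recorded in the manifest and used by any
#'   randomized step.
#' @param figures write SVG figures (default TRUE).
#' @return (invisibly) a list with the recoded genotypes, the ANOVA table,
#'   the decomposition, and the paths written.
#' @export
runPipeline <- function(input, outDir, dialect = "auto",
                        orientation = "individuals_in_rows",
                        scheme = "rare1", referenceId = NULL,
                        variant = "double_centered", k = 7L,
                        individualGroups = NULL, ammi1 = TRUE,
                        arrange = FALSE, seed = 1L, figures = TRUE) {
  .checkVariant(variant)
  if (variant == "snp_standardized" && identical(scheme, "vcf_ref"))
    stop("SNP-Standardized PCA cannot be used with VCF coding: ",
         "the reference genome has a standard deviation of zero")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (is(input, "GenotypeMatrix")) {
    gm <- input
    checksum <- NA_character_
    inputName <- "<in-memory>"
  } else {
    gm <- readGenotypeMatrix(input, dialect = dialect,
                             orientation = orientation)
    checksum <- unname(tools::md5sum(input))
    inputName <- input
  }

  mask <- rep(FALSE, ncol(gm@values))
  if (!is.null(scheme)) {
    rec <- recodeGenotypes(gm, scheme, referenceId = referenceId,
                           seed = seed)
    gm <- rec$genotypes
    mask <- rec$mask
    paths$flips <- file.path(outDir, "flips.tsv")
    writePolarityMask(mask, snpIds(gm), paths$flips)
    paths$recoded <- file.path(outDir, "recoded.tsv")
    writeGenotypeMatrix(gm, paths$recoded)
  }

  anova <- augmentedAnova(gm, variant, k = k)
  paths$anova <- file.path(outDir, "anova.tsv")
  writeAnovaTable(anova, paths$anova)

  kMax <- .rankBound(nrow(gm@values), ncol(gm@values), variant)
  res <- snpPca(gm, variant, k = min(k, kMax))
  sc <- rbind(
    data.frame(axis = "individuals", id = rownames(res@individualVectors),
               scores(res, "individuals"), check.names = FALSE),
    data.frame(axis = "snps", id = rownames(res@snpVectors),
               scores(res, "snps"), check.names = FALSE))
  paths$scores <- file.path(outDir, "scores.tsv")
  utils::write.table(sc, paths$scores, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  groups <- NULL
  snpGroups <- NULL
  if (!is.null(individualGroups)) {
    groups <- readGroupAssignment(individualGroups, "individuals")
    snpGroups <- suppressWarnings(
      snpGroupsFromIndividualGroups(gm, groups))
    paths$snpGroups <- file.path(outDir, "snp_groups.tsv")
    writeGroupAssignment(snpGroups, paths$snpGroups)
  }

  spec <- buildBiplot(res, axes = c(1L, min(2L, length(res@singularValues))),
                      individualGroups = groups, snpGroups = snpGroups)
  paths$biplotCoords <- file.path(outDir, "biplot_coords.tsv")
  writeBiplotCoordinates(spec, paths$biplotCoords)
  if (figures) {
    paths$biplot <- file.path(outDir, "biplot.svg")
    plotBiplot(spec, paths$biplot)
  }

  fit <- NULL
  if (ammi1) {
    kDc <- .rankBound(nrow(gm@values), ncol(gm@values), "double_centered")
    fit <- fitAmmi(gm, k = max(1L, min(k, kDc)))
    aspec <- buildBiplot(fit, individualGroups = groups,
                         snpGroups = snpGroups)
    paths$ammi1Coords <- file.path(outDir, "ammi1_coords.tsv")
    writeBiplotCoordinates(aspec, paths$ammi1Coords)
    if (figures) {
      paths$ammi1 <- file.path(outDir, "ammi1.svg")
      plotBiplot(aspec, paths$ammi1)
    }
  }

  arr <- NULL
  if (arrange) {
    arr <- suppressWarnings(arrangeByCa1(gm))
    paths$individualOrder <- file.path(outDir, "individual_order.txt")
    writeLines(individualIds(gm)[arr@individualOrder],
               paths$individualOrder)
    paths$snpOrder <- file.path(outDir, "snp_order.txt")
    writeLines(snpIds(gm)[arr@snpOrder], paths$snpOrder)
    if (figures) {
      paths$heatmap <- file.path(outDir, "arranged.png")
      plotArrangedMatrix(arr, paths$heatmap)
    }
  }

  manifest <- list(
    package = "snppca",
    version = as.character(utils::packageVersion("snppca")),
    input = inputName, inputChecksum = checksum,
    graph = "biplot", coding = coding(gm), variant = variant,
    components = min(k, kMax), seed = seed,
    flippedSnps = sum(mask),
    outputs = paths)
  paths$manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(genotypes = gm, anova = anova, pca = res, ammi = fit,
                 arranged = arr, biplot = spec, paths = paths))
}
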