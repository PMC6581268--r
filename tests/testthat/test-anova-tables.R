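test_that("three-source ANOVA reproduces hand calculations", {
  # symmetric 2x2: pure interaction
  tab <- threeSourceAnova(matrix(c(1, 0, 0, 1), 2))
  expect_equal(tab$ss, c(1, 0, 0, 1))
  expect_equal(tab$df, c(3, 1, 1, 1))
  # [[1,1],[0,1]]: hand ANOVA gives 0.25 per source
  tab2 <- threeSourceAnova(matrix(c(1, 0, 1, 1), 2))
  expect_equal(tab2$ss, c(0.75, 0.25, 0.25, 0.25))
  expect_error(threeSourceAnova(matrix(1, 1, 3)), "2 x 2")
})

test_that("three-source ANOVA agrees with stats::aov", {
  m <- mkMatrix(rbinom(30, 1, 0.5), 5)
  set.seed(3)
  m <- mkMatrix(rbinom(30, 1, 0.5), 5)
  d <- data.frame(y = as.vector(m),
                  ind = factor(rep(seq_len(5), 6)),
                  snp = factor(rep(seq_len(6), each = 5)))
  av <- summary(stats::aov(y ~ ind + snp, d))[[1]]
  tab <- threeSourceAnova(m)
  expect_equal(tab$ss[tab$source == "Individuals"], av["ind", "Sum Sq"])
  expect_equal(tab$ss[tab$source == "SNPs"], av["snp", "Sum Sq"])
  expect_equal(tab$ss[tab$source == "SxI"], av["Residuals", "Sum Sq"])
  expect_equal(tab$df[-1], c(av["snp", "Df"], av["ind", "Df"],
                             av["Residuals", "Df"]))
})

test_that("sources are orthogonal: they sum to the corrected total", {
  for (seed in 1:5) {
    gm <- randomPolymorphic(6, 8, seed = 200 + seed)
    tab <- threeSourceAnova(gm)
    expect_equal(sum(tab$ss[-1]), tab$ss[1],
                 tolerance = 1e-6 * max(tab$ss[1], 1))
    expect_equal(sum(tab$df[-1]), tab$df[1])
  }
})

test_that("DC-PCA ANOVA closes the SxI subtotal with IPCs and residual", {
  gm <- randomPolymorphic(8, 10, seed = 33)
  tab <- dcPcaAnova(gm, k = 4)
  ipc <- grepl("^IPC", tab$source)
  expect_equal(sum(tab$ss[ipc]) + tab$ss[tab$source == "Residual"],
               tab$ss[tab$source == "SxI"], tolerance = 1e-9)
  expect_equal(sum(tab$df[ipc]) + tab$df[tab$source == "Residual"],
               tab$df[tab$source == "SxI"])
  # additive (interaction-free) data: every IPC SS is zero
  add <- outer(c(0, 1, 1, 2), c(1, 1, 0, 2, 2), "+")
  dimnames(add) <- list(paste0("i", 1:4), paste0("s", 1:5))
  tabAdd <- dcPcaAnova(add, k = 3)
  expect_lt(max(tabAdd$ss[grepl("^IPC", tabAdd$source)]), 1e-18)
})

test_that("rare1 and common1 codings give identical ANOVA tables", {
  gm <- codingSafePolymorphic(9, 12, seed = 51)  # odd rows: no ties
  r1 <- recodeGenotypes(gm, "rare1")$genotypes
  c1 <- recodeGenotypes(gm, "common1")$genotypes
  for (variant in pcaVariants()) {
    a <- augmentedAnova(r1, variant, k = 3)
    b <- augmentedAnova(c1, variant, k = 3)
    expect_equal(a$ss, b$ss, tolerance = 1e-9,
                 label = paste("ss for", variant))
    expect_identical(a$df, b$df)
  }
})

test_that("augmented portions sum to each component's SS", {
  gm <- polymorphicBernoulli(10, 14, 0.05, 0.03, 0.08, seed = 9)
  for (variant in c("snp_centered", "individual_centered",
                    "snp_standardized", "individual_standardized",
                    "grand_mean_centered")) {
    aug <- augmentedAnova(gm, variant, k = 3)
    sources <- attr(aug, "portionSources")
    rows <- grepl("^PC[0-9]+$|^Residual$", aug$source)
    portionSum <- unname(rowSums(aug[rows, sources, drop = FALSE]))
    expect_equal(portionSum, aug$ss[rows], tolerance = 1e-9,
                 label = paste("row closure for", variant))
  }
})

test_that("augmented columns close onto the source SS for centered variants", {
  gm <- polymorphicBernoulli(12, 16, 0.05, 0.04, 0.08, seed = 19)
  raw <- threeSourceAnova(gm)
  ssInd <- raw$ss[raw$source == "Individuals"]
  ssSnp <- raw$ss[raw$source == "SNPs"]
  ssInt <- raw$ss[raw$source == "SxI"]

  aug <- augmentedAnova(gm, "snp_centered", k = 4)
  comp <- grepl("^PC[0-9]+$|^Residual$", aug$source)
  expect_equal(sum(aug$Individuals[comp]), ssInd, tolerance = 1e-9)
  expect_equal(sum(aug$SxI[comp]), ssInt, tolerance = 1e-9)

  aug2 <- augmentedAnova(gm, "individual_centered", k = 4)
  comp2 <- grepl("^PC[0-9]+$|^Residual$", aug2$source)
  expect_equal(sum(aug2$SNPs[comp2]), ssSnp, tolerance = 1e-9)
  expect_equal(sum(aug2$SxI[comp2]), ssInt, tolerance = 1e-9)
})

test_that("snp-centered PCs carry no Individual portion when row means are equal", {
  # constant row sums: all Individual means identical
  v <- rbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(0, 0, 1, 1), c(1, 0, 0, 1))
  dimnames(v) <- list(paste0("i", 1:4), paste0("s", 1:4))
  aug <- augmentedAnova(v, "snp_centered", k = 2)
  pcs <- grepl("^PC", aug$source)
  expect_lt(max(aug$Individuals[pcs]), 1e-18)
})

test_that("double-centered input returns the plain table unaugmented", {
  gm <- randomPolymorphic(6, 8, seed = 71)
  aug <- augmentedAnova(gm, "double_centered", k = 3)
  expect_false(inherits(aug, "snppcaAugmentedAnova"))
  expect_equal(aug$ss, dcPcaAnova(gm, k = 3)$ss)
})

test_that("the outcome classifier separates main, interaction, and mixed PCs", {
  # strong SNP main effects: individual-centered PC1 is main-dominated
  gm <- polymorphicBernoulli(30, 40, 0.25, 0.0, 0.03, seed = 77)
  aug <- augmentedAnova(gm, "individual_centered", k = 2)
  out <- classifyPcOutcomes(aug)
  expect_equal(out$outcome[1], "main_dominated")
  # negligible main effects: snp-centered PC1 is interaction-dominated
  gm2 <- polymorphicBernoulli(30, 40, 0.02, 0.0, 0.2, seed = 78)
  out2 <- classifyPcOutcomes(augmentedAnova(gm2, "snp_centered", k = 2))
  expect_equal(out2$outcome[1], "interaction_dominated")
  # threshold behavior on a synthetic row
  fake <- augmentedAnova(gm2, "snp_centered", k = 2)
  cls <- classifyPcOutcomes(fake, mixedThreshold = 1e-9)
  expect_true(all(cls$outcome == "mixed" |
                    pmin(cls$mainShare, cls$interactionShare) < 1e-9))
})

test_that("anova tables export as TSV and JSON", {
  gm <- randomPolymorphic(5, 6, seed = 81)
  tab <- dcPcaAnova(gm, k = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeAnovaTable(tab, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$ss, tab$ss, tolerance = 1e-12)
  js <- withr::local_tempfile(fileext = ".json")
  writeAnovaTable(tab, js, format = "json")
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$ss, tab$ss)
})
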