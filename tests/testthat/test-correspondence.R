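test_that("the two-block matrix separates with first singular value 1", {
  ca <- caDecompose(block4(), k = 1)
  expect_equal(unname(singularValues(ca)), 1, tolerance = 1e-12)
  rc <- unname(ca@individualCoords[, 1])
  expect_equal(rc[1], rc[2], tolerance = 1e-10)
  expect_equal(rc[3], rc[4], tolerance = 1e-10)
  expect_lt(rc[1] * rc[3], 0)  # opposite signs across blocks
})

test_that("CA agrees with the vegan correspondence-analysis oracle", {
  requireNamespace("vegan", quietly = TRUE)
  for (seed in c(7, 19, 23)) {
    gm <- randomPolymorphic(6, 8, seed = seed)
    ours <- caDecompose(gm, k = 3)
    ref <- vegan::cca(genotypeValues(gm))
    expect_equal(unname(singularValues(ours)),
                 unname(sqrt(ref$CA$eig[1:3])), tolerance = 1e-8)
    site <- vegan::scores(ref, display = "sites", choices = 1,
                          scaling = "none")[, 1]
    expect_gt(abs(cor(site, ours@individualCoords[, 1])), 1 - 1e-8)
  }
})

test_that("power method matches the SVD route on random binary matrices", {
  for (seed in 1:20) {
    gm <- randomPolymorphic(6, 8, seed = 300 + seed)
    a <- caDecompose(gm, k = 1)
    b <- caDecompose(gm, method = "power")
    expect_equal(unname(singularValues(b)), unname(singularValues(a)),
                 tolerance = 1e-8)
    expect_lt(signedDev(a@snpCoords[, 1], b@snpCoords[, 1]), 1e-7)
  }
})

test_that("zero margins and structureless matrices are rejected by name", {
  v <- mkMatrix(c(0, 0, 0, 1, 0, 1, 1, 1, 0), 3)
  v[, 1] <- 0L
  expect_error(caDecompose(GenotypeMatrix(v)), "zero-margin SNP.*s1")
  ones <- mkGenotypes(rep(1, 12), 3)
  expect_error(caDecompose(ones), "no nontrivial")
})

test_that("CA1 arrangement restores contiguous blocks from shuffled input", {
  v <- genotypeValues(block4())[c(1, 3, 2, 4), ]
  gm <- GenotypeMatrix(v, coding = "rare1")
  arr <- arrangeByCa1(gm)
  lab <- rownames(arrangedValues(arr))
  blockOf <- unname(c(i1 = 1, i2 = 1, i3 = 2, i4 = 2)[lab])
  expect_true(identical(blockOf, sort(blockOf)) ||
                identical(blockOf, rev(sort(blockOf))))
  # applying the stored orders reproduces the displayed matrix
  expect_identical(arrangedValues(arr),
                   v[arr@individualOrder, arr@snpOrder])
})

test_that("warning is raised when arranging a non-rare1 coding", {
  gm <- randomPolymorphic(6, 8, seed = 45)
  expect_warning(arrangeByCa1(gm), "rare1")
})

test_that("the diagonal statistic is 1 on the identity and handles uniform mass", {
  expect_equal(diagonalStatistic(diag(5)), 1)
  # permutation-invariant input: statistic equals its own null
  ones <- mkGenotypes(rep(1, 20), 4)
  res <- suppressWarnings(diagonalConcentration(ones, nullReps = 5, seed = 2))
  expect_equal(res$nullMean, res$statistic)
  expect_equal(res$exceedance, 1)
})

test_that("banded structure beats its within-column randomization null", {
  gm <- diagonalBandMatrix(20, 24, 3, 0.05, seed = 11)
  res <- diagonalConcentration(gm, nullReps = 49, seed = 12)
  # a degenerate randomization replicate (no CA structure) may be dropped
  expect_gte(length(res$nullValues), 45)
  expect_equal(res$exceedance, 0)
  expect_gt(res$statistic, res$nullMean + 3 * res$nullSd)
})

test_that("CA1 ordering is invariant to input permutations up to reversal", {
  gm <- diagonalBandMatrix(12, 15, 3, 0.05, seed = 21)
  arr <- arrangeByCa1(gm)
  idsA <- individualIds(gm)[arr@individualOrder]
  set.seed(31)
  perm <- sample(nrow(genotypeValues(gm)))
  gmP <- GenotypeMatrix(genotypeValues(gm)[perm, ], coding = "rare1")
  arrP <- arrangeByCa1(gmP)
  idsB <- individualIds(gmP)[arrP@individualOrder]
  expect_true(identical(idsA, idsB) || identical(idsA, rev(idsB)))
  # the concentration statistic is permutation-invariant too
  expect_equal(arrP@concentration, arr@concentration, tolerance = 1e-10)
})

test_that("concentration is invariant under simultaneous order reversal", {
  gm <- diagonalBandMatrix(10, 12, 3, 0, seed = 1)
  arr <- arrangeByCa1(gm)
  v <- arrangedValues(arr)
  expect_equal(diagonalStatistic(v[rev(seq_len(nrow(v))),
                                   rev(seq_len(ncol(v)))]),
               diagonalStatistic(v), tolerance = 1e-12)
})

test_that("gradient data concentrates more after arrangement than as received", {
  hits <- 0
  for (seed in 1:5) {
    gm <- diagonalBandMatrix(15, 18, 3, 0.1, seed = seed)
    set.seed(seed + 500)
    shuffled <- GenotypeMatrix(
      genotypeValues(gm)[sample(15), sample(18)], coding = "rare1")
    arr <- arrangeByCa1(shuffled)
    if (arr@concentration > diagonalStatistic(genotypeValues(shuffled)))
      hits <- hits + 1
  }
  expect_gte(hits, 4)
})
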