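test_that("transforms satisfy their centering identities", {
  gm <- randomPolymorphic(7, 9, seed = 5)
  tol <- 1e-9
  tm <- transformGenotypes(gm, "snp_centered")
  expect_lt(max(abs(colMeans(tm@values))), tol)
  tm <- transformGenotypes(gm, "individual_centered")
  expect_lt(max(abs(rowMeans(tm@values))), tol)
  tm <- transformGenotypes(gm, "double_centered")
  expect_lt(max(abs(rowMeans(tm@values))), tol)
  expect_lt(max(abs(colMeans(tm@values))), tol)
  tm <- transformGenotypes(gm, "grand_mean_centered")
  expect_lt(abs(mean(tm@values)), tol)
  tm <- transformGenotypes(gm, "snp_standardized")
  expect_lt(max(abs(colMeans(tm@values))), tol)
  expect_equal(unname(apply(tm@values, 2, sd)), rep(1, 9))
  tm <- transformGenotypes(gm, "individual_standardized")
  expect_equal(unname(apply(tm@values, 1, sd)), rep(1, 7))
})

test_that("hand-computable cases transform as expected", {
  # snp centering of the 2x2 identity
  tm <- transformGenotypes(identity2(), "snp_centered")
  expect_equal(unname(tm@values), matrix(c(0.5, -0.5, -0.5, 0.5), 2))
  # a purely additive matrix double-centers to zero
  add <- outer(c(1, 2, 3), c(0, 1, 1, 2), "+")
  dimnames(add) <- list(paste0("i", 1:3), paste0("s", 1:4))
  tm <- transformGenotypes(add, "double_centered")
  expect_lt(max(abs(tm@values)), 1e-12)
  # a monomorphic SNP cannot be standardized
  mono <- mkGenotypes(c(0, 0, 0, 1, 0, 1), 3)
  expect_error(transformGenotypes(mono, "snp_standardized"), "s1")
})

test_that("the 2x2 identity decomposes by hand: lambda 1, scores 0.70711", {
  res <- snpPca(identity2(), "double_centered", k = 1)
  expect_equal(unname(singularValues(res)), 1)
  expect_equal(res@componentSS, 1)
  expect_equal(sort(unname(scores(res, "individuals")[, 1])),
               c(-1, 1) / sqrt(2), tolerance = 1e-10)
  expect_equal(sort(unname(scores(res, "snps")[, 1])),
               c(-1, 1) / sqrt(2), tolerance = 1e-10)
  # rank-1 reconstruction is exactly the interaction matrix
  expect_equal(unname(reconstructComponents(res, 1)),
               0.5 * matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)
})

test_that("Gollob df rule reproduces the printed values and closes", {
  expect_identical(componentDf(1341, 635, 1, "double_centered"), 1973L)
  expect_identical(componentDf(1341, 635, 7, "double_centered"), 1961L)
  expect_identical(componentDf(1341, 635, 1, "snp_centered"), 1974L)
  expect_identical(componentDf(1341, 635, 1, "grand_mean_centered"), 1975L)
  # S x I df = sum of the first 7 IPC dfs plus the printed residual df
  ipcDf <- componentDf(1341, 635, 1:7, "double_centered")
  expect_identical(sum(ipcDf) + 835791L, 634L * 1340L)
  expect_error(componentDf(3, 3, 5, "double_centered"), "nonpositive")
})

test_that("df bookkeeping closes on arbitrary layouts and variants", {
  for (variant in pcaVariants()) {
    for (dims in list(c(6, 9), c(8, 5))) {
      R <- dims[1]; C <- dims[2]
      gm <- randomPolymorphic(R, C, seed = R * C)
      k <- 3
      res <- snpPca(gm, variant, k = k)
      srcDf <- switch(variant,
        double_centered = (R - 1) * (C - 1),
        snp_centered = , snp_standardized = (R - 1) * C,
        individual_centered = , individual_standardized = R * (C - 1),
        grand_mean_centered = R * C - 1)
      expect_equal(sum(res@componentDf) + res@residualDf, srcDf)
    }
  }
})

test_that("energy is conserved: sum of squared singular values = total SS", {
  for (variant in pcaVariants()) {
    gm <- randomPolymorphic(8, 6, seed = 17)
    kMax <- switch(variant,
      double_centered = 5, snp_centered = 6, snp_standardized = 6,
      individual_centered = 5, individual_standardized = 5,
      grand_mean_centered = 6)
    kMax <- min(kMax, 5)
    res <- snpPca(gm, variant, k = kMax)
    tm <- transformGenotypes(gm, variant)
    # retained component SS plus residual SS must equal the total SS
    expect_equal(sum(res@componentSS) + res@residualSS, sum(tm@values^2),
                 tolerance = 1e-6 * sum(tm@values^2))
    expect_equal(res@totalSS, sum(tm@values^2),
                 tolerance = 1e-6 * sum(tm@values^2))
  }
})

test_that("decompose matches a brute-force eigendecomposition oracle", {
  for (seed in 1:10) {
    nI <- sample(4:8, 1)
    nS <- sample(4:8, 1)
    gm <- randomPolymorphic(nI, nS, seed = 100 + seed)
    for (variant in c("double_centered", "snp_centered",
                      "grand_mean_centered")) {
      tm <- transformGenotypes(gm, variant)
      ev <- eigen(crossprod(tm@values), symmetric = TRUE)
      k <- 2
      res <- snpPca(gm, variant, k = k)
      expect_equal(unname(singularValues(res)),
                   sqrt(pmax(ev$values[seq_len(k)], 0)), tolerance = 1e-8)
      for (n in seq_len(k)) {
        # eigenvectors are only identified up to sign, and not at all
        # within a (near-)degenerate eigenvalue pair
        gap <- min(abs(ev$values[n] - ev$values[-n]))
        if (ev$values[n] < 1e-8 || gap < 1e-4 * max(ev$values)) next
        expect_lt(signedDev(res@snpVectors[, n], ev$vectors[, n]), 1e-6)
      }
    }
  }
})

test_that("reconstruction is complete at full rank and zero at k = 0", {
  gm <- randomPolymorphic(5, 4, seed = 23)
  tm <- transformGenotypes(gm, "double_centered")
  res <- snpPca(gm, "double_centered", k = 3)
  expect_lt(max(abs(reconstructComponents(res, 3) - tm@values)), 1e-10)
  expect_equal(unname(reconstructComponents(res, 0)),
               matrix(0, 5, 4))
  expect_error(reconstructComponents(res, 4), "retained")
})

test_that("joint sign flips leave reconstructed products unchanged", {
  gm <- randomPolymorphic(6, 5, seed = 31)
  res <- snpPca(gm, "double_centered", k = 2)
  flipped <- res
  flipped@individualVectors[, 1] <- -flipped@individualVectors[, 1]
  flipped@snpVectors[, 1] <- -flipped@snpVectors[, 1]
  expect_equal(reconstructComponents(flipped, 2),
               reconstructComponents(res, 2), tolerance = 1e-12)
})

test_that("score scalings follow their conventions", {
  gm <- randomPolymorphic(6, 5, seed = 37)
  res <- snpPca(gm, "double_centered", k = 2)
  sym <- scores(res, "individuals")
  expect_equal(sym, sweep(res@individualVectors, 2,
                          sqrt(singularValues(res)), "*"))
  prin <- scores(res, "individuals", scaling = "axis_principal")
  expect_equal(prin, sweep(res@individualVectors, 2,
                           singularValues(res), "*"))
  # symmetric scores multiply out to the rank-1 interaction estimate
  est <- tcrossprod(sym[, 1], scores(res, "snps")[, 1])
  expect_equal(est, singularValues(res)[1] *
                 tcrossprod(res@individualVectors[, 1], res@snpVectors[, 1]),
               tolerance = 1e-12)
})

test_that("k beyond the rank bound is rejected", {
  gm <- randomPolymorphic(4, 6, seed = 41)
  expect_error(snpPca(gm, "double_centered", k = 4), "rank bound")
  expect_silent(snpPca(gm, "double_centered", k = 3))
})
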