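test_that("band matrices are deterministic at zero noise and reproducible", {
  a <- diagonalBandMatrix(20, 24, 3, 0, seed = 1)
  b <- diagonalBandMatrix(20, 24, 3, 0, seed = 999)
  expect_identical(genotypeValues(a), genotypeValues(b))
  c1 <- diagonalBandMatrix(20, 24, 3, 0.2, seed = 7)
  c2 <- diagonalBandMatrix(20, 24, 3, 0.2, seed = 7)
  expect_identical(genotypeValues(c1), genotypeValues(c2))
  expect_false(identical(genotypeValues(c1), genotypeValues(a)))
  expect_error(diagonalBandMatrix(20, 24, 3, 0.6, seed = 1), "noiseRate")
  expect_error(diagonalBandMatrix(1, 24, 3, 0, seed = 1), "degenerate")
})

test_that("band output is rare1-coded and valid", {
  for (seed in 1:3) {
    gm <- diagonalBandMatrix(20, 24, 3, 0.1, seed = seed)
    expect_equal(coding(gm), "rare1")
    expect_true(max(allele1Frequencies(gm)$snp) <= 0.5 + 1e-12)
    rep <- validateGenotypes(gm)
    expect_equal(rep$valueViolations, 0)
    expect_equal(rep$missingCount, 0)
  }
})

test_that("the single gradient arches in the IPC1-IPC2 plane", {
  gm <- diagonalBandMatrix(20, 24, 3, 0, seed = 1)
  res <- snpPca(gm, "double_centered", k = 2)
  si <- scores(res, "individuals")
  # the arch: IPC2 is a strong quadratic function of gradient position
  t <- seq_len(20)
  fit <- lm(si[, 2] ~ t + I(t^2))
  expect_gt(summary(fit)$r.squared, 0.6)
  # with single-signed curvature (a genuine arch, not a wiggle)
  expect_gt(abs(coef(fit)[3]) * 20^2 / 4, diff(range(si[, 2])) / 4)
})

test_that("individuals and matched SNPs track each other under rare1", {
  gm <- diagonalBandMatrix(20, 24, 3, 0, seed = 1)
  res <- snpPca(gm, "double_centered", k = 2)
  si <- scores(res, "individuals")
  ss <- scores(res, "snps")
  matched <- round((seq_len(20) - 0.5) / 20 * 24 + 0.5)
  angI <- atan2(si[, 2], si[, 1])
  angS <- atan2(ss[matched, 2], ss[matched, 1])
  offset <- (angS - angI + pi) %% (2 * pi) - pi
  expect_lt(mean(abs(offset)), 0.3)
})

test_that("common1 coding rotates the SNP arch by about 180 degrees", {
  gm <- diagonalBandMatrix(20, 24, 3, 0, seed = 1)
  c1 <- recodeGenotypes(gm, "common1")$genotypes
  res <- snpPca(c1, "double_centered", k = 2)
  si <- scores(res, "individuals")
  ss <- scores(res, "snps")
  matched <- round((seq_len(20) - 0.5) / 20 * 24 + 0.5)
  angI <- atan2(si[, 2], si[, 1])
  angS <- atan2(ss[matched, 2], ss[matched, 1])
  offset <- (angS - angI + pi) %% (2 * pi) - pi
  expect_gt(mean(abs(offset)), pi - 0.3)
})

test_that("unstructured Bernoulli draws have near-null ANOVA shares", {
  # under independence, E share of each main source is df/(RC - 1)
  shares <- t(vapply(1:25, function(s) {
    g <- structuredBernoulli(40, 60, 0, 0, 0, seed = s)$genotypes
    a <- threeSourceAnova(g)
    a$ss[2:4] / a$ss[1]
  }, numeric(3)))
  expSnp <- 59 / 2399; expInd <- 39 / 2399
  expect_lt(abs(mean(shares[, 1]) - expSnp), 3 * sd(shares[, 1]))
  expect_lt(abs(mean(shares[, 2]) - expInd), 3 * sd(shares[, 2]))
  expect_gt(mean(shares[, 3]), 0.9)
})

test_that("requested interaction dominance is realized across seeds", {
  wins <- 0
  for (s in 1:20) {
    g <- structuredBernoulli(60, 120, 0.04, 0.01, 0.20, seed = s)$genotypes
    a <- threeSourceAnova(g)
    sh <- a$ss[2:4] / a$ss[1]
    if (sh[3] > sh[1] && sh[3] > sh[2]) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("realized main-effect shares are monotone in requested shares", {
  realized <- vapply(c(0.02, 0.08, 0.15), function(target) {
    g <- structuredBernoulli(100, 200, target, 0.01, 0.05,
                             seed = 3)$genotypes
    a <- threeSourceAnova(g)
    a$ss[2] / a$ss[1]
  }, numeric(1))
  expect_true(all(diff(realized) > 0))
})

test_that("infeasible shares are rejected with the saturation rule", {
  expect_error(structuredBernoulli(300, 600, 0.05, 0.01, 0.30, seed = 1),
               "saturates")
  expect_error(structuredBernoulli(10, 10, 0.5, 0.4, 0.3, seed = 1),
               "less than 1")
  expect_error(structuredBernoulli(10, 10, -0.1, 0, 0, seed = 1),
               "nonnegative")
})

test_that("the generating truth is returned and matches the surface", {
  out <- structuredBernoulli(30, 40, 0.05, 0.02, 0.1, seed = 4)
  expect_named(out$truth, c("a", "b", "g", "h", "base", "pi"))
  expect_equal(dim(out$truth$pi), c(30, 40))
  expect_true(all(out$truth$pi >= 0.02 & out$truth$pi <= 0.98))
  rep <- validateGenotypes(out$genotypes)
  expect_equal(rep$valueViolations, 0)
})
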