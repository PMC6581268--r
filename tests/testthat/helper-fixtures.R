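# Small fixtures built in code.

# named 0/1 matrix from a vector, filled by column
mkMatrix <- function(x, nrow, inds = NULL, snps = NULL) {
  m <- matrix(x, nrow = nrow)
  rownames(m) <- if (is.null(inds)) paste0("i", seq_len(nrow(m))) else inds
  colnames(m) <- if (is.null(snps)) paste0("s", seq_len(ncol(m))) else snps
  m
}

mkGenotypes <- function(x, nrow, coding = "unknown", ...) {
  GenotypeMatrix(mkMatrix(x, nrow, ...), coding = coding)
}

# the 2x2 identity example: DC interaction is 0.5 * [[1,-1],[-1,1]]
identity2 <- function() mkGenotypes(c(1, 0, 0, 1), 2)

# the 2x2 two-block CA example
block4 <- function() {
  mkGenotypes(c(1, 1, 0, 0, 1, 1, 0, 0, 0, 0, 1, 1, 0, 0, 1, 1), 4)
}

# a random polymorphic binary matrix with no zero margins
randomPolymorphic <- function(nInd, nSnp, seed, p = 0.5) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(nInd * nSnp, 1L, p), nInd, nSnp)
    ok <- all(colMeans(m) > 0) && all(colMeans(m) < 1) &&
      all(rowMeans(m) > 0) && all(rowMeans(m) < 1)
    if (ok) break
  }
  mkGenotypes(as.vector(m), nInd)
}

# random polymorphic matrix that stays row-polymorphic under rare1 and
# common1 recoding (needed by individual-standardized comparisons)
codingSafePolymorphic <- function(nInd, nSnp, seed) {
  repeat {
    gm <- randomPolymorphic(nInd, nSnp, seed = seed)
    r1 <- recodeGenotypes(gm, "rare1")$genotypes
    c1 <- recodeGenotypes(gm, "common1")$genotypes
    sdOk <- function(g) all(apply(genotypeValues(g), 1, sd) > 0)
    if (sdOk(r1) && sdOk(c1)) return(gm)
    seed <- seed + 1000
  }
}

# structured Bernoulli draw with monomorphic SNPs dropped
polymorphicBernoulli <- function(nInd, nSnp, shareSnp, shareInd, shareInt,
                                 seed) {
  g <- structuredBernoulli(nInd, nSnp, shareSnp, shareInd, shareInt,
                           seed = seed)$genotypes
  mono <- validateGenotypes(g)$monomorphicSnps
  if (length(mono)) g <- g[, setdiff(snpIds(g), mono)]
  g
}

# deviation between two unit vectors up to sign
signedDev <- function(a, b) min(max(abs(a - b)), max(abs(a + b)))
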