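#' Diagonal-band genotype matrix driven by a single gradient
#'
#' Generates the classic gradient-structured 0/1 matrix: entry (r, c) is 1
#' when the normalized positions \code{r~ = (r - 0.5)/nInd} and
#' \code{c~ = (c - 0.5)/nSnp} differ by at most \code{bandWidth/nSnp}
#' (a band of about \code{2 * bandWidth + 1} columns around the diagonal),
#' and 0 elsewhere. Each entry is then flipped independently with
#' probability \code{noiseRate}, and the result is recoded rare1 so the
#' output satisfies the rare-allele convention regardless of noise. DC-PCA
#' of such a matrix shows the arch (horseshoe) distortion: the single
#' gradient bends into a quadratic curve in the IPC1-IPC2 plane, with
#' Individuals and SNPs at the same gradient position tracking each other.
#'
#' @param nInd,nSnp dimensions (default 20 x 24).
#' @param bandWidth band half-width in column units (default 3).
#' @param noiseRate independent flip probability in [0, 0.5) (default 0).
#' @param seed integer seed (mandatory; the generator must be
#'   reproducible even at zero noise, where it is deterministic).
#' @return A rare1-coded [GenotypeMatrix-class].
#' @examples
#' gm <- diagonalBandMatrix(20, 24, bandWidth = 3, noiseRate = 0, seed = 1)
#' @export
diagonalBandMatrix <- function(nInd = 20L, nSnp = 24L, bandWidth = 3,
                               noiseRate = 0, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (nInd < 2L || nSnp < 2L) stop("degenerate dimensions")
  if (bandWidth < 1) stop("bandWidth must be at least 1")
  if (noiseRate < 0 || noiseRate >= 0.5)
    stop("noiseRate must be in [0, 0.5)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rr <- (seq_len(nInd) - 0.5) / nInd
  cc <- (seq_len(nSnp) - 0.5) / nSnp
  v <- 1L * (abs(outer(rr, cc, "-")) <= bandWidth / nSnp)
  if (noiseRate > 0) {
    flips <- matrix(stats::runif(nInd * nSnp) < noiseRate, nInd, nSnp)
    v <- ifelse(flips, 1L - v, v)
  }
  dimnames(v) <- list(sprintf("ind%04d", seq_len(nInd)),
                      sprintf("snp%04d", seq_len(nSnp)))
  gm <- GenotypeMatrix(v, coding = "unknown")
  # guarantee rare1 regardless of band geometry and noise
  recodeGenotypes(gm, "rare1")$genotypes
}

#' Bernoulli genotype matrix with controlled effect structure
#'
#' Draws entries independently as Bernoulli(pi_rc) with
#' \code{pi_rc = clamp(base + a_r + b_c + g_r * h_c, eps, 1 - eps)}
#' (\code{eps = 0.02}). The Individual-main vector \code{a}, SNP-main
#' vector \code{b}, and the interaction factors \code{g}, \code{h} are
#' balanced two-level (plus/minus) vectors in random order, rescaled so
#' that, in expectation, each structural source contributes the requested
#' share of the total corrected SS (the baseline Bernoulli sampling noise
#' contributes the remainder). Two-level factors keep the rank-1
#' interaction surface at constant magnitude — no spikes into the clamp
#' region — and emulate two diverged subpopulations with a differentiated
#' SNP block, the canonical discrete population-structure signal; the
#' smooth-gradient case is covered by [diagonalBandMatrix()]. The
#' generating truth is returned alongside the matrix so parameter-recovery
#' checks can compare realized against requested structure. If clamping
#' still saturates more than 10 percent of cells the requested shares are
#' infeasible and an error is raised.
#'
#' @param nInd,nSnp dimensions.
#' @param shareSnp,shareInd,shareInt requested expected SS shares of the
#'   SNP-main, Individual-main, and interaction sources (nonnegative, sum
#'   below 1).
#' @param base baseline allele-1 probability (default 0.5, which maximizes
#'   the feasible share region; polarity is arbitrary before recoding, so a
#'   symmetric baseline loses no generality).
#' @param seed integer seed (mandatory).
#' @return list with \code{genotypes} (a [GenotypeMatrix-class]) and
#'   \code{truth} (list: a, b, g, h, base, pi).
#' @export
structuredBernoulli <- function(nInd, nSnp, shareSnp = 0, shareInd = 0,
                                shareInt = 0, base = 0.5, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  shares <- c(shareSnp, shareInd, shareInt)
  if (any(shares < 0)) stop("shares must be nonnegative")
  sTot <- sum(shares)
  if (sTot >= 1) stop("shares must sum to less than 1")
  eps <- 0.02
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  # expected sampling-noise SS at the baseline; structural SS targets follow
  noiseSS <- nInd * nSnp * base * (1 - base)
  totalSS <- noiseSS / (1 - sTot)
  # balanced +/- factors in random order: centered, unit norm, constant
  # magnitude (up to an odd-size imbalance), so the rank-1 interaction
  # surface never spikes into the clamp region
  unitVec <- function(n) {
    z <- sample(c(rep(1, n %/% 2), rep(-1, n - n %/% 2)))
    z <- z - mean(z)
    z / sqrt(sum(z^2))
  }
  b <- unitVec(nSnp) * sqrt(shareSnp * totalSS / nInd)   # SNP main
  a <- unitVec(nInd) * sqrt(shareInd * totalSS / nSnp)   # Individual main
  g <- unitVec(nInd)
  h <- unitVec(nSnp)
  int <- sqrt(shareInt * totalSS) * outer(g, h)
  pi <- base + outer(a, rep(1, nSnp)) + outer(rep(1, nInd), b) + int
  saturated <- mean(pi < eps | pi > 1 - eps)
  pi <- pmin(pmax(pi, eps), 1 - eps)
  if (saturated > 0.10)
    stop(sprintf("infeasible shares: clamping saturates %.1f%% of cells",
                 100 * saturated))
  v <- matrix(stats::rbinom(nInd * nSnp, 1L, pi), nInd, nSnp,
              dimnames = list(sprintf("ind%04d", seq_len(nInd)),
                              sprintf("snp%04d", seq_len(nSnp))))
  list(genotypes = GenotypeMatrix(v, coding = "unknown"),
       truth = list(a = a, b = b, g = g, h = h, base = base, pi = pi))
}
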