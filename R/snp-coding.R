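#' Allele-1 frequencies and Individual means
#'
#' For a binary genotype matrix, the mean of a SNP column across Individuals
#' is the frequency of the allele coded 1, and the mean of an Individual row
#' across SNPs is that Individual's frequency of alleles coded 1. These are
#' the main effects that centering removes and that the AMMI1 abscissa
#' displays.
#'
#' @param x a binary-mode [GenotypeMatrix-class].
#' @return list with numeric vectors \code{snp} (per-SNP frequency of the
#'   allele coded 1) and \code{individual} (per-Individual mean), plus
#'   \code{grand} (grand mean).
#' @export
allele1Frequencies <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (x@ploidyMode != "binary")
    stop("allele-1 frequencies require binary mode; ",
         "convert diploid data first")
  v <- x@values
  list(snp = colMeans(v), individual = rowMeans(v), grand = mean(v))
}

#' Apply a polarity mask
#'
#' Complements the flagged SNP columns (\code{x -> 1 - x}, or \code{2 - x}
#' in diploid mode). Applying the same mask twice restores the original
#' matrix.
#'
#' @param x a [GenotypeMatrix-class].
#' @param mask logical vector of length \code{ncol(x)}; \code{TRUE} flips
#'   that SNP's polarity.
#' @param coding coding tag for the result (default \code{"mixed"} when any
#'   flip occurred, otherwise unchanged).
#' @return A [GenotypeMatrix-class].
#' @export
applyPolarityMask <- function(x, mask, coding = NULL) {
  stopifnot(is(x, "GenotypeMatrix"))
  mask <- as.logical(mask)
  if (length(mask) != ncol(x@values))
    stop("mask length must equal the number of SNPs")
  v <- x@values
  top <- if (x@ploidyMode == "diploid") 2L else 1L
  v[, mask] <- top - v[, mask, drop = FALSE]
  if (is.null(coding))
    coding <- if (any(mask)) "mixed" else x@coding
  new("GenotypeMatrix", values = v, coding = coding,
      ploidyMode = x@ploidyMode)
}

#' Recode a genotype matrix between SNP coding schemes
#'
#' Per-SNP polarity conversion between the coding schemes:
#' \describe{
#'   \item{rare1}{minor allele coded 1: flip every SNP whose allele-1
#'     frequency exceeds 0.5. The recommended coding for biplots and CA1
#'     arrangement.}
#'   \item{common1}{major allele coded 1: the elementwise complement of
#'     rare1 away from frequency ties.}
#'   \item{vcf_ref}{the designated reference Individual's allele coded 0 on
#'     every SNP, so its row becomes all zeros (the VCF coding concept).}
#'   \item{random_mixed}{each SNP flipped independently with
#'     \code{flipProbability}, seeded; emulates arbitrary mixed codings.}
#'   \item{explicit}{a user-supplied polarity mask.}
#' }
#' SNPs at exactly frequency 0.5 have no rare allele; for rare1/common1 they
#' are left unflipped and reported in \code{ties}.
#'
#' @param x a binary-mode [GenotypeMatrix-class].
#' @param scheme one of \code{"rare1"}, \code{"common1"}, \code{"vcf_ref"},
#'   \code{"random_mixed"}, \code{"explicit"}.
#' @param referenceId Individual id for \code{vcf_ref}.
#' @param seed integer seed, mandatory for \code{random_mixed}.
#' @param flipProbability flip probability for \code{random_mixed}
#'   (default 0.5).
#' @param mask logical mask for \code{explicit}.
#' @return list with elements \code{genotypes} (recoded
#'   [GenotypeMatrix-class] with its coding tag set), \code{mask} (logical:
#'   which SNPs were complemented), and \code{ties} (SNP ids at frequency
#'   exactly 0.5).
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0, 1, 1, 1, 1, 0), nrow = 3,
#'                      dimnames = list(letters[1:3], c("s1", "s2"))))
#' recodeGenotypes(gm, "rare1")$mask
#' @export
recodeGenotypes <- function(x, scheme = c("rare1", "common1", "vcf_ref",
                                          "random_mixed", "explicit"),
                            referenceId = NULL, seed = NULL,
                            flipProbability = 0.5, mask = NULL) {
  stopifnot(is(x, "GenotypeMatrix"))
  scheme <- match.arg(scheme)
  if (x@ploidyMode != "binary")
    stop("recoding schemes apply to binary mode; see recodeDiploidRare2()")
  v <- x@values
  freq <- colMeans(v)
  ties <- colnames(v)[abs(freq - 0.5) < .Machine$double.eps^0.5]

  flip <- switch(scheme,
    rare1 = freq > 0.5 + .Machine$double.eps^0.5,
    common1 = freq < 0.5 - .Machine$double.eps^0.5,
    vcf_ref = {
      if (is.null(referenceId) || !referenceId %in% rownames(v))
        stop("vcf_ref requires a referenceId present among the Individuals")
      v[referenceId, ] == 1L
    },
    random_mixed = {
      if (is.null(seed))
        stop("random_mixed requires an explicit seed")
      if (flipProbability < 0 || flipProbability > 1)
        stop("flipProbability must be in [0, 1]")
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(as.integer(seed))
      stats::runif(ncol(v)) < flipProbability
    },
    explicit = {
      if (is.null(mask))
        stop("explicit scheme requires a mask")
      as.logical(mask)
    })

  codingTag <- switch(scheme,
    rare1 = "rare1", common1 = "common1",
    vcf_ref = paste0("vcf:", referenceId),
    random_mixed = "mixed", explicit = "mixed")
  out <- applyPolarityMask(x, flip, coding = codingTag)
  list(genotypes = out, mask = unname(flip), ties = ties)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Recode a diploid 0/1/2 matrix so the rarest homozygote is 2
#'
#' Per SNP, if the homozygote coded 2 is more common than the homozygote
#' coded 0, the column is complemented (\code{x -> 2 - x}); heterozygotes
#' (1) are unchanged. Homozygote-count ties are left unflipped.
#'
#' @param x a diploid-mode [GenotypeMatrix-class].
#' @return list with \code{genotypes} and the logical \code{mask} of flipped
#'   SNPs.
#' @export
recodeDiploidRare2 <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (x@ploidyMode != "diploid")
    stop("recodeDiploidRare2 requires diploid mode")
  v <- x@values
  n2 <- colSums(v == 2L)
  n0 <- colSums(v == 0L)
  flip <- n2 > n0
  out <- applyPolarityMask(x, flip, coding = "rare1")
  list(genotypes = out, mask = unname(flip))
}

#' Read or write a polarity mask
#'
#' Serialized as a two-column TSV: snp_id, flipped (0/1).
#'
#' @param mask logical vector, one entry per SNP.
#' @param snpIds SNP identifiers parallel to \code{mask}.
#' @param path file path.
#' @return \code{readPolarityMask}: named logical vector.
#' @export
writePolarityMask <- function(mask, snpIds, path) {
  utils::write.table(
    data.frame(id = snpIds, flipped = as.integer(mask)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePolarityMask
#' @export
readPolarityMask <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses =
                             c("character", "integer"))
  stats::setNames(tab[[2L]] == 1L, tab[[1L]])
}
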