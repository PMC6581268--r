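# standardized residuals of the independence model:
# S = diag(r)^-1/2 (P - r c') diag(c)^-1/2, P = X / sum(X)
.caResiduals <- function(v) {
  tot <- sum(v)
  if (tot <= 0) stop("all-zero matrix")
  p <- v / tot
  r <- rowSums(p); c <- colSums(p)
  if (any(r == 0))
    stop("zero-margin Individual(s): ",
         paste(utils::head(rownames(v)[r == 0], 5L), collapse = ", "))
  if (any(c == 0))
    stop("zero-margin SNP(s): ",
         paste(utils::head(colnames(v)[c == 0], 5L), collapse = ", "))
  s <- (p - outer(r, c)) / sqrt(outer(r, c))
  list(s = s, r = r, c = c)
}

#' Correspondence analysis of a genotype matrix
#'
#' Correspondence analysis (reciprocal averaging) of a nonnegative matrix
#' via SVD of the standardized residuals of the independence model, which
#' excludes the trivial margins axis by construction and yields singular
#' values of at most 1. Standard coordinates divide the singular vectors by
#' the square roots of the margins. CA uses chi-squared rather than
#' Euclidean distances, which is why CA1 ordering (unlike PCA) concentrates
#' large values along the matrix diagonal for gradient-structured data.
#'
#' The \code{"power"} method runs power iteration on the standardized
#' residual matrix, converging to the first axis only; it matches the SVD
#' route to within \code{tol} and is the classical fast path when only CA1
#' is needed.
#'
#' @param x a [GenotypeMatrix-class] or nonnegative matrix; every
#'   Individual and SNP must have at least one 1.
#' @param k number of nontrivial axes to keep (default 2; \code{"power"}
#'   computes only the first).
#' @param method \code{"svd"} (default) or \code{"power"}.
#' @param tol convergence tolerance for the power method.
#' @param maxIter iteration cap for the power method.
#' @return A [GenotypeCa-class].
#' @examples
#' block <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
#'                c(0, 0, 1, 1), c(0, 0, 1, 1))
#' dimnames(block) <- list(paste0("i", 1:4), paste0("s", 1:4))
#' singularValues(caDecompose(GenotypeMatrix(block), k = 1))
#' @export
caDecompose <- function(x, k = 2L, method = c("svd", "power"),
                        tol = 1e-10, maxIter = 10000L) {
  method <- match.arg(method)
  v <- .valuesOf(x)
  if (any(v < 0)) stop("correspondence analysis needs nonnegative data")
  res <- .caResiduals(v)
  s <- res$s
  if (method == "power") {
    k <- 1L
    # deterministic start aligned with a left-to-right gradient
    w <- seq_len(ncol(s)) - (ncol(s) + 1) / 2
    w <- w / sqrt(sum(w^2))
    lambda <- 0
    for (it in seq_len(maxIter)) {
      u <- drop(s %*% w)
      nu <- sqrt(sum(u^2))
      if (nu < tol) stop("matrix has no nontrivial correspondence structure")
      u <- u / nu
      wNew <- drop(crossprod(s, u))
      lambdaNew <- sqrt(sum(wNew^2))
      wNew <- wNew / lambdaNew
      if (sum((wNew - w)^2) < tol^2 && abs(lambdaNew - lambda) < tol) {
        w <- wNew; lambda <- lambdaNew
        break
      }
      w <- wNew; lambda <- lambdaNew
      if (it == maxIter)
        stop("power method failed to converge in ", maxIter, " iterations")
    }
    u <- drop(s %*% w) / lambda
    sv <- lambda
    U <- matrix(u, ncol = 1L); W <- matrix(w, ncol = 1L)
  } else {
    dec <- svd(s)
    keep <- which(dec$d > 1e-12)
    if (!length(keep))
      stop("matrix has no nontrivial correspondence structure")
    k <- min(k, length(keep))
    sv <- dec$d[seq_len(k)]
    U <- dec$u[, seq_len(k), drop = FALSE]
    W <- dec$v[, seq_len(k), drop = FALSE]
  }
  al <- .alignSigns(U, W)
  rowCoord <- al$u / sqrt(res$r)
  colCoord <- al$v / sqrt(res$c)
  dimnames(rowCoord) <- list(rownames(v), paste0("CA", seq_len(ncol(U))))
  dimnames(colCoord) <- list(colnames(v), paste0("CA", seq_len(ncol(W))))
  new("GenotypeCa", singularValues = sv, individualCoords = rowCoord,
      snpCoords = colCoord, method = method)
}

#' Diagonal-concentration statistic of a matrix in display order
#'
#' \code{1 - 2 * sum(v * |r~ - c~|) / sum(v)} over normalized display ranks
#' \code{r~ = (row - 0.5)/R}, \code{c~ = (col - 0.5)/C}: 1 when all mass
#' lies exactly on the diagonal, around 0 for structureless mass, negative
#' when mass concentrates in the off-corners.
#'
#' @param v nonnegative matrix, already in the display order to score.
#' @return numeric(1) in [-1, 1].
#' @examples
#' diagonalStatistic(diag(5))  # 1
#' @export
diagonalStatistic <- function(v) {
  v <- as.matrix(v)
  if (sum(v) == 0) stop("all-zero matrix")
  R <- nrow(v); C <- ncol(v)
  rr <- (seq_len(R) - 0.5) / R
  cc <- (seq_len(C) - 0.5) / C
  dev <- abs(outer(rr, cc, "-"))
  1 - 2 * sum(v * dev) / sum(v)
}

.diagStat <- diagonalStatistic

#' Arrange a matrix by ranked CA1 scores
#'
#' Permutes rows and columns into rank order of their first-axis CA scores.
#' For data structured by a single dominant gradient this concentrates the
#' 1s along the matrix diagonal, displaying the joint structure of
#' SNPs-and-Individuals. The direction of the order (which is arbitrary in
#' CA) is fixed by requiring the first arranged row's 1-entries to sit at a
#' smaller mean column rank than the last row's; ties in CA1 scores are
#' broken by original index. A warning is issued unless the coding is
#' rare1, the only coding for which diagonal concentration is expected to
#' succeed.
#'
#' @param x a [GenotypeMatrix-class].
#' @param ca optional precomputed [GenotypeCa-class] (must include axis 1).
#' @return An [ArrangedGenotypes-class].
#' @export
arrangeByCa1 <- function(x, ca = NULL) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (!identical(x@coding, "rare1"))
    warning("CA1 arrangement is expected to display diagonal structure ",
            "only for coding rare1 (current coding: ", x@coding, ")")
  if (is.null(ca)) {
    ca <- tryCatch(caDecompose(x, k = 1L), error = function(e) {
      if (grepl("no nontrivial", conditionMessage(e))) NULL else stop(e)
    })
  }
  if (is.null(ca)) {
    # structureless (independence-model) matrix: keep the received order
    warning("no nontrivial correspondence structure; keeping input order")
    rowOrder <- seq_len(nrow(x@values))
    colOrder <- seq_len(ncol(x@values))
  } else {
    rowOrder <- order(ca@individualCoords[, 1L], seq_len(nrow(x@values)))
    colOrder <- order(ca@snpCoords[, 1L], seq_len(ncol(x@values)))
  }
  v <- x@values[rowOrder, colOrder, drop = FALSE]
  meanColRank <- function(row) {
    ones <- which(row == 1)
    if (!length(ones)) NA_real_ else mean(ones)
  }
  first <- meanColRank(v[1L, ])
  last <- meanColRank(v[nrow(v), ])
  if (!is.na(first) && !is.na(last) && first > last) {
    rowOrder <- rev(rowOrder)
    colOrder <- rev(colOrder)
    v <- x@values[rowOrder, colOrder, drop = FALSE]
  }
  new("ArrangedGenotypes", source = x,
      individualOrder = as.integer(rowOrder),
      snpOrder = as.integer(colOrder),
      concentration = .diagStat(v))
}

#' Diagonal-concentration statistic with a randomization null
#'
#' Measures how strongly the 1s of an arranged matrix concentrate along the
#' diagonal: \code{1 - 2 * sum(v * |r~ - c~|) / sum(v)} with normalized row
#' and column ranks \code{r~ = (rank - 0.5)/R}, \code{c~ = (rank - 0.5)/C}.
#' The statistic is 1 when all mass lies exactly on the diagonal and is
#' invariant under simultaneous reversal of both orders.
#'
#' The null distribution destroys the joint structure while preserving the
#' margins of each SNP: each column of the source matrix is permuted
#' independently, the CA1 arrangement is recomputed, and the statistic
#' recorded. For structured data the observed statistic exceeds the null;
#' for structureless data it is a typical draw from it.
#'
#' @param am an [ArrangedGenotypes-class] (or a [GenotypeMatrix-class],
#'   which is arranged first).
#' @param nullReps number of within-column randomization replicates
#'   (default 0: statistic only).
#' @param seed integer seed for the randomization (required when
#'   \code{nullReps > 0}).
#' @return list with \code{statistic}, \code{nullMean}, \code{nullSd},
#'   \code{exceedance} (proportion of null replicates at or above the
#'   observed statistic), and \code{nullValues}.
#' @export
diagonalConcentration <- function(am, nullReps = 0L, seed = NULL) {
  if (is(am, "GenotypeMatrix"))
    am <- suppressWarnings(arrangeByCa1(am))
  stopifnot(is(am, "ArrangedGenotypes"))
  stat <- am@concentration
  nullValues <- numeric(0)
  if (nullReps > 0L) {
    if (is.null(seed)) stop("a seed is required for the randomization null")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    v <- am@source@values
    for (rep in seq_len(nullReps)) {
      perm <- apply(v, 2L, sample)
      dimnames(perm) <- dimnames(v)
      gm <- new("GenotypeMatrix", values = perm, coding = am@source@coding,
                ploidyMode = am@source@ploidyMode)
      arr <- try(suppressWarnings(arrangeByCa1(gm)), silent = TRUE)
      nullValues[rep] <- if (inherits(arr, "try-error")) NA_real_
        else arr@concentration
    }
    nullValues <- nullValues[!is.na(nullValues)]
  }
  list(statistic = stat,
       nullMean = if (length(nullValues)) mean(nullValues) else NA_real_,
       nullSd = if (length(nullValues) > 1L) stats::sd(nullValues)
                else NA_real_,
       exceedance = if (length(nullValues)) mean(nullValues >= stat)
                    else NA_real_,
       nullValues = nullValues)
}
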