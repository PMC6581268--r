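.splitDialect <- function(lines, dialect) {
  switch(dialect,
    tsv = strsplit(lines, "\t", fixed = TRUE),
    csv = strsplit(lines, ",", fixed = TRUE),
    whitespace = strsplit(trimws(lines), "[ \t]+"),
    stop("unknown dialect: ", dialect))
}

.sniffDialect <- function(line) {
  if (grepl("\t", line)) "tsv" else if (grepl(",", line)) "csv" else "whitespace"
}

.isNumericToken <- function(x) {
  suppressWarnings(!is.na(as.numeric(x)))
}

#' Read a genotype matrix from delimited text
#'
#' Reads a rectangular 0/1 (or 0/1/2) table. A first row whose cells are not
#' all numeric is treated as SNP identifiers, and likewise a non-numeric
#' first column as Individual identifiers; otherwise identifiers are
#' generated. A missing-value token or non-integer cell is a hard error
#' naming the offending row and column (these matrices must be complete).
#'
#' @param path file path.
#' @param dialect \code{"auto"} (default, sniffed from the first line),
#'   \code{"tsv"}, \code{"csv"}, or \code{"whitespace"}.
#' @param orientation \code{"individuals_in_rows"} (internal convention,
#'   default) or \code{"snps_in_rows"}; the latter is transposed on entry.
#' @param coding coding tag to record (default \code{"unknown"}).
#' @return A [GenotypeMatrix-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\ts1\ts2", "a\t0\t1", "b\t1\t1", "c\t0\t0"), tf)
#' readGenotypeMatrix(tf)
#' @export
readGenotypeMatrix <- function(path,
                               dialect = c("auto", "tsv", "csv", "whitespace"),
                               orientation = c("individuals_in_rows",
                                               "snps_in_rows"),
                               coding = "unknown") {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop("empty file: ", path)
  if (dialect == "auto")
    dialect <- .sniffDialect(lines[[1L]])
  cells <- .splitDialect(lines, dialect)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop(sprintf("non-rectangular input: line %d has %d fields, expected %d",
                 which(widths != widths[1L])[1L],
                 widths[widths != widths[1L]][1L], widths[1L]))
  tab <- do.call(rbind, cells)

  headerRow <- !all(.isNumericToken(tab[1L, -1L]))
  bodyFirstRow <- if (headerRow) 2L else 1L
  idCol <- !all(.isNumericToken(tab[bodyFirstRow:nrow(tab), 1L]))

  rowIds <- if (idCol) tab[bodyFirstRow:nrow(tab), 1L] else NULL
  colIds <- if (headerRow) tab[1L, (if (idCol) 2L else 1L):ncol(tab)] else NULL
  body <- tab[bodyFirstRow:nrow(tab),
              (if (idCol) 2L else 1L):ncol(tab), drop = FALSE]

  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric or missing cell '%s' at data row %d (%s), column %d (%s)",
      body[bad[1L], bad[2L]], bad[1L],
      if (is.null(rowIds)) "unnamed" else rowIds[bad[1L]], bad[2L],
      if (is.null(colIds)) "unnamed" else colIds[bad[2L]]))
  }
  if (any(num != round(num))) {
    bad <- which(num != round(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer cell at data row %d, column %d",
                 bad[1L], bad[2L]))
  }
  gm <- GenotypeMatrix(num, individualIds = rowIds, snpIds = colIds,
                       coding = coding)
  if (orientation == "snps_in_rows") gm <- transposeGenotypes(gm)
  gm
}

#' Write a genotype matrix as delimited text
#'
#' Writes the matrix with a header row of SNP identifiers and a first column
#' of Individual identifiers, so that [readGenotypeMatrix()] round-trips
#' bit-identically.
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output file path.
#' @param dialect \code{"tsv"} (default), \code{"csv"}, or
#'   \code{"whitespace"}.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeMatrix <- function(x, path, dialect = c("tsv", "csv",
                                                     "whitespace")) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect, tsv = "\t", csv = ",", whitespace = " ")
  v <- genotypeValues(x)
  header <- paste(c("id", colnames(v)), collapse = sep)
  body <- vapply(seq_len(nrow(v)), function(r)
    paste(c(rownames(v)[r], v[r, ]), collapse = sep), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Transpose a genotype matrix
#'
#' Swaps the Individual and SNP axes. Used to adapt external
#' SNPs-in-rows layouts to the internal Individuals-in-rows convention.
#'
#' @param x a [GenotypeMatrix-class].
#' @return A [GenotypeMatrix-class] with axes swapped.
#' @export
transposeGenotypes <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  new("GenotypeMatrix", values = t(x@values), coding = x@coding,
      ploidyMode = x@ploidyMode)
}

#' Shift raw genotype codes
#'
#' Applies a bijective code-to-code mapping to every entry, e.g. shifting a
#' received 1/2 coding to the internal 0/1 convention.
#'
#' @param x a [GenotypeMatrix-class] or integer matrix.
#' @param mapping named numeric vector, names are observed codes, values the
#'   replacement codes, e.g. \code{c("1" = 0, "2" = 1)}.
#' @return An object of the same kind as \code{x} with codes replaced.
#' @examples
#' m <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("a","b"), c("s1","s2")))
#' genotypeValues(shiftCodes(GenotypeMatrix(m), c("1" = 0, "2" = 1)))
#' @export
shiftCodes <- function(x, mapping) {
  v <- if (is(x, "GenotypeMatrix")) x@values else as.matrix(x)
  observed <- sort(unique(as.vector(v)))
  if (!all(as.character(observed) %in% names(mapping)))
    stop("mapping is missing observed code(s): ",
         paste(setdiff(as.character(observed), names(mapping)),
               collapse = ", "))
  if (anyDuplicated(mapping[as.character(observed)]))
    stop("mapping is not a bijection on the observed value set")
  out <- matrix(mapping[as.character(v)], nrow = nrow(v),
                dimnames = dimnames(v))
  if (is(x, "GenotypeMatrix"))
    GenotypeMatrix(out, coding = x@coding, ploidyMode = "auto")
  else out
}

#' Validate a genotype matrix
#'
#' Reporting-only scan: monomorphic SNPs (allele-1 frequency 0 or 1, which
#' standardized PCA variants and correspondence analysis cannot accept),
#' duplicated identifiers, value-set violations, and missing entries.
#'
#' @param x a [GenotypeMatrix-class] or numeric matrix.
#' @return A list of class \code{"snppcaValidation"} with elements
#'   \code{monomorphicSnps}, \code{duplicatedIndividualIds},
#'   \code{duplicatedSnpIds}, \code{valueViolations}, \code{missingCount}.
#' @export
validateGenotypes <- function(x) {
  v <- if (is(x, "GenotypeMatrix")) x@values else as.matrix(x)
  allowed <- if (is(x, "GenotypeMatrix") && x@ploidyMode == "diploid")
    0:2 else 0:1
  mono <- colnames(v)[apply(v, 2L, function(col)
    all(col == col[1L], na.rm = TRUE))]
  rep <- list(
    monomorphicSnps = if (is.null(mono)) character(0) else mono,
    duplicatedIndividualIds =
      unique(rownames(v)[duplicated(rownames(v))]),
    duplicatedSnpIds = unique(colnames(v)[duplicated(colnames(v))]),
    valueViolations = sum(!(v %in% allowed), na.rm = TRUE),
    missingCount = sum(is.na(v)))
  class(rep) <- "snppcaValidation"
  rep
}

#' @export
print.snppcaValidation <- function(x, ...) {
  cat("Genotype validation report\n")
  cat("  monomorphic SNPs:", length(x$monomorphicSnps), "\n")
  cat("  duplicated Individual ids:",
      length(x$duplicatedIndividualIds), "\n")
  cat("  duplicated SNP ids:", length(x$duplicatedSnpIds), "\n")
  cat("  value-set violations:", x$valueViolations, "\n")
  cat("  missing entries:", x$missingCount, "\n")
  invisible(x)
}

#' Export a validation report as JSON
#'
#' @param report result of [validateGenotypes()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeValidationReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read or write group assignments
#'
#' A group assignment is a two-column TSV (id, label) mapping Individuals or
#' SNPs to named groups, represented in R as a data.frame with columns
#' \code{id} and \code{label} and an \code{"axis"} attribute.
#'
#' @param path file path.
#' @param axis \code{"individuals"} or \code{"snps"}.
#' @return \code{readGroupAssignment}: the assignment data.frame.
#' @export
readGroupAssignment <- function(path, axis = c("individuals", "snps")) {
  axis <- match.arg(axis)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) != 2L)
    stop("group file must have exactly two columns (id, label)")
  groupAssignment(tab[[1L]], tab[[2L]], axis)
}

#' @rdname readGroupAssignment
#' @param ids,labels parallel id and group-label vectors.
#' @export
groupAssignment <- function(ids, labels, axis = c("individuals", "snps")) {
  axis <- match.arg(axis)
  if (length(ids) != length(labels))
    stop("ids and labels must have the same length")
  if (anyDuplicated(ids))
    stop("duplicated ids in group assignment")
  out <- data.frame(id = as.character(ids), label = as.character(labels),
                    stringsAsFactors = FALSE)
  attr(out, "axis") <- axis
  out
}

#' @rdname readGroupAssignment
#' @param groups an assignment data.frame.
#' @export
writeGroupAssignment <- function(groups, path) {
  utils::write.table(groups[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
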