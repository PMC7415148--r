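# Reading vendor tables and writing residue tables.
#
# Input is delimited text (comma, tab or semicolon; sniffed when not given).
# Spreadsheets should be exported to CSV/TSV first. Numeric output is
# written with "%.17g" so that write -> read is the exact identity on
# doubles.

.sniffSep <- function(path, skipRows) {
  lines <- readLines(path, n = skipRows + 2L, warn = FALSE)
  if (length(lines) <= skipRows) stop("file has no rows: ", path)
  probe <- lines[skipRows + 1L]
  counts <- c("\t" = lengths(regmatches(probe, gregexpr("\t", probe))),
              "," = lengths(regmatches(probe, gregexpr(",", probe))),
              ";" = lengths(regmatches(probe, gregexpr(";", probe))))
  if (max(counts) == 0L)
    return("\t")                     # single-column file; separator is moot
  best <- counts == max(counts)
  if (sum(best) > 1L)
    stop("cannot sniff the field separator of '", path,
         "'; pass sep = explicitly")
  names(counts)[best]
}

#' Read a lipid abundance table from delimited text
#'
#' Reads a table with lipid identifiers in one column (the first, by
#' default), one sample per remaining column and a single header row, into a
#' \linkS4class{LipidTable}. Vendor exports often carry preamble lines above
#' the header; \code{skipRows} drops them. The field separator is sniffed
#' among tab, comma and semicolon unless given. Trailing all-empty rows and
#' unnamed all-empty columns are removed. Columns are not type-screened
#' here; \code{\link{makeResiduesTable}} does that.
#'
#' @param path path to a delimited text file.
#' @param skipRows number of preamble rows to skip before the header
#'   (default 0).
#' @param nameColumn 1-based position of the identifier column (default 1).
#' @param sep field separator; \code{NULL} (default) sniffs it.
#' @param decimalComma set TRUE for European exports using "," as the
#'   decimal mark (then the separator cannot be ",").
#' @return a \linkS4class{LipidTable}.
#' @export
readLipidTable <- function(path, skipRows = 0, nameColumn = 1, sep = NULL,
                           decimalComma = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (is.null(sep)) sep <- .sniffSep(path, skipRows)
  if (decimalComma && sep == ",")
    stop("decimal commas require a non-comma field separator")
  df <- utils::read.table(path, header = TRUE, sep = sep, skip = skipRows,
                          dec = if (decimalComma) "," else ".",
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          blank.lines.skip = TRUE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty table: ", path)
  # trailing unnamed, all-empty columns (spreadsheet export artefacts)
  emptyCol <- vapply(seq_along(df), function(j) {
    nm <- names(df)[j]
    v <- df[[j]]
    (is.na(nm) || !nzchar(nm) || grepl("^V[0-9]+$", nm)) &&
      all(is.na(v) | !nzchar(trimws(as.character(v))))
  }, logical(1))
  df <- df[, !emptyCol, drop = FALSE]
  if (nameColumn < 1L || nameColumn > ncol(df))
    stop("name column ", nameColumn, " out of range (table has ",
         ncol(df), " columns)")
  ids <- trimws(as.character(df[[nameColumn]]))
  rest <- df[, -nameColumn, drop = FALSE]
  # trailing all-empty rows
  emptyRow <- (is.na(ids) | !nzchar(ids)) &
    apply(rest, 1L, function(r)
      all(is.na(r) | !nzchar(trimws(as.character(r)))))
  ids <- ids[!emptyRow]
  rest <- rest[!emptyRow, , drop = FALSE]
  if (length(ids) == 0L) stop("empty table: ", path)
  LipidTable(ids, rest)
}

#' Write a residue table as delimited text
#'
#' Writes the header row of sample names (first field \code{"residue"}),
#' then one row per residue label, tab-separated by default. Values are
#' written at full double precision, so \code{\link{readResidueTable}} on
#' the written file reproduces the table exactly, labels and values.
#'
#' @param table a \linkS4class{ResidueTable}.
#' @param path output file path.
#' @param sep single-character field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
writeResidueTable <- function(table, path, sep = "\t") {
  stopifnot(is(table, "ResidueTable"),
            is.character(sep), nchar(sep) == 1L)
  m <- abundance(table)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c(
    paste(c("residue", colnames(m)), collapse = sep),
    vapply(seq_len(nrow(m)), function(i)
      paste(c(rownames(m)[i], fmt(m[i, ])), collapse = sep), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeResidueTable
#' @export
readResidueTable <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  lab <- as.character(df[[1L]])
  parts <- strsplit(lab, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("not residue labels: ", paste(lab[bad], collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- lab
  ResidueTable(m,
               vapply(parts, function(p) as.integer(p[1L]), integer(1)),
               vapply(parts, function(p) as.integer(p[2L]), integer(1)))
}
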