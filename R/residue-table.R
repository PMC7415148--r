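# Conversion of analyte x sample tables into residue x sample tables by
# index-weighted allocation.

.noSampleColumns <- function() {
  stop(structure(
    class = c("noSampleColumnsError", "error", "condition"),
    list(message = "no numeric sample columns remain after screening",
         call = NULL)))
}

.nothingExtracted <- function(n) {
  stop(structure(
    class = c("nothingExtractedError", "error", "condition"),
    list(message = sprintf(
      "nothing extracted: all %d rows were unparseable", n), call = NULL)))
}

# A column counts as numeric when every non-missing cell is a number or
# parses as one (vendor exports often store numbers as text); empty strings
# count as missing. Returns list(data=<numeric DataFrame>, dropped=<names>).
.screenColumns <- function(sampleData) {
  isNum <- logical(ncol(sampleData))
  coerced <- vector("list", ncol(sampleData))
  for (j in seq_len(ncol(sampleData))) {
    col <- sampleData[[j]]
    if (is.numeric(col)) {
      isNum[j] <- TRUE
      coerced[[j]] <- as.numeric(col)
    } else if (is.logical(col) && all(is.na(col))) {
      isNum[j] <- TRUE               # an all-missing column carries no type
      coerced[[j]] <- as.numeric(col)
    } else if (is.character(col) || is.factor(col)) {
      v <- trimws(as.character(col))
      v[!nzchar(v)] <- NA_character_
      num <- suppressWarnings(as.numeric(v))
      if (all(is.na(num) == is.na(v))) {
        isNum[j] <- TRUE
        coerced[[j]] <- num
      }
    }
  }
  if (any(isNum)) {
    args <- stats::setNames(coerced[isNum], colnames(sampleData)[isNum])
    kept <- do.call(S4Vectors::DataFrame, c(args, list(check.names = FALSE)))
  } else {
    kept <- S4Vectors::DataFrame(matrix(numeric(0), nrow = nrow(sampleData),
                                        ncol = 0))
  }
  list(data = kept, dropped = colnames(sampleData)[!isNum])
}

#' Drop non-numeric columns from a lipid table
#'
#' Restricts a \linkS4class{LipidTable} to columns whose every value is
#' numeric, dropping leftover label or annotation columns that cannot carry
#' abundance information. Missing values are permitted (they are missing, not
#' text), and a text column in which every non-missing cell parses as a
#' decimal number is retained after coercion. Dropped column names are
#' reported via \code{message()} and kept in the result's metadata.
#'
#' @param table a \linkS4class{LipidTable}.
#' @return the screened \linkS4class{LipidTable}; the dropped column names
#'   are in \code{attr(x, "droppedColumns")}.
#' @examples
#' lt <- LipidTable("FA(18:3)",
#'                  data.frame(S1 = 1, note = "keep?", S2 = 2))
#' dropNonNumericColumns(lt)
#' @export
dropNonNumericColumns <- function(table) {
  stopifnot(is(table, "LipidTable"))
  scr <- .screenColumns(table@sampleData)
  if (ncol(scr$data) == 0L) .noSampleColumns()
  if (length(scr$dropped))
    message("dropped non-numeric column(s): ",
            paste(scr$dropped, collapse = ", "))
  out <- LipidTable(table@identifiers, scr$data)
  attr(out, "droppedColumns") <- scr$dropped
  out
}

#' Convert a lipid abundance table into a residue abundance table
#'
#' The core conversion: each row's identifier is parsed
#' (\code{\link{parseIdentifier}}), expanded into index-weighted residues
#' (\code{\link{weightedResidues}}), and each occurrence adds
#' \code{weight * abundance} into its residue's output row, sample by sample.
#' Units are unchanged. Non-numeric columns are dropped first; unparseable
#' rows are skipped with a warning and counted, never fatal; missing input
#' cells contribute nothing. Duplicate identifiers are processed
#' independently and sum into the same residue rows.
#'
#' @param table a \linkS4class{LipidTable}, or a data.frame whose first
#'   column holds the lipid identifiers.
#' @param dialect identifier dialect, \code{"refmet"} (default) or
#'   \code{"generic"}; see \code{\link{parseIdentifier}}.
#' @param dropAmbiguous discard all ambiguous mass isobars (index > 1)
#'   instead of allocating 1/index per occurrence?
#' @param maxCarbons if set, residues with more carbons than this (inclusive
#'   bound: \code{maxCarbons} itself is kept) are excluded; the conventional
#'   cutoff for named fatty acids is 30.
#' @param lexicon a \linkS4class{Lexicon} for natural-language names.
#' @return a \linkS4class{ResidueTable}. Its \code{metadata()} records
#'   \code{rowsRead}, \code{rowsSkipped}, \code{skippedIdentifiers} and
#'   \code{droppedColumns}.
#' @examples
#' lt <- LipidTable(c("FA(18:3)", "PG(P-22:1/18:1)/PG(O-22:2/18:1)"),
#'                  data.frame(S1 = c(10, 4)))
#' abundance(makeResiduesTable(lt))
#' @export
makeResiduesTable <- function(table, dialect = c("refmet", "generic"),
                              dropAmbiguous = FALSE, maxCarbons = NULL,
                              lexicon = defaultLexicon()) {
  dialect <- match.arg(dialect)
  if (is.data.frame(table)) {
    if (ncol(table) < 2L)
      stop("a lipid table needs an identifier column plus sample columns")
    table <- LipidTable(table[[1L]], table[-1L])
  }
  stopifnot(is(table, "LipidTable"))
  if (length(table@identifiers) < 1L)
    stop("empty lipid table")
  scr <- .screenColumns(table@sampleData)
  if (ncol(scr$data) == 0L) .noSampleColumns()
  m <- as.matrix(as.data.frame(scr$data))
  ids <- table@identifiers
  n <- length(ids)

  labels <- character(0)
  carbonsV <- integer(0)
  dbV <- integer(0)
  contrib <- vector("list", n)
  contribLabels <- vector("list", n)
  skippedIds <- character(0)
  for (i in seq_len(n)) {
    lip <- tryCatch(
      parseIdentifier(ids[i], dialect = dialect, lexicon = lexicon),
      lipidParseError = function(e) NULL)
    if (is.null(lip)) {
      skippedIds <- c(skippedIds, ids[i])
      next
    }
    wr <- weightedResidues(lip, dropAmbiguous = dropAmbiguous)
    if (!nrow(wr)) next
    if (!is.null(maxCarbons)) {
      wr <- wr[wr$carbons <= maxCarbons, , drop = FALSE]
      if (!nrow(wr)) next
    }
    amt <- m[i, ]
    amt[is.na(amt)] <- 0          # missing cells contribute nothing
    contrib[[i]] <- wr$weight %o% amt
    contribLabels[[i]] <- wr$label
    new <- !wr$label %in% labels & !duplicated(wr$label)
    if (any(new)) {
      labels <- c(labels, wr$label[new])
      carbonsV <- c(carbonsV, wr$carbons[new])
      dbV <- c(dbV, wr$doubleBonds[new])
    }
  }
  if (length(skippedIds) == n) .nothingExtracted(n)
  if (length(skippedIds))
    warning(sprintf("skipped %d unparseable row(s): %s",
                    length(skippedIds),
                    paste(unique(skippedIds), collapse = ", ")),
            call. = FALSE)

  out <- matrix(0, nrow = length(labels), ncol = ncol(m),
                dimnames = list(labels, colnames(m)))
  for (i in seq_len(n)) {
    if (is.null(contrib[[i]])) next
    idx <- match(contribLabels[[i]], labels)
    for (k in seq_along(idx))
      out[idx[k], ] <- out[idx[k], ] + contrib[[i]][k, ]
  }
  rt <- ResidueTable(out, carbonsV, dbV)
  metadata(rt) <- list(rowsRead = n,
                       rowsSkipped = length(skippedIds),
                       skippedIdentifiers = skippedIds,
                       droppedColumns = scr$dropped)
  rt
}

#' Filter a residue table by chain length
#'
#' Removes residues longer than \code{maxCarbons} carbon atoms (the bound is
#' inclusive: a \code{30:0} residue survives \code{maxCarbons = 30}). Long
#' sum-composition totals -- artefacts of unresolved mass isobars such as the
#' 42:2 reported from unresolved sphingomyelins -- are the usual casualties;
#' the longest fatty acids distinguishable by name are C-24 species, so 30 is
#' a conservative conventional cutoff.
#'
#' @param table a \linkS4class{ResidueTable}.
#' @param maxCarbons positive integer, the inclusive carbon-count bound.
#' @return the filtered \linkS4class{ResidueTable}; retained rows are
#'   unchanged.
#' @examples
#' lt <- LipidTable(c("FA(24:0)", "SM 42:2"), data.frame(S1 = c(1, 1)))
#' rt <- makeResiduesTable(lt, dialect = "generic")
#' residueLabels(filterMaxCarbons(rt, 30))
#' @export
filterMaxCarbons <- function(table, maxCarbons) {
  stopifnot(is(table, "ResidueTable"),
            is.numeric(maxCarbons), length(maxCarbons) == 1L,
            maxCarbons >= 1)
  table[rowData(table)$carbons <= maxCarbons, ]
}
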