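#' @rdname Residue-class
setMethod("carbons", "Residue", function(x) x@carbons)

#' @rdname Residue-class
setMethod("doubleBonds", "Residue", function(x) x@doubleBonds)

#' @rdname Residue-class
setMethod("linkType", "Residue", function(x) x@link)

#' @rdname Residue-class
setMethod("residueLabel", "Residue",
          function(x) paste0(x@carbons, ":", x@doubleBonds))

#' @rdname isSaturated
setMethod("isSaturated", "Residue", function(x) x@doubleBonds == 0L)

#' @rdname isSaturated
setMethod("isSaturated", "ResidueTable", function(x) {
  db <- rowData(x)$doubleBonds
  names(db) <- rownames(x)
  db == 0L
})

#' @rdname Lipid-class
setMethod("ambiguityIndex", "Lipid", function(x) length(x@alternatives))

#' @rdname Lipid-class
setMethod("rawName", "Lipid", function(x) x@rawName)

#' @rdname Lipid-class
setMethod("alternatives", "Lipid", function(x) x@alternatives)

#' @rdname LipidTable-class
setMethod("identifiers", "LipidTable", function(x) x@identifiers)

#' @rdname LipidTable-class
setMethod("sampleNames", "LipidTable", function(x) colnames(x@sampleData))

#' @rdname LipidTable-class
setMethod("dim", "LipidTable",
          function(x) c(length(x@identifiers), ncol(x@sampleData)))

#' @rdname ResidueTable-class
setMethod("residueLabels", "ResidueTable", function(x) rownames(x))

#' @rdname ResidueTable-class
setMethod("abundance", "ResidueTable", function(x) assay(x, "abundance"))

#' @rdname ResidueTable-class
setMethod("sampleNames", "ResidueTable", function(x) colnames(x))

#' @rdname Residue-class
setMethod("carbons", "ResidueTable", function(x) {
  v <- rowData(x)$carbons
  names(v) <- rownames(x)
  v
})

#' @rdname Residue-class
setMethod("doubleBonds", "ResidueTable", function(x) {
  v <- rowData(x)$doubleBonds
  names(v) <- rownames(x)
  v
})

#' @rdname GroupDesign-class
setMethod("sampleGroups", "GroupDesign", function(x) x@sampleToGroup)

#' @rdname GroupDesign-class
setMethod("baselinePairs", "GroupDesign", function(x) x@baselinePairs)

setMethod("show", "Residue", function(object) {
  extra <- if (object@link == "acyl") "" else paste0(" [", object@link, "]")
  cat("Residue ", residueLabel(object), extra, "\n", sep = "")
})

setMethod("show", "Lipid", function(object) {
  cat("Lipid: ", object@rawName, "\n", sep = "")
  cat("  ambiguity index: ", ambiguityIndex(object), "\n", sep = "")
  for (alt in object@alternatives) {
    lab <- vapply(alt@chains, residueLabel, character(1))
    cat("  ", alt@classToken,
        if (alt@sumComposition) " (sum composition): " else ": ",
        paste(lab, collapse = " / "), "\n", sep = "")
  }
})

setMethod("show", "LipidTable", function(object) {
  cat("LipidTable with ", length(object@identifiers), " lipids and ",
      ncol(object@sampleData), " columns\n", sep = "")
  n <- min(5L, length(object@identifiers))
  if (n)
    cat("  ", paste(utils::head(object@identifiers, n), collapse = ", "),
        if (length(object@identifiers) > n) ", ..." else "", "\n", sep = "")
})

setMethod("show", "Lexicon", function(object) {
  cat("Lexicon: ", nrow(object@trivialNames), " trivial names, ",
      length(object@carbonRoots), " carbon roots (C",
      min(object@carbonRoots), "-C", max(object@carbonRoots), "), ",
      length(object@unsaturationSuffixes), " unsaturation suffixes\n",
      sep = "")
})

setMethod("show", "GroupDesign", function(object) {
  cat("GroupDesign: ", length(object@sampleToGroup), " samples in ",
      length(unique(object@sampleToGroup)), " groups; ",
      length(object@baselinePairs), " baseline pairs\n", sep = "")
})

setMethod("show", "PipelineReport", function(object) {
  cat("Residue extraction run\n")
  cat("  rows read:        ", object@rowsRead, "\n", sep = "")
  cat("  rows skipped:     ", object@rowsSkipped,
      if (object@rowsSkipped)
        paste0(" (", paste(object@skippedIdentifiers, collapse = ", "), ")")
      else "", "\n", sep = "")
  cat("  columns dropped:  ", length(object@droppedColumns),
      if (length(object@droppedColumns))
        paste0(" (", paste(object@droppedColumns, collapse = ", "), ")")
      else "", "\n", sep = "")
  cat("  residues emitted: ", object@residuesEmitted, "\n", sep = "")
  cat("  output:           ", object@outputPath, "\n", sep = "")
})

#' @describeIn LipidTable-class flatten to a base data.frame (identifier
#'   column \code{Lipid} first, then the sample columns).
#' @param row.names,optional,... passed on as in
#'   \code{\link[base]{as.data.frame}}.
#' @export
as.data.frame.LipidTable <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  cbind(data.frame(Lipid = x@identifiers, stringsAsFactors = FALSE),
        as.data.frame(x@sampleData))
}
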