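#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.LINK_TYPES <- c("acyl", "ether", "plasmalogen")

#' Residue: a single fatty acid moiety
#'
#' A fatty acyl (or alkyl) chain summarized as carbons:double-bonds, the
#' atomic output unit of residue extraction. The link type records how the
#' chain is attached to the lipid backbone (ester bond, ether bond from an
#' \code{O-} prefix, or vinyl-ether bond from a \code{P-} prefix); it is
#' metadata only and does not enter residue identity, so a plasmalogen-linked
#' \code{P-22:1} chain and a plain acyl \code{22:1} chain aggregate into the
#' same \code{22:1} residue.
#'
#' @slot carbons integer(1), number of carbon atoms (>= 1).
#' @slot doubleBonds integer(1), number of C=C unsaturations
#'   (0 <= doubleBonds < carbons).
#' @slot link character(1), one of \code{"acyl"}, \code{"ether"},
#'   \code{"plasmalogen"}.
#'
#' @examples
#' r <- Residue(18, 3)
#' residueLabel(r)
#' isSaturated(r)
#' @exportClass Residue
setClass("Residue",
  representation(carbons = "integer", doubleBonds = "integer",
                 link = "character"))

setValidity("Residue", function(object) {
  msg <- character(0)
  if (length(object@carbons) != 1L || is.na(object@carbons) ||
      object@carbons < 1L)
    msg <- c(msg, "'carbons' must be a single integer >= 1")
  if (length(object@doubleBonds) != 1L || is.na(object@doubleBonds) ||
      object@doubleBonds < 0L)
    msg <- c(msg, "'doubleBonds' must be a single integer >= 0")
  if (length(msg) == 0L && object@doubleBonds >= object@carbons)
    msg <- c(msg, sprintf("a %d-carbon chain cannot carry %d double bonds",
                          object@carbons, object@doubleBonds))
  if (length(object@link) != 1L || !object@link %in% .LINK_TYPES)
    msg <- c(msg, sprintf("'link' must be one of: %s",
                          paste(.LINK_TYPES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @param carbons number of carbon atoms.
#' @param doubleBonds number of C=C double bonds.
#' @param link chain linkage type (\code{"acyl"}, \code{"ether"} or
#'   \code{"plasmalogen"}).
#' @return \code{Residue()} returns a \linkS4class{Residue} object.
#' @rdname Residue-class
#' @export
Residue <- function(carbons, doubleBonds, link = "acyl") {
  new("Residue", carbons = as.integer(carbons),
      doubleBonds = as.integer(doubleBonds), link = link)
}

#' AlternativeID: one candidate identification of a lipid
#'
#' One of possibly several alternative identifications carried by a lipid
#' identifier. Mass isobars (distinct species indistinguishable by mass in
#' the assay) are reported as several AlternativeIDs in one
#' \linkS4class{Lipid}. A sum-composition alternative gives only the total
#' carbons:double-bonds of all chains combined (e.g. the 42:2 of
#' \code{SM 42:2}) and carries that total as its single chain.
#'
#' @slot classToken character(1), the lipid class shorthand (e.g. "PG",
#'   "PC", "SM", "FA").
#' @slot chains list of \linkS4class{Residue}, the parsed chains (never
#'   empty; exactly one element when \code{sumComposition} is TRUE).
#' @slot sumComposition logical(1), TRUE when the identifier gives only a
#'   total C:D rather than per-chain values.
#' @exportClass AlternativeID
setClass("AlternativeID",
  representation(classToken = "character", chains = "list",
                 sumComposition = "logical"))

setValidity("AlternativeID", function(object) {
  msg <- character(0)
  if (length(object@classToken) != 1L || is.na(object@classToken))
    msg <- c(msg, "'classToken' must be a single string")
  if (length(object@chains) < 1L)
    msg <- c(msg, "'chains' must be non-empty")
  if (!all(vapply(object@chains, is, logical(1), class2 = "Residue")))
    msg <- c(msg, "every chain must be a Residue")
  if (length(object@sumComposition) != 1L || is.na(object@sumComposition))
    msg <- c(msg, "'sumComposition' must be TRUE or FALSE")
  if (isTRUE(object@sumComposition) && length(object@chains) != 1L)
    msg <- c(msg, "a sum-composition alternative has exactly one (total) chain")
  if (length(msg)) msg else TRUE
})

AlternativeID <- function(classToken, chains, sumComposition = FALSE) {
  new("AlternativeID", classToken = classToken, chains = chains,
      sumComposition = sumComposition)
}

#' Lipid: a parsed lipid identifier
#'
#' The result of parsing one lipid identifier string: the raw name, one or
#' more alternative identifications, and the ambiguity index. The index is
#' the number of alternatives; residue counts and amounts attributed to this
#' lipid are divided by it, so unambiguous lipids (index 1) contribute full
#' weight and an n-way mass isobar contributes 1/n per occurrence.
#'
#' @slot rawName character(1), the identifier as given.
#' @slot alternatives list of \linkS4class{AlternativeID} (>= 1).
#'
#' @examples
#' lip <- parseIdentifier("PG(P-22:1/18:1)/PG(O-22:2/18:1)")
#' ambiguityIndex(lip)
#' weightedResidues(lip)
#' @exportClass Lipid
setClass("Lipid",
  representation(rawName = "character", alternatives = "list"))

setValidity("Lipid", function(object) {
  msg <- character(0)
  if (length(object@rawName) != 1L || is.na(object@rawName) ||
      !nzchar(object@rawName))
    msg <- c(msg, "'rawName' must be a non-empty string")
  if (length(object@alternatives) < 1L)
    msg <- c(msg, "a Lipid carries at least one alternative identification")
  if (!all(vapply(object@alternatives, is, logical(1),
                  class2 = "AlternativeID")))
    msg <- c(msg, "every alternative must be an AlternativeID")
  if (length(msg)) msg else TRUE
})

Lipid <- function(rawName, alternatives) {
  new("Lipid", rawName = rawName, alternatives = alternatives)
}

#' Lexicon: fatty acid name components
#'
#' Maps natural-language fatty-acid name components to chain composition:
#' trivial name stems ("palmitic", "linolenic", ...), systematic Greek carbon
#' roots ("octadeca", "eicosa", ..., covering chain lengths 2-30) and
#' unsaturation suffixes ("anoic" = 0 through "hexaenoic" = 6 double bonds).
#' The default lexicon ships as a tab-separated data file
#' (\code{system.file("extdata", "fatty_acid_lexicon.tsv", package =
#' "LipidResidues")}) and can be replaced via \code{\link{readLexicon}}, so
#' coverage disputes are data patches, not code changes. Lookup is
#' case-insensitive.
#'
#' @slot trivialNames data.frame with columns stem, carbons, doubleBonds.
#' @slot carbonRoots named integer vector, root stem -> carbon count.
#' @slot unsaturationSuffixes named integer vector, suffix -> double bonds.
#' @exportClass Lexicon
setClass("Lexicon",
  representation(trivialNames = "data.frame", carbonRoots = "integer",
                 unsaturationSuffixes = "integer"))

setValidity("Lexicon", function(object) {
  msg <- character(0)
  tn <- object@trivialNames
  if (!all(c("stem", "carbons", "doubleBonds") %in% names(tn)))
    msg <- c(msg, "trivialNames needs columns stem, carbons, doubleBonds")
  else if (nrow(tn) &&
           (any(tn$carbons < 1) | any(tn$doubleBonds < 0) |
            any(tn$doubleBonds >= tn$carbons)))
    msg <- c(msg, "trivial name values must be valid residues (0 <= D < C)")
  if (!all(2:30 %in% object@carbonRoots))
    msg <- c(msg, "carbonRoots must cover every chain length 2-30")
  if (is.null(names(object@carbonRoots)) ||
      is.null(names(object@unsaturationSuffixes)))
    msg <- c(msg, "roots and suffixes must be named vectors")
  if (length(msg)) msg else TRUE
})

#' LipidTable: analyte-by-sample abundance table
#'
#' The input table of a residue extraction run: one lipid identifier per row
#' (identifiers need not be unique; duplicates are processed independently
#' and summed downstream) and one sample per column. Columns may still be of
#' mixed type at this stage; \code{\link{dropNonNumericColumns}} screens them
#' before extraction. Abundance units are whatever the upstream assay
#' produced (e.g. pmol/ug protein) and are never rescaled.
#'
#' @slot identifiers character vector of lipid identifier strings, one per
#'   row.
#' @slot sampleData a \link[S4Vectors]{DataFrame} of per-sample columns
#'   (same number of rows as identifiers).
#'
#' @examples
#' lt <- LipidTable(c("FA(18:3)", "PC(16:0/18:1)"),
#'                  data.frame(S1 = c(1, 2), S2 = c(3, 4)))
#' identifiers(lt)
#' sampleNames(lt)
#' @exportClass LipidTable
setClass("LipidTable",
  representation(identifiers = "character", sampleData = "DataFrame"))

setValidity("LipidTable", function(object) {
  msg <- character(0)
  if (nrow(object@sampleData) != length(object@identifiers))
    msg <- c(msg, "sampleData must have one row per identifier")
  if (any(is.na(object@identifiers)) || any(!nzchar(object@identifiers)))
    msg <- c(msg, "identifiers must be non-empty strings")
  if (length(msg)) msg else TRUE
})

#' @param identifiers character vector of lipid identifiers.
#' @param sampleData data.frame or DataFrame of sample columns.
#' @return \code{LipidTable()} returns a \linkS4class{LipidTable}.
#' @rdname LipidTable-class
#' @export
LipidTable <- function(identifiers, sampleData) {
  new("LipidTable", identifiers = as.character(identifiers),
      sampleData = as(sampleData, "DataFrame"))
}

#' ResidueTable: residue-by-sample abundance table
#'
#' The output of residue extraction: a \link[SummarizedExperiment]{SummarizedExperiment}
#' with one row per distinct residue label ("C:D", including sum-composition
#' totals such as "42:2"), one column per retained sample, and a single
#' \code{"abundance"} assay of index-weighted aggregated amounts in the same
#' units as the input. Rows are unique and sorted by (carbons, doubleBonds);
#' \code{rowData} carries the two counts.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}; rowData
#'   has integer columns \code{carbons} and \code{doubleBonds}.
#'
#' @examples
#' lt <- LipidTable("FA(18:3)", data.frame(S1 = 10))
#' rt <- makeResiduesTable(lt)
#' residueLabels(rt)
#' abundance(rt)
#' @exportClass ResidueTable
setClass("ResidueTable", contains = "SummarizedExperiment")

setValidity("ResidueTable", function(object) {
  msg <- character(0)
  if (length(SummarizedExperiment::assayNames(object)) != 1L ||
      SummarizedExperiment::assayNames(object)[1L] != "abundance")
    msg <- c(msg, "a ResidueTable has exactly one assay, named 'abundance'")
  rd <- rowData(object)
  if (!all(c("carbons", "doubleBonds") %in% names(rd)))
    return(c(msg, "rowData needs columns carbons and doubleBonds"))
  lab <- if (nrow(rd)) paste0(rd$carbons, ":", rd$doubleBonds)
         else character(0)
  if (nrow(rd) > 0L && !identical(rownames(object), lab))
    msg <- c(msg, "rownames must be the 'C:D' labels from rowData")
  if (anyDuplicated(lab))
    msg <- c(msg, "residue labels must be unique")
  if (is.unsorted(order(rd$carbons, rd$doubleBonds)) ||
      !identical(order(rd$carbons, rd$doubleBonds), seq_along(lab)))
    msg <- c(msg, "rows must be sorted by (carbons, doubleBonds)")
  if (length(msg)) msg else TRUE
})

#' @param abundance numeric matrix, residues in rows, samples in columns.
#' @param carbons,doubleBonds integer vectors, one entry per row of
#'   \code{abundance}.
#' @return \code{ResidueTable()} returns a \linkS4class{ResidueTable}.
#' @rdname ResidueTable-class
#' @export
ResidueTable <- function(abundance, carbons, doubleBonds) {
  carbons <- as.integer(carbons)
  doubleBonds <- as.integer(doubleBonds)
  abundance <- as.matrix(abundance)
  o <- order(carbons, doubleBonds)
  abundance <- abundance[o, , drop = FALSE]
  carbons <- carbons[o]
  doubleBonds <- doubleBonds[o]
  rownames(abundance) <- if (length(carbons))
    paste0(carbons, ":", doubleBonds) else character(0)
  se <- SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = DataFrame(carbons = carbons, doubleBonds = doubleBonds))
  new("ResidueTable", se)
}

#' GroupDesign: sample grouping and per-subject baseline pairing
#'
#' Describes the experimental layout of a residue table: which group each
#' sample belongs to, and (optionally) which sample is the within-subject
#' baseline of each treatment sample, as used for percent-change summaries
#' where every treatment value is compared with the same subject's own
#' baseline measurement.
#'
#' @slot sampleToGroup named character vector, sample name -> group label.
#' @slot baselinePairs named character vector, treatment sample ->
#'   its baseline sample (may be empty).
#'
#' @examples
#' gd <- GroupDesign(c(b1 = "baseline", t1 = "diet"), c(t1 = "b1"))
#' baselinePairs(gd)
#' @exportClass GroupDesign
setClass("GroupDesign",
  representation(sampleToGroup = "character", baselinePairs = "character"))

setValidity("GroupDesign", function(object) {
  msg <- character(0)
  if (length(object@sampleToGroup) && is.null(names(object@sampleToGroup)))
    msg <- c(msg, "sampleToGroup must be named by sample")
  bp <- object@baselinePairs
  if (length(bp)) {
    if (is.null(names(bp)) || any(!nzchar(names(bp))))
      msg <- c(msg, "baselinePairs must be named by treatment sample")
    else {
      known <- names(object@sampleToGroup)
      if (length(known) && !all(c(names(bp), bp) %in% known))
        msg <- c(msg, "baseline pairs must reference known samples")
      if (any(names(bp) == bp))
        msg <- c(msg, "no sample can be its own baseline")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param sampleToGroup named character vector mapping sample -> group.
#' @param baselinePairs named character vector mapping treatment sample ->
#'   baseline sample.
#' @return \code{GroupDesign()} returns a \linkS4class{GroupDesign}.
#' @rdname GroupDesign-class
#' @export
GroupDesign <- function(sampleToGroup, baselinePairs = character(0)) {
  new("GroupDesign", sampleToGroup = sampleToGroup,
      baselinePairs = baselinePairs)
}

#' PipelineReport: summary of a full extraction run
#'
#' Returned by \code{\link{runPipeline}}: counts of rows read, rows skipped
#' as unparseable (with their identifiers), columns dropped as non-numeric,
#' residues emitted, and the output path written.
#'
#' @slot rowsRead integer(1).
#' @slot rowsSkipped integer(1).
#' @slot skippedIdentifiers character vector.
#' @slot droppedColumns character vector.
#' @slot residuesEmitted integer(1).
#' @slot outputPath character(1).
#' @exportClass PipelineReport
setClass("PipelineReport",
  representation(rowsRead = "integer", rowsSkipped = "integer",
                 skippedIdentifiers = "character",
                 droppedColumns = "character",
                 residuesEmitted = "integer", outputPath = "character"))
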