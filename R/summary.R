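# Downstream residue summaries: saturation partition, abundance partition,
# percent change against per-subject baselines.

#' Partition a residue table by saturation
#'
#' Splits a \linkS4class{ResidueTable} into saturated residues (no C=C
#' double bond) and unsaturated residues (one or more). The two parts are an
#' exact partition of the input rows.
#'
#' @param table a \linkS4class{ResidueTable}.
#' @return a list with elements \code{saturated} and \code{unsaturated},
#'   both \linkS4class{ResidueTable}s.
#' @examples
#' lt <- LipidTable(c("FA(16:0)", "FA(18:2)"), data.frame(S1 = c(1, 2)))
#' parts <- splitBySaturation(makeResiduesTable(lt))
#' residueLabels(parts$saturated)
#' @export
splitBySaturation <- function(table) {
  stopifnot(is(table, "ResidueTable"))
  sat <- rowData(table)$doubleBonds == 0L
  list(saturated = table[sat, ], unsaturated = table[!sat, ])
}

#' Partition a residue table by mean abundance
#'
#' Splits residues into abundant and less-abundant at a threshold in the
#' table's own units: a residue is abundant when its grand mean across all
#' samples exceeds the threshold (strictly), otherwise less abundant. The
#' customary threshold for plasma and cell lipidomes is 0.5 in pmol-scale
#' units. Missing values are ignored in the mean.
#'
#' @param table a \linkS4class{ResidueTable}.
#' @param threshold positive abundance threshold, in input units.
#' @return a list with elements \code{abundant} and \code{lessAbundant},
#'   both \linkS4class{ResidueTable}s.
#' @examples
#' lt <- LipidTable(c("FA(16:0)", "FA(24:1)"),
#'                  data.frame(S1 = c(2, 0.1), S2 = c(3, 0.2)))
#' parts <- splitByAbundance(makeResiduesTable(lt), threshold = 0.5)
#' residueLabels(parts$abundant)
#' @export
splitByAbundance <- function(table, threshold = 0.5) {
  stopifnot(is(table, "ResidueTable"),
            is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  means <- rowMeans(abundance(table), na.rm = TRUE)
  hi <- !is.na(means) & means > threshold
  list(abundant = table[hi, ], lessAbundant = table[!hi, ])
}

#' Percent change of each treatment sample versus its own baseline
#'
#' For every treatment sample named in the design's baseline pairing,
#' computes per residue \code{100 * (treatment - baseline) / baseline},
#' comparing each subject only with its own baseline measurement. A residue
#' whose baseline value is zero for a pair yields \code{NA} for that pair,
#' never an infinity. The result is scale-invariant: rescaling all
#' abundances by a positive constant leaves every percent change unchanged.
#'
#' @param table a \linkS4class{ResidueTable} containing both the treatment
#'   and the baseline samples.
#' @param design a \linkS4class{GroupDesign} whose \code{baselinePairs} map
#'   every treatment sample to its baseline sample.
#' @return a \linkS4class{ResidueTable} of percent changes, one column per
#'   treatment sample (values in percent, may be negative or \code{NA}).
#' @examples
#' lt <- LipidTable("FA(18:1)", data.frame(b1 = 2, t1 = 3))
#' gd <- GroupDesign(c(b1 = "baseline", t1 = "diet"), c(t1 = "b1"))
#' abundance(percentChangeVsBaseline(makeResiduesTable(lt), gd))  # +50
#' @export
percentChangeVsBaseline <- function(table, design) {
  stopifnot(is(table, "ResidueTable"), is(design, "GroupDesign"))
  bp <- baselinePairs(design)
  if (!length(bp))
    stop(structure(
      class = c("incompleteDesignError", "error", "condition"),
      list(message = "the design defines no baseline pairs", call = NULL)))
  missingS <- setdiff(unique(c(names(bp), bp)), colnames(table))
  if (length(missingS))
    stop(structure(
      class = c("incompleteDesignError", "error", "condition"),
      list(message = sprintf(
        "baseline pairing references sample(s) absent from the table: %s",
        paste(missingS, collapse = ", ")), call = NULL)))
  m <- abundance(table)
  trt <- m[, names(bp), drop = FALSE]
  base <- m[, unname(bp), drop = FALSE]
  pc <- 100 * (trt - base) / base
  pc[!is.na(base) & base == 0] <- NA_real_
  colnames(pc) <- names(bp)
  out <- ResidueTable(pc, rowData(table)$carbons, rowData(table)$doubleBonds)
  metadata(out) <- c(metadata(table), list(baselinePairs = bp))
  out
}

#' Read a group design file
#'
#' Reads a delimited text file with columns \code{sample}, \code{group} and
#' optionally \code{baseline_sample} (empty where a sample has no baseline,
#' e.g. for the baseline samples themselves) into a
#' \linkS4class{GroupDesign}.
#'
#' @param path path to the design file.
#' @param sep field separator (default tab).
#' @return a \linkS4class{GroupDesign}.
#' @export
readGroupDesign <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("design file needs columns 'sample' and 'group'")
  s2g <- stats::setNames(as.character(df$group), df$sample)
  bp <- character(0)
  if ("baseline_sample" %in% names(df)) {
    keep <- !is.na(df$baseline_sample) & nzchar(df$baseline_sample)
    bp <- stats::setNames(as.character(df$baseline_sample[keep]),
                          df$sample[keep])
  }
  GroupDesign(s2g, bp)
}
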