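# Deterministic synthetic lipidome generator.
#
# Identifiers are drawn from the same grammar the parser accepts (class
# tokens with 1-3 chains, optional O-/P- and sphingoid prefixes, top-level
# isobar alternatives, sum compositions, natural-language names), but the
# ground-truth residue table is assembled directly from the chains the
# generator drew -- never by parsing the strings -- so it is an independent
# oracle for the parsing and allocation code.

.SIM_CLASSES <- c("PC", "PE", "PG", "PI", "PS", "DG", "TG", "CE", "FA")

# Natural-language names with their known chain compositions, written down
# independently of the lexicon data file.
.SIM_COMMON_NAMES <- list(
  list(name = "linolenic acid",         chains = list(c(18L, 3L))),
  list(name = "octadecatrienoic acid",  chains = list(c(18L, 3L))),
  list(name = "palmitic acid",          chains = list(c(16L, 0L))),
  list(name = "hexadecanoic acid",      chains = list(c(16L, 0L))),
  list(name = "oleic acid",             chains = list(c(18L, 1L))),
  list(name = "arachidonic acid",       chains = list(c(20L, 4L))),
  list(name = "lignoceric acid",        chains = list(c(24L, 0L))),
  list(name = "docosahexaenoic acid",   chains = list(c(22L, 6L))),
  list(name = "oleyl oleate",           chains = list(c(18L, 1L), c(18L, 1L))),
  list(name = "stearyl stearate",       chains = list(c(18L, 0L), c(18L, 0L))))

# sample() on a length-1 vector would sample from 1:x; draw positionally
.pick <- function(x) x[sample.int(length(x), 1L)]

.drawChain <- function(carbonRange, doubleBondRange) {
  nC <- .pick(seq(carbonRange[1L], carbonRange[2L]))
  dMax <- min(doubleBondRange[2L], nC - 1L)
  dMin <- min(doubleBondRange[1L], dMax)
  nD <- .pick(seq(dMin, dMax))
  c(nC, nD)
}

.chainToken <- function(chain, allowPrefix) {
  prefix <- ""
  if (allowPrefix && stats::runif(1) < 0.15)
    prefix <- .pick(c("O-", "P-", "d"))
  paste0(prefix, chain[1L], ":", chain[2L])
}

#' Generate a synthetic lipidome with exact ground truth
#'
#' Emits a deterministic synthetic analyte-by-sample table of
#' grammar-generated lipid identifiers together with the exact
#' residue-by-sample table it must reduce to. Identifiers mix plain
#' shorthand (\code{CLASS(chain/...)}, 1-3 chains, occasional O-/P-/d
#' prefixes), two-way mass isobars (both alternatives sharing a chain
#' count, as mass isobars do), sum compositions (\code{"SM 42:2"} style)
#' and natural-language names, in the given proportions. Abundances are
#' log-normal, spanning the conventional 0.5-unit abundant/less-abundant
#' threshold. The ground truth is assembled directly from the chains the
#' generator drew, with 1/index weight per occurrence -- it shares no code
#' with \code{\link{parseIdentifier}} or \code{\link{makeResiduesTable}},
#' so it can serve as an independent oracle for both.
#'
#' The same seed reproduces the output byte for byte.
#'
#' @param nLipids number of lipid rows (default 60).
#' @param nSamples number of sample columns (default 6).
#' @param fractionAmbiguous expected fraction of two-way mass isobars
#'   (default 0.15).
#' @param fractionSumComposition expected fraction of sum-composition
#'   identifiers (default 0.10).
#' @param fractionCommonNames expected fraction of natural-language names
#'   (default 0.10). The three fractions must sum to at most 1; the
#'   remainder is plain shorthand.
#' @param carbonRange integer range of chain lengths (default c(12, 24)).
#' @param doubleBondRange integer range of double-bond counts (default
#'   c(0, 6); capped at carbons - 1 per chain).
#' @param chainRange integer range of chains per lipid (default c(1, 3)).
#' @param abundanceMeanlog,abundanceSdlog log-normal abundance parameters
#'   (defaults log(0.5) and 1.5).
#' @param seed integer random seed; required, so every lipidome is
#'   reproducible.
#' @return a list with elements \code{table} (a \linkS4class{LipidTable}),
#'   \code{truth} (the exact \linkS4class{ResidueTable}) and \code{manifest}
#'   (a data.frame with one row per lipid: identifier, category, ambiguity
#'   index, chain count per alternative, and whether the identifier is
#'   refmet-dialect compatible).
#' @examples
#' sim <- simulateLipidome(nLipids = 10, nSamples = 3, seed = 1)
#' sim$table
#' residueLabels(sim$truth)
#' @export
simulateLipidome <- function(nLipids = 60, nSamples = 6,
                             fractionAmbiguous = 0.15,
                             fractionSumComposition = 0.10,
                             fractionCommonNames = 0.10,
                             carbonRange = c(12, 24),
                             doubleBondRange = c(0, 6),
                             chainRange = c(1, 3),
                             abundanceMeanlog = log(0.5),
                             abundanceSdlog = 1.5,
                             seed) {
  stopifnot(nLipids >= 1, nSamples >= 1,
            fractionAmbiguous >= 0, fractionSumComposition >= 0,
            fractionCommonNames >= 0)
  if (fractionAmbiguous + fractionSumComposition + fractionCommonNames > 1)
    stop("the three category fractions must sum to at most 1")
  if (carbonRange[1L] < 2 || carbonRange[2L] < carbonRange[1L])
    stop("infeasible carbon range")
  if (doubleBondRange[1L] < 0 || doubleBondRange[2L] < doubleBondRange[1L])
    stop("infeasible double-bond range")
  if (chainRange[1L] < 1 || chainRange[2L] < chainRange[1L])
    stop("infeasible chain-count range")
  if (missing(seed)) stop("'seed' is required")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  ids <- character(nLipids)
  category <- character(nLipids)
  index <- integer(nLipids)
  chainsPerAlt <- integer(nLipids)
  # per lipid: list of alternatives, each a list of c(carbons, doubleBonds)
  altChains <- vector("list", nLipids)

  u <- stats::runif(nLipids)
  for (i in seq_len(nLipids)) {
    if (u[i] < fractionCommonNames) {
      pick <- .SIM_COMMON_NAMES[[.pick(seq_along(.SIM_COMMON_NAMES))]]
      ids[i] <- pick$name
      category[i] <- "common_name"
      altChains[[i]] <- list(pick$chains)
    } else if (u[i] < fractionCommonNames + fractionSumComposition) {
      cls <- .pick(c("SM", "PC", "TG"))
      total <- c(.pick(30:44), .pick(0:6))
      ids[i] <- paste0(cls, " ", total[1L], ":", total[2L])
      category[i] <- "sum_composition"
      altChains[[i]] <- list(list(total))
    } else if (u[i] < fractionCommonNames + fractionSumComposition +
                        fractionAmbiguous) {
      cls <- .pick(.SIM_CLASSES)
      k <- .pick(seq(chainRange[1L], chainRange[2L]))
      a1 <- replicate(k, .drawChain(carbonRange, doubleBondRange),
                      simplify = FALSE)
      a2 <- replicate(k, .drawChain(carbonRange, doubleBondRange),
                      simplify = FALSE)
      frag <- function(ch) paste0(
        cls, "(",
        paste(vapply(ch, .chainToken, character(1), allowPrefix = TRUE),
              collapse = "/"), ")")
      ids[i] <- paste0(frag(a1), "/", frag(a2))
      category[i] <- "ambiguous"
      altChains[[i]] <- list(a1, a2)
    } else {
      cls <- .pick(.SIM_CLASSES)
      k <- .pick(seq(chainRange[1L], chainRange[2L]))
      ch <- replicate(k, .drawChain(carbonRange, doubleBondRange),
                      simplify = FALSE)
      ids[i] <- paste0(
        cls, "(",
        paste(vapply(ch, .chainToken, character(1), allowPrefix = TRUE),
              collapse = "/"), ")")
      category[i] <- "plain"
      altChains[[i]] <- list(ch)
    }
    index[i] <- length(altChains[[i]])
    chainsPerAlt[i] <- length(altChains[[i]][[1L]])
  }

  sampleNames <- sprintf("S%02d", seq_len(nSamples))
  abundances <- matrix(
    stats::rlnorm(nLipids * nSamples, abundanceMeanlog, abundanceSdlog),
    nrow = nLipids, dimnames = list(NULL, sampleNames))

  # ---- independent brute-force ground truth ----
  # enumerate alternatives, allocate amount/index per chain occurrence
  truthEnv <- new.env(parent = emptyenv())
  for (i in seq_len(nLipids)) {
    w <- 1 / index[i]
    for (alt in altChains[[i]]) {
      for (chain in alt) {
        lab <- paste0(chain[1L], ":", chain[2L])
        prev <- if (exists(lab, truthEnv)) get(lab, truthEnv)
                else numeric(nSamples)
        assign(lab, prev + w * abundances[i, ], truthEnv)
      }
    }
  }
  labs <- ls(truthEnv)
  cd <- do.call(rbind, strsplit(labs, ":", fixed = TRUE))
  truthM <- do.call(rbind, lapply(labs, get, envir = truthEnv))
  dimnames(truthM) <- list(labs, sampleNames)
  truth <- ResidueTable(truthM, as.integer(cd[, 1L]), as.integer(cd[, 2L]))

  manifest <- data.frame(
    identifier = ids, category = category, index = index,
    chainsPerAlternative = chainsPerAlt,
    refmetCompatible = category %in% c("plain", "ambiguous"),
    stringsAsFactors = FALSE)

  list(table = LipidTable(ids, as.data.frame(abundances)),
       truth = truth, manifest = manifest)
}
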