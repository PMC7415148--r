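# Shorthand lipid identifier parsing.
#
# Grammar, informally:
#   identifier  := alternative ("/" alternative)*        (split at depth 0)
#   alternative := CLASS "(" chain (("/"|"_") chain)* ")"
#                | CLASS " " chain                        (sum composition)
#                | chain                                  (bare FA shorthand)
#                | natural-language name                  (generic dialect)
#   chain       := ("O-"|"P-"|"d"|"t")? digits ":" digits
# A "/" inside parentheses separates chains; a "/" at parenthesis depth zero
# separates alternative identifications of a mass isobar.

.CHAIN_RE <- "^(O-|P-|d|t)?([0-9]+):([0-9]+)$"

#' Split a lipid identifier into its alternative identifications
#'
#' Splits only at \code{"/"} characters at parenthesis-nesting depth zero,
#' never inside \code{(...)}: the identifier
#' \code{"PG(P-22:1/18:1)/PG(O-22:2/18:1)"} names a two-way mass isobar and
#' splits into two fragments, while the slashes between its chains do not
#' split. Joining the fragments back with \code{"/"} reproduces the input.
#'
#' @param name a lipid identifier string.
#' @return character vector of one or more non-empty fragments.
#' @examples
#' splitAlternatives("PG(P-22:1/18:1)/PG(O-22:2/18:1)")
#' splitAlternatives("PC(16:0/18:1)")
#' @export
splitAlternatives <- function(name) {
  if (length(name) != 1L || is.na(name) || !nzchar(name))
    .malformedIdentifier(as.character(name)[1L], "empty identifier")
  chars <- strsplit(name, "", fixed = TRUE)[[1L]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        .malformedIdentifier(name, "unbalanced parentheses")
    } else if (ch == "/" && depth == 0L) cuts <- c(cuts, i)
  }
  if (depth != 0L)
    .malformedIdentifier(name, "unbalanced parentheses")
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  frags <- substring(name, starts, ends)
  if (any(!nzchar(frags)))
    .malformedIdentifier(name, "empty alternative between separators")
  frags
}

#' Parse a single chain token
#'
#' Decodes one chain token of the shorthand grammar into a
#' \linkS4class{Residue}: optional link prefix (\code{O-} ether, \code{P-}
#' plasmalogen/vinyl-ether) or sphingoid-base hydroxylation prefix (\code{d},
#' \code{t}), then carbons, \code{":"}, double bonds. The residue label never
#' carries the prefix -- a \code{P-22:1} chain is reported as \code{22:1} --
#' and the \code{O-}/\code{P-} link survives only as residue metadata.
#'
#' @param token a chain token such as \code{"18:3"}, \code{"P-22:1"} or
#'   \code{"d18:1"}.
#' @return a \linkS4class{Residue}.
#' @examples
#' parseChainToken("P-22:1")
#' parseChainToken("d18:1")
#' @export
parseChainToken <- function(token) {
  if (length(token) != 1L || is.na(token)) .unparseableChain(token)
  tok <- trimws(token)
  m <- regexec(.CHAIN_RE, tok)[[1L]]
  if (m[1L] == -1L) .unparseableChain(token)
  parts <- regmatches(tok, list(m))[[1L]]
  prefix <- parts[2L]
  link <- switch(prefix, "O-" = "ether", "P-" = "plasmalogen", "acyl")
  nC <- as.integer(parts[3L])
  nD <- as.integer(parts[4L])
  if (nC < 1L || nD >= nC)
    .unparseableChain(token)
  Residue(nC, nD, link = link)
}

# One alternative (one fragment of a possibly isobaric identifier).
.parseAlternative <- function(frag, dialect, lexicon) {
  frag <- trimws(frag)
  # CLASS(chain/chain/...) -- the RefMet shorthand core
  m <- regexec("^([^()]+?)\\((.+)\\)$", frag)[[1L]]
  if (m[1L] != -1L) {
    parts <- regmatches(frag, list(m))[[1L]]
    inner <- parts[3L]
    if (!grepl("[()]", inner)) {
      tokens <- trimws(strsplit(inner, "[/_]")[[1L]])
      chains <- lapply(tokens, parseChainToken)
      return(AlternativeID(trimws(parts[2L]), chains))
    }
  }
  if (dialect == "generic") {
    # CLASS C:D -- sum composition (total carbons and double bonds only)
    m <- regexec("^(\\S+)\\s+((O-|P-|d|t)?[0-9]+:[0-9]+)$", frag)[[1L]]
    if (m[1L] != -1L) {
      parts <- regmatches(frag, list(m))[[1L]]
      return(AlternativeID(parts[2L], list(parseChainToken(parts[3L])),
                           sumComposition = TRUE))
    }
    # bare chain shorthand, e.g. "18:1"
    if (grepl(.CHAIN_RE, frag))
      return(AlternativeID("FA", list(parseChainToken(frag))))
    # natural-language ester, e.g. "linoleyl palmitate"
    if (grepl("^\\S+yl\\s+\\S+ate$", .normalizeName(frag)))
      return(AlternativeID("FA", decodeEsterName(frag, lexicon)))
    # natural-language fatty acid name, e.g. "linolenic acid"
    res <- tryCatch(decodeFattyAcidName(frag, lexicon),
                    lipidParseError = function(e) NULL)
    if (!is.null(res))
      return(AlternativeID("FA", list(res)))
  }
  .unparseableLipid(frag, sprintf("no %s-dialect rule matches", dialect))
}

#' Parse a lipid identifier into a Lipid
#'
#' Parses one identifier string into a \linkS4class{Lipid}: the identifier is
#' split into alternative identifications at top-level \code{"/"}, each
#' alternative is decoded into its chains, and the ambiguity index is the
#' number of alternatives (1 for an unambiguous identifier). The
#' \code{refmet} dialect accepts only the strict \code{CLASS(chain/chain)}
#' shorthand; the \code{generic} dialect additionally accepts space-separated
#' sum compositions (\code{"SM 42:2"}), bare chain shorthand (\code{"18:1"})
#' and natural-language fatty acid and ester names, so everything the refmet
#' dialect parses is parsed identically by generic.
#'
#' @param name a lipid identifier string.
#' @param dialect \code{"refmet"} (strict shorthand, the default) or
#'   \code{"generic"}.
#' @param lexicon a \linkS4class{Lexicon} for natural-language names.
#' @return a \linkS4class{Lipid}.
#' @examples
#' parseIdentifier("PG(P-22:1/18:1)/PG(O-22:2/18:1)")
#' parseIdentifier("FA(18:3)")
#' parseIdentifier("SM 42:2", dialect = "generic")
#' @export
parseIdentifier <- function(name, dialect = c("refmet", "generic"),
                            lexicon = defaultLexicon()) {
  dialect <- match.arg(dialect)
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name)))
    .unparseableLipid(as.character(name)[1L], "empty identifier")
  name <- trimws(name)
  frags <- splitAlternatives(name)
  alts <- lapply(frags, .parseAlternative, dialect = dialect,
                 lexicon = lexicon)
  Lipid(rawName = name, alternatives = alts)
}

#' Index-weighted residues of a parsed lipid
#'
#' Expands a \linkS4class{Lipid} into one row per chain occurrence across all
#' its alternatives, each carrying weight 1/index. An unambiguous lipid
#' (index 1) contributes its residues with full weight; for an n-way mass
#' isobar every occurrence is counted 1/n times, so a residue present in all
#' alternatives still sums to weight 1 while residues unique to one
#' alternative sum to 1/n. With \code{dropAmbiguous = TRUE} any lipid with
#' index > 1 contributes nothing, discarding ambiguous mass isobars while
#' retaining residues from unambiguous lipids.
#'
#' Occurrences of the same label are deliberately not merged here; summing is
#' the aggregation step of \code{\link{makeResiduesTable}}.
#'
#' @param lipid a \linkS4class{Lipid}.
#' @param dropAmbiguous discard lipids with ambiguity index > 1?
#' @return a data.frame with columns \code{label}, \code{carbons},
#'   \code{doubleBonds}, \code{link}, \code{sumComposition} and
#'   \code{weight}, one row per chain occurrence (possibly zero rows).
#' @examples
#' lip <- parseIdentifier("PG(P-22:1/18:1)/PG(O-22:2/18:1)")
#' wr <- weightedResidues(lip)
#' tapply(wr$weight, wr$label, sum)  # 18:1 -> 1.0, 22:1 and 22:2 -> 0.5
#' @export
weightedResidues <- function(lipid, dropAmbiguous = FALSE) {
  stopifnot(is(lipid, "Lipid"))
  idx <- ambiguityIndex(lipid)
  empty <- data.frame(label = character(0), carbons = integer(0),
                      doubleBonds = integer(0), link = character(0),
                      sumComposition = logical(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  if (dropAmbiguous && idx > 1L) return(empty)
  rows <- lapply(alternatives(lipid), function(alt) {
    data.frame(
      label = vapply(alt@chains, residueLabel, character(1)),
      carbons = vapply(alt@chains, carbons, integer(1)),
      doubleBonds = vapply(alt@chains, doubleBonds, integer(1)),
      link = vapply(alt@chains, linkType, character(1)),
      sumComposition = rep(alt@sumComposition, length(alt@chains)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$weight <- rep(1 / idx, nrow(out))
  rownames(out) <- NULL
  out
}
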