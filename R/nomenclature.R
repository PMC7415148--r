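# Natural-language fatty acid name decoding.
#
# Two routes into the lexicon: trivial names are looked up whole
# ("linolenic" -> 18:3); systematic names are decomposed into a Greek carbon
# root plus an unsaturation suffix ("octadecatrienoic" = octadeca + trienoic
# -> 18:3). Both routes yield identical labels for the same species.

.normalizeName <- function(name) {
  s <- tolower(trimws(name))
  gsub("[[:space:]]+", " ", s)
}

# Positional/geometric isomer decorations carry no information at the
# carbons:double-bonds resolution, so they are stripped: parenthesized
# locant blocks like "(9z,12z)" and leading prefixes like "9-", "cis-",
# "all-cis-", "alpha-", "omega-3-".
.stripLocants <- function(s) {
  s <- gsub("\\([^)]*\\)", "", s)
  s <- gsub("(^|[ -])(all|cis|trans|alpha|beta|gamma|delta|omega|n|[0-9]+[ez]?)-",
            "\\1", s)
  # repeat to peel stacked prefixes such as "all-cis-9,12-"
  repeat {
    s2 <- gsub("(^|[ -])(all|cis|trans|alpha|beta|gamma|delta|omega|n|[0-9]+[ez]?)-",
               "\\1", s)
    s2 <- gsub("^[0-9]+(,[0-9]+)*[ -]?", "", s2)
    if (identical(s2, s)) break
    s <- s2
  }
  trimws(gsub("[[:space:]]+", " ", s))
}

# Root lookup with vowel elision: systematic names drop the root's final "a"
# before a vowel-initial suffix ("octadeca" + "anoic" -> "octadecanoic"), so
# a remainder matches a root either verbatim or after restoring the "a".
.matchRoot <- function(rem, lexicon) {
  roots <- lexicon@carbonRoots
  hit <- match(rem, names(roots))
  if (is.na(hit)) hit <- match(paste0(rem, "a"), names(roots))
  if (is.na(hit)) NA_integer_ else unname(roots[hit])
}

.decodeSystematic <- function(stem, lexicon) {
  suffixes <- lexicon@unsaturationSuffixes
  for (suf in names(suffixes)[order(-nchar(names(suffixes)))]) {
    if (!endsWith(stem, suf)) next
    rem <- substr(stem, 1L, nchar(stem) - nchar(suf))
    nC <- .matchRoot(rem, lexicon)
    if (is.na(nC)) next
    nD <- unname(suffixes[suf])
    if (nD >= nC) next
    return(Residue(nC, nD))
  }
  NULL
}

.decodeTrivial <- function(stem, lexicon) {
  tn <- lexicon@trivialNames
  hit <- match(stem, tn$stem)
  if (is.na(hit)) NULL else Residue(tn$carbons[hit], tn$doubleBonds[hit])
}

#' Decode a natural-language fatty acid name
#'
#' Turns a fatty acid name into its \linkS4class{Residue}. Trivial names
#' ("linolenic acid", "palmitic acid", "arachidonic acid") are resolved
#' through the lexicon; systematic names ("octadecatrienoic acid") are
#' decomposed into carbon root + unsaturation suffix. The trailing "acid" is
#' optional, matching is case-insensitive, and positional isomer decorations
#' (e.g. "9Z") are ignored. Trivial and systematic routes agree wherever both
#' name the same species: "octadecatrienoic acid", "linolenic acid" and the
#' shorthand FA(18:3) all denote the 18:3 residue.
#'
#' @param name a single fatty acid name.
#' @param lexicon a \linkS4class{Lexicon}; defaults to the bundled one.
#' @return a \linkS4class{Residue}.
#' @examples
#' decodeFattyAcidName("octadecatrienoic acid")
#' decodeFattyAcidName("linolenic acid")
#' decodeFattyAcidName("arachidonic acid")
#' @seealso \code{\link{decodeEsterName}}, \code{\link{parseIdentifier}}
#' @export
decodeFattyAcidName <- function(name, lexicon = defaultLexicon()) {
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name)))
    .unparseableName(as.character(name)[1L], "empty name")
  s <- .stripLocants(.normalizeName(name))
  s <- sub(" acid$", "", s)
  res <- .decodeTrivial(s, lexicon)
  if (is.null(res)) res <- .decodeSystematic(s, lexicon)
  if (is.null(res))
    .unparseableName(name, "neither a known trivial name nor root+suffix")
  res
}

# Decode one ester component. kind "acid" handles "-ate" stems
# (palmitate -> palmitic; octadecanoate -> octadecanoic); kind "alcohol"
# handles "-yl" stems (linoleyl -> linoleic; octadecenyl -> octadecenoic;
# plain alkyls like octadecyl resolve through the carbon root, saturated).
.decodeEsterComponent <- function(stem, kind, lexicon) {
  res <- .decodeTrivial(paste0(stem, "ic"), lexicon)
  if (!is.null(res)) return(res)
  if (kind == "acid") {
    res <- .decodeSystematic(paste0(stem, "ic"), lexicon)
    if (!is.null(res)) return(res)
  }
  res <- .decodeSystematic(paste0(stem, "oic"), lexicon)
  if (!is.null(res)) return(res)
  nC <- .matchRoot(stem, lexicon)
  if (!is.na(nC)) return(Residue(nC, 0L))
  NULL
}

#' Decode a fatty acid ester name
#'
#' Decodes a two-word ester name of the form "<alcohol>-yl <acid>-ate"
#' ("linoleyl palmitate", "oleyl oleate") into its two fatty acid residues,
#' one from the acid component and one from the fatty alcohol component.
#' Both components are resolved through the same lexicon as
#' \code{\link{decodeFattyAcidName}}. The two residues are returned sorted by
#' (carbons, doubleBonds) for determinism.
#'
#' @inheritParams decodeFattyAcidName
#' @param name a two-word ester name.
#' @return a list of two \linkS4class{Residue} objects.
#' @examples
#' decodeEsterName("linoleyl palmitate")
#' decodeEsterName("oleyl oleate")
#' @export
decodeEsterName <- function(name, lexicon = defaultLexicon()) {
  s <- .stripLocants(.normalizeName(name))
  words <- strsplit(s, " ", fixed = TRUE)[[1L]]
  if (length(words) != 2L)
    .unparseableName(name, "an ester name has exactly two words")
  if (!endsWith(words[1L], "yl") || !endsWith(words[2L], "ate"))
    .unparseableName(name, "expected '<...>yl <...>ate'")
  alcoholStem <- substr(words[1L], 1L, nchar(words[1L]) - 2L)
  acidStem <- substr(words[2L], 1L, nchar(words[2L]) - 3L)
  acid <- .decodeEsterComponent(acidStem, "acid", lexicon)
  if (is.null(acid))
    .unparseableName(name, sprintf("unknown acid component '%s'", words[2L]))
  alcohol <- .decodeEsterComponent(alcoholStem, "alcohol", lexicon)
  if (is.null(alcohol))
    .unparseableName(name,
                     sprintf("unknown alcohol component '%s'", words[1L]))
  out <- list(acid, alcohol)
  o <- order(vapply(out, carbons, integer(1)),
             vapply(out, doubleBonds, integer(1)))
  out[o]
}
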