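.lexiconCache <- new.env(parent = emptyenv())

#' Read a fatty acid name lexicon
#'
#' Loads a lexicon from a tab-separated file with columns
#' \code{kind} (\code{trivial}, \code{root} or \code{suffix}), \code{stem},
#' \code{carbons} and \code{double_bonds}. Trivial rows map a whole name stem
#' to a chain composition; root rows map a systematic Greek carbon root to a
#' chain length; suffix rows map an unsaturation suffix to a double-bond
#' count. Stems are lowercased on load so lookup is case-insensitive.
#'
#' @param path path to the lexicon file; the default is the lexicon bundled
#'   with the package (chain lengths 2-30, unsaturation 0-6, ~45 trivial
#'   names).
#' @return a \linkS4class{Lexicon}.
#' @examples
#' lex <- defaultLexicon()
#' lex
#' @export
readLexicon <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("kind", "stem", "carbons", "double_bonds")
  if (!all(need %in% names(raw)))
    stop("lexicon file needs columns: ", paste(need, collapse = ", "))
  raw$stem <- tolower(trimws(raw$stem))
  triv <- raw[raw$kind == "trivial", ]
  roots <- raw[raw$kind == "root", ]
  suff <- raw[raw$kind == "suffix", ]
  carbonRoots <- as.integer(roots$carbons)
  names(carbonRoots) <- roots$stem
  suffixes <- as.integer(suff$double_bonds)
  names(suffixes) <- suff$stem
  new("Lexicon",
      trivialNames = data.frame(stem = triv$stem,
                                carbons = as.integer(triv$carbons),
                                doubleBonds = as.integer(triv$double_bonds),
                                stringsAsFactors = FALSE),
      carbonRoots = carbonRoots,
      unsaturationSuffixes = suffixes)
}

#' @rdname readLexicon
#' @export
defaultLexicon <- function() {
  if (!exists("default", envir = .lexiconCache)) {
    path <- system.file("extdata", "fatty_acid_lexicon.tsv",
                        package = "LipidResidues", mustWork = TRUE)
    assign("default", readLexicon(path), envir = .lexiconCache)
  }
  get("default", envir = .lexiconCache)
}
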