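test_that("trivial and systematic names decode to the same residues", {
  # same chemical species through either route -> identical label
  pairs <- list(
    c("linolenic acid", "octadecatrienoic acid", "18:3"),
    c("palmitic acid", "hexadecanoic acid", "16:0"),
    c("stearic acid", "octadecanoic acid", "18:0"),
    c("oleic acid", "octadecenoic acid", "18:1"),
    c("arachidic acid", "eicosanoic acid", "20:0"),
    c("behenic acid", "docosanoic acid", "22:0"),
    c("lignoceric acid", "tetracosanoic acid", "24:0"))
  for (p in pairs) {
    expect_identical(residueLabel(decodeFattyAcidName(p[1])), p[3])
    expect_identical(residueLabel(decodeFattyAcidName(p[2])), p[3])
  }
})

test_that("well-known fatty acid names decode to their published residues", {
  expect_identical(residueLabel(decodeFattyAcidName("arachidonic acid")),
                   "20:4")
  expect_identical(residueLabel(decodeFattyAcidName("docosahexaenoic acid")),
                   "22:6")
  expect_identical(residueLabel(decodeFattyAcidName("nervonic acid")), "24:1")
  # trailing "acid" is optional, lookup is case/whitespace-insensitive
  expect_identical(residueLabel(decodeFattyAcidName("  Linolenic   ACID ")),
                   "18:3")
  expect_identical(residueLabel(decodeFattyAcidName("palmitoleic")), "16:1")
  # positional/geometric decorations are ignored
  expect_identical(
    residueLabel(decodeFattyAcidName("all-cis-9,12-octadecadienoic acid")),
    "18:2")
})

test_that("every root+suffix combination in the lexicon decodes", {
  lex <- defaultLexicon()
  roots <- lex@carbonRoots
  suffixes <- lex@unsaturationSuffixes
  for (r in names(roots)) {
    for (s in names(suffixes)) {
      nC <- unname(roots[r])
      nD <- unname(suffixes[s])
      # systematic names elide the root's final "a" before a vowel
      stem <- if (substr(s, 1, 1) %in% c("a", "e"))
        paste0(sub("a$", "", r), s) else paste0(r, s)
      name <- paste(stem, "acid")
      if (nD < nC) {
        res <- decodeFattyAcidName(name)
        expect_identical(carbons(res), nC)
        expect_identical(doubleBonds(res), nD)
      } else {
        # more double bonds than bonds available cannot be a residue
        expect_error(decodeFattyAcidName(name), class = "lipidParseError")
      }
    }
  }
})

test_that("unrecognized names raise a classed unparseable-name error", {
  expect_error(decodeFattyAcidName("unobtainic acid"),
               class = "unparseableNameError")
  expect_error(decodeFattyAcidName(""), class = "unparseableNameError")
  err <- tryCatch(decodeFattyAcidName("gibberish acid"),
                  error = function(e) e)
  expect_match(conditionMessage(err), "gibberish")
})

test_that("ester names decode into their acid and alcohol residues", {
  # symmetric esters
  expect_identical(vapply(decodeEsterName("oleyl oleate"), residueLabel, ""),
                   c("18:1", "18:1"))
  expect_identical(
    vapply(decodeEsterName("stearyl stearate"), residueLabel, ""),
    c("18:0", "18:0"))
  # mixed ester: a 16:0 from the palmitate acid plus the C18 alcohol residue
  lp <- decodeEsterName("linoleyl palmitate")
  expect_length(lp, 2L)
  labs <- vapply(lp, residueLabel, "")
  expect_identical(sum(labs == "16:0"), 1L)
  expect_identical(vapply(lp, carbons, integer(1))[labs != "16:0"], 18L)
  # systematic components work too
  expect_identical(
    vapply(decodeEsterName("hexadecyl octadecanoate"), residueLabel, ""),
    c("16:0", "18:0"))
  expect_identical(
    vapply(decodeEsterName("octadecenyl hexadecanoate"), residueLabel, ""),
    c("16:0", "18:1"))
})

test_that("ester decoding always yields two valid residues, sorted", {
  combos <- expand.grid(
    alcohol = c("oleyl", "stearyl", "palmityl", "linoleyl", "myristyl"),
    acid = c("palmitate", "oleate", "stearate", "arachidonate"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    res <- decodeEsterName(paste(combos$alcohol[i], combos$acid[i]))
    expect_length(res, 2L)
    for (r in res) {
      expect_true(carbons(r) >= 1L)
      expect_true(doubleBonds(r) >= 0L && doubleBonds(r) < carbons(r))
    }
    cs <- vapply(res, carbons, integer(1))
    ds <- vapply(res, doubleBonds, integer(1))
    expect_true(cs[1] < cs[2] || (cs[1] == cs[2] && ds[1] <= ds[2]))
  }
  expect_error(decodeEsterName("linoleyl"), class = "unparseableNameError")
  expect_error(decodeEsterName("fooyl barate"),
               class = "unparseableNameError")
})

test_that("saturation is zero double bonds", {
  expect_true(isSaturated(Residue(16, 0)))
  expect_false(isSaturated(Residue(18, 2)))
  expect_true(isSaturated(decodeFattyAcidName("lignoceric acid")))
})

test_that("residue invariants are enforced by the class", {
  expect_error(Residue(0, 0), "carbons")
  expect_error(Residue(18, 18))         # doubleBonds < carbons
  expect_error(Residue(18, -1))
  expect_error(Residue(18, 1, link = "ester"))
  expect_identical(residueLabel(Residue(8, 1)), "8:1")  # no padding
})

test_that("a replacement lexicon file can be loaded and used", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("kind\tstem\tcarbons\tdouble_bonds",
               "suffix\tanoic\tNA\t0",
               "suffix\tenoic\tNA\t1",
               paste0("root\t", c("etha", "propa", "buta", "penta", "hexa",
                                  "hepta", "octa", "nona", "deca", "undeca",
                                  "dodeca", "trideca", "tetradeca",
                                  "pentadeca", "hexadeca", "heptadeca",
                                  "octadeca", "nonadeca", "eicosa",
                                  "heneicosa", "docosa", "tricosa",
                                  "tetracosa", "pentacosa", "hexacosa",
                                  "heptacosa", "octacosa", "nonacosa",
                                  "triaconta"),
                      "\t", c(2:30), "\tNA"),
               "trivial\tcustomic\t17\t1"), path)
  lex <- readLexicon(path)
  expect_identical(residueLabel(decodeFattyAcidName("customic acid", lex)),
                   "17:1")
  # the trimmed lexicon no longer knows polyunsaturation suffixes
  expect_error(decodeFattyAcidName("octadecatrienoic acid", lex),
               class = "unparseableNameError")
})
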