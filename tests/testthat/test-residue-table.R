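test_that("non-numeric columns are dropped, numeric-as-text is retained", {
  lt <- LipidTable(
    c("FA(18:3)", "PC(16:0/18:1)"),
    data.frame(S1 = c(1.5, 2), note = c("a", "b"), S2 = c(3, 4),
               asText = c("1.5", "2.25"), stringsAsFactors = FALSE))
  expect_message(out <- dropNonNumericColumns(lt), "note")
  expect_identical(sampleNames(out), c("S1", "S2", "asText"))
  expect_identical(attr(out, "droppedColumns"), "note")
  expect_identical(out@sampleData$asText, c(1.5, 2.25))  # coerced
  # missing values are missing, not text
  lt2 <- LipidTable("FA(18:3)",
                    data.frame(S1 = NA_real_, S2 = "", S3 = "7",
                               stringsAsFactors = FALSE))
  out2 <- dropNonNumericColumns(lt2)
  expect_identical(sampleNames(out2), c("S1", "S2", "S3"))
})

test_that("column screening is idempotent and errors when nothing remains", {
  lt <- LipidTable(c("a", "b"),
                   data.frame(S1 = c(1, 2), txt = c("x", "y"),
                              stringsAsFactors = FALSE))
  once <- suppressMessages(dropNonNumericColumns(lt))
  twice <- dropNonNumericColumns(once)
  expect_identical(identifiers(once), identifiers(twice))
  expect_identical(as.data.frame(once), as.data.frame(twice))
  allText <- LipidTable("a", data.frame(txt = "x", stringsAsFactors = FALSE))
  expect_error(dropNonNumericColumns(allText),
               class = "noSampleColumnsError")
  expect_error(suppressMessages(makeResiduesTable(allText)),
               class = "noSampleColumnsError")
})

test_that("single unambiguous lipids pass amounts through with weight 1", {
  lt <- LipidTable("FA(18:3)", data.frame(S1 = 10.0))
  rt <- makeResiduesTable(lt)
  expect_identical(residueLabels(rt), "18:3")
  expect_identical(unname(abundance(rt)[1, 1]), 10.0)
})

test_that("a two-way isobar splits amounts by the index", {
  lt <- LipidTable("PG(P-22:1/18:1)/PG(O-22:2/18:1)", data.frame(S1 = 4.0))
  rt <- makeResiduesTable(lt)
  m <- abundance(rt)
  expect_identical(m["18:1", "S1"], 4.0)   # in both alternatives: 2 x 4/2
  expect_identical(m["22:1", "S1"], 2.0)   # one alternative only: 4/2
  expect_identical(m["22:2", "S1"], 2.0)
  # discarding ambiguous isobars leaves nothing from this lipid
  rt2 <- makeResiduesTable(lt, dropAmbiguous = TRUE)
  expect_identical(nrow(rt2), 0L)
})

test_that("duplicate identifiers sum into the same residue rows", {
  lt <- LipidTable(c("FA(18:3)", "FA(18:3)"), data.frame(S1 = c(1, 2)))
  rt <- makeResiduesTable(lt)
  expect_identical(unname(abundance(rt)["18:3", "S1"]), 3.0)
})

test_that("missing cells contribute nothing", {
  lt <- LipidTable(c("FA(18:3)", "PC(18:3/16:0)"),
                   data.frame(S1 = c(NA, 2), S2 = c(5, NA)))
  m <- abundance(makeResiduesTable(lt))
  expect_identical(m["18:3", "S1"], 2.0)   # NA row adds nothing
  expect_identical(m["18:3", "S2"], 5.0)
  expect_identical(m["16:0", "S2"], 0.0)   # only contributor was missing
})

test_that("rows are sorted by carbons then double bonds, labels unique", {
  lt <- LipidTable(c("PC(18:1/16:0)", "FA(16:1)", "FA(4:0)"),
                   data.frame(S1 = c(1, 1, 1)))
  rt <- makeResiduesTable(lt)
  expect_identical(residueLabels(rt), c("4:0", "16:0", "16:1", "18:1"))
  rd <- as.data.frame(SummarizedExperiment::rowData(rt))
  expect_false(is.unsorted(rd$carbons))
})

test_that("row permutation does not change the residue table", {
  sim <- simulateLipidome(nLipids = 30, nSamples = 3, seed = 23)
  df <- as.data.frame(sim$table)
  rt1 <- makeResiduesTable(df, dialect = "generic")
  perm <- sample(seq_len(nrow(df)))
  rt2 <- makeResiduesTable(df[perm, ], dialect = "generic")
  expect_identical(residueLabels(rt1), residueLabels(rt2))
  expect_equal(abundance(rt1), abundance(rt2))
})

test_that("mass is conserved when all alternatives share a chain count", {
  # two chains per lipid everywhere -> output total = 2 x input total
  sim <- simulateLipidome(nLipids = 25, nSamples = 4,
                          fractionAmbiguous = 0.4,
                          fractionSumComposition = 0,
                          fractionCommonNames = 0,
                          chainRange = c(2, 2), seed = 29)
  rt <- makeResiduesTable(sim$table, dialect = "generic")
  expect_equal(unname(colSums(abundance(rt))),
               unname(2 * colSums(simAbundances(sim))))
})

test_that("dropAmbiguous equals pre-filtering to index-1 rows", {
  sim <- simulateLipidome(nLipids = 40, nSamples = 3,
                          fractionAmbiguous = 0.35, seed = 31)
  df <- as.data.frame(sim$table)
  viaFlag <- makeResiduesTable(df, dialect = "generic",
                               dropAmbiguous = TRUE)
  keep <- sim$manifest$index == 1L
  viaFilter <- makeResiduesTable(df[keep, ], dialect = "generic")
  expect_identical(residueLabels(viaFlag), residueLabels(viaFilter))
  expect_equal(abundance(viaFlag), abundance(viaFilter))
})

test_that("the carbon cutoff is inclusive and drops long sum compositions", {
  lt <- LipidTable(c("FA(24:0)", "SM 42:2", "FA(30:0)", "FA(31:0)"),
                   data.frame(S1 = rep(1, 4)))
  rt <- makeResiduesTable(lt, dialect = "generic")
  expect_identical(residueLabels(filterMaxCarbons(rt, 30)),
                   c("24:0", "30:0"))
  expect_identical(residueLabels(filterMaxCarbons(rt, 100)),
                   residueLabels(rt))   # larger than any row: identity
  kept <- filterMaxCarbons(rt, 30)
  expect_identical(abundance(kept),
                   abundance(rt)[residueLabels(kept), , drop = FALSE])
  # same cutoff applied inside makeResiduesTable
  rt30 <- makeResiduesTable(lt, dialect = "generic", maxCarbons = 30)
  expect_identical(residueLabels(rt30), c("24:0", "30:0"))
})

test_that("unparseable rows are skipped, counted and named, never fatal", {
  lt <- LipidTable(c("FA(18:3)", "total protein"), data.frame(S1 = c(1, 99)))
  expect_warning(rt <- makeResiduesTable(lt), "total protein")
  expect_identical(residueLabels(rt), "18:3")
  md <- S4Vectors::metadata(rt)
  expect_identical(md$rowsSkipped, 1L)
  expect_identical(md$skippedIdentifiers, "total protein")
  allBad <- LipidTable(c("??", "!!"), data.frame(S1 = c(1, 2)))
  expect_error(makeResiduesTable(allBad), class = "nothingExtractedError")
})
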