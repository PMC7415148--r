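---
title: "Extracting fatty acid residues from lipid identifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting fatty acid residues from lipid identifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LipidResidues)
```

## The problem

Lipidomics assays quantify molecular lipids, but the identifiers they report
mix resolutions: fully resolved species (`PC(16:0/18:1)`), sum compositions
where only the total chain makeup is known (`SM 42:2`), unresolved mass
isobars reported as joined alternatives
(`PG(P-22:1/18:1)/PG(O-22:2/18:1)`), and occasionally plain-language names
("linolenic acid", "linoleyl palmitate"). Residue-level questions — how
saturated is this lipidome, which chain lengths shift under a diet — need
all of these reduced to a common unit: the fatty acid residue,
carbons:double-bonds. This package does that reduction and aggregates whole
abundance tables into residue tables.

## The model

### Residues and identity

A residue is a chain summarized as `C:D`. Link chemistry (ester vs ether
`O-` vs vinyl-ether `P-`) and sphingoid hydroxylation (`d`/`t`) are parsed
and retained as metadata but deliberately excluded from residue identity:
the assay-level questions the residue unit serves do not distinguish a
22:1 alkenyl chain from a 22:1 acyl chain, and sum compositions could never
carry the distinction anyway. So `P-22:1` aggregates as `22:1`.

### The ambiguity index

An identifier that joins $i$ alternative identifications at top level
describes one measured amount that could belong to any of $i$ isobaric
species. Rather than picking a winner or discarding the row, every residue
occurrence is weighted $1/i$: residues common to all alternatives keep full
weight, residues unique to one alternative get $1/i$ of the amount. For
`PG(P-22:1/18:1)/PG(O-22:2/18:1)` ($i = 2$): 18:1 sums to 1, while 22:1 and
22:2 sum to 0.5 each. The rule applies uniformly to any $i \ge 2$. The
alternative policy, `dropAmbiguous = TRUE`, discards every $i > 1$ lipid and
keeps full-weight residues from unambiguous ones; it is exactly equivalent
to pre-filtering the input to index-1 rows (a tested invariant).

A `/` separates alternatives only at parenthesis-nesting depth zero; inside
parentheses it (or `_`, a common vendor variant) separates chains. Splitting
and rejoining at depth zero reproduces the identifier byte for byte.

### The name lexicon

Natural-language decoding uses a data-file lexicon, not code: trivial stems
("palmitic" → 16:0), systematic Greek carbon roots ("octadeca" → 18,
covering lengths 2–30) and unsaturation suffixes ("anoic" → 0 …
"hexaenoic" → 6). Systematic decomposition tries suffixes longest-first and
restores the root's elided final "a" ("octadecanoic" = octadeca + anoic).
Ester names decode per component: the "-ate" word as an acid, the "-yl"
word as a fatty alcohol. Both routes agree wherever both name a species —
tested exhaustively over every root × suffix pair and over a trivial/
systematic name table. Positional and geometric decorations ("9Z", "cis-")
are stripped: the residue unit carries no position. Coverage gaps are fixed
by editing or replacing the TSV (`readLexicon()`), not by code changes.

One nomenclature corner deserves a note: "linoleyl palmitate" is sometimes
quoted as yielding 16:0 and 18:1, but linoleyl alcohol is the 18:2 species;
this package's lexicon follows standard chemistry (16:0 + 18:2). The
residue *counts* — two residues, exactly one 16:0 — are the same under
either reading, and that is what the acceptance checks assert.

### Table conversion

`makeResiduesTable()` drops non-numeric columns first (a column is numeric
when every non-missing cell is, or parses as, a number — vendor exports
often store numbers as text), then adds `weight × abundance` into residue
rows per sample. Policies, each of them a deliberate choice where several
were defensible:

* **Missing cells contribute nothing.** NA is "not measured", not zero; a
  residue row never turns NA because one contributing lipid was missing.
* **Duplicate identifiers sum.** Rows are processed independently;
  duplicate rows are additive, consistent with splitting one analyte across
  rows.
* **Unparseable rows are skipped**, warned about and counted in the
  result's metadata — a dataset-wide run must not die on one vendor quirk.
  Only a table where *every* row fails is an error.
* **Output rows are unique and sorted** by (carbons, doubleBonds), so
  outputs are diffable across runs.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `dialect` | `"refmet"` | strict `CLASS(...)` shorthand only; `"generic"` adds sum forms, bare `C:D` and names. Generic is a strict superset: on shorthand both dialects agree exactly (tested). |
| `dropAmbiguous` | `FALSE` | discard $i>1$ isobars instead of $1/i$ weighting |
| `maxCarbons` | unset | inclusive residue length cutoff; 30 is the conventional choice, since the longest unambiguous named fatty acids are C-24 and longer labels are mostly unresolved sum-composition artefacts (e.g. a 42:2 arising from `SM 42:2`) |
| `threshold` (`splitByAbundance`) | 0.5 | abundant / less-abundant boundary, in input units (pmol-scale by convention); classification uses the grand mean across all samples, strictly above the threshold |

Percent change versus baseline computes
$100\,(x_{trt}-x_{base})/x_{base}$ per residue, pairing every treatment
sample with its own subject's baseline via an explicit design file — the
pairing is never inferred from column order. A zero baseline yields NA,
never an infinity. The statistic is invariant to rescaling all abundances.

## The synthetic lipidome generator

`simulateLipidome()` is how the package validates itself without external
data. It emulates the *shape* of real lipidomic exports: identifiers drawn
from the shorthand grammar (1–3 chains, occasional `O-`/`P-`/`d` prefixes),
two-way mass isobars, sum compositions and natural-language names in
configurable proportions, and log-normal abundances
(meanlog $= \log 0.5$, sdlog $= 1.5$) spanning the 0.5-unit
abundant/less-abundant boundary, as real lipid amounts span orders of
magnitude. Defaults (60 lipids × 6 samples, 15% ambiguous, 10% sum
compositions, 10% names) mirror the row counts and small group sizes
(n = 3–9) typical of the tables this tool processes.

Crucially, the generator writes the **exact ground-truth residue table
itself**, by enumerating the chains it drew and allocating $1/i$ per
occurrence — it never calls the parser. Generator and parser can therefore
check each other: the test suite demands exact agreement across hundreds of
seeded lipidomes (12 lipids × 3 samples each, sized to keep the default run
fast), plus a conservation law on tables where every alternative has the
same chain count (output mass per sample = chain count × input mass).

What passing these tests does *not* show: real exports contain vendor
annotations the grammar does not generate (adducts, oxidized/hydroxylated
species, quality flags). Those rows are skipped and reported, not silently
absorbed — inspect the skip report on real data.

## Numerical and degenerate-input choices

* Residue tables are written with `%.17g` formatting, so write → read is
  the exact identity on doubles and identical runs are byte-identical.
* Input separators are sniffed among tab/comma/semicolon; a tie is an
  error, not a guess. Decimal commas need an explicit flag.
* An empty residue table (e.g. everything dropped as ambiguous) is a valid
  zero-row object, not an error; "every row unparseable" is an error.
* A chain token with $D \ge C$ is rejected as unparseable; the invariant
  $0 \le D < C$ is enforced by the `Residue` class itself.
* Spreadsheet input is out of scope; export to CSV/TSV first. (Delimited
  text is the interchange format the rest of the toolchain consumes
  anyway.)

## Known limitations

* No oxidized, branched, hydroxy or estolide nomenclature; no adducts,
  isotope labels or fragment-level interpretation.
* The link type (`O-`/`P-`) survives only as per-occurrence metadata, not
  in the aggregated table.
* Three-or-more-way isobars use the same $1/i$ rule; there is no
  likelihood-based reweighting.
* Statistical testing (ANOVA, post-hoc) and ordination are left to the
  standard R tools on the exported table.
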