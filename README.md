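# LipidResidues

High-throughput lipidomics reports *molecular lipids* — identifiers such as
`PC(16:0/18:1)` or `PG(P-22:1/18:1)/PG(O-22:2/18:1)` — but many biological
questions are really about the *fatty acid residues* those lipids carry: the
acyl and alkyl chains summarized as carbons:double-bonds (18:2, 20:4, ...).
LipidResidues decodes lipid identifiers into their residues and converts
whole analyte × sample abundance tables into residue × sample tables, for
lipidomics analysts who want residue-level signatures (saturation balance,
chain-length distributions, per-subject percent changes) out of standard
vendor or repository exports.

## The method

Three identifier forms are decoded:

* **Shorthand** (RefMet-style): `CLASS(chain/chain/...)`, with ether (`O-`),
  plasmalogen (`P-`) and sphingoid-base (`d`, `t`) prefixes. Prefixes are
  stripped from the residue label — a `P-22:1` chain is the residue `22:1` —
  and kept as metadata.
* **Sum compositions**: `SM 42:2` gives only the total carbons and double
  bonds of all chains; the total becomes a single residue (these long
  pseudo-residues are usually removed later with a carbon cutoff, C-30 by
  convention).
* **Natural-language names**: `"linolenic acid"`, `"octadecatrienoic acid"`
  and `FA(18:3)` all yield the 18:3 residue; esters such as
  `"linoleyl palmitate"` yield one residue per component. A shipped,
  replaceable lexicon maps trivial names and systematic Greek roots +
  unsaturation suffixes (chain lengths 2–30, 0–6 double bonds).

**Mass-isobar ambiguity.** When one identifier joins several alternative
identifications (mass isobars), e.g.
`PG(P-22:1/18:1)/PG(O-22:2/18:1)`, the number of alternatives is the
**ambiguity index** *i* (here 2; unambiguous identifiers have *i* = 1).
Every residue occurrence is counted 1/*i* times: the 18:1 present in both
alternatives sums to weight 1, while 22:1 and 22:2 each get 0.5. Amounts are
allocated the same way — a row with abundance *a* adds *a*/*i* per
occurrence into its residues — so for a residue *r* and sample *s*:

```
residue[r, s] = Σ_lipids Σ_occurrences of r  abundance[lipid, s] / index(lipid)
```

Alternatively all ambiguous isobars can be discarded (`dropAmbiguous`),
keeping residues only from unambiguous lipids.

## Worked example

```r
library(LipidResidues)

lip <- parseIdentifier("PG(P-22:1/18:1)/PG(O-22:2/18:1)")
lip
#> Lipid: PG(P-22:1/18:1)/PG(O-22:2/18:1)
#>   ambiguity index: 2
#>   PG: 22:1 / 18:1
#>   PG: 22:2 / 18:1

wr <- weightedResidues(lip)
tapply(wr$weight, wr$label, sum)
#> 18:1 22:1 22:2
#>  1.0  0.5  0.5

lt <- LipidTable(c("FA(18:3)", "PG(P-22:1/18:1)/PG(O-22:2/18:1)"),
                 data.frame(S1 = c(10, 4)))
abundance(makeResiduesTable(lt))
#>      S1
#> 18:1  4
#> 18:3 10
#> 22:1  2
#> 22:2  2
```

The 4.0 units of the two-way isobar split as 2 × 4/2 to 18:1 (present in
both alternatives) and 4/2 each to 22:1 and 22:2; the unambiguous FA(18:3)
passes through untouched. Units are never rescaled.

Whole files run through one call (or the `inst/scripts/lipresidue.R` CLI):

```r
runPipeline("mydata.csv", "residues.tsv", dialect = "generic",
            maxCarbons = 30)
#> Residue extraction run
#>   rows read:        ...
#>   rows skipped:     0
#>   columns dropped:  0
#>   residues emitted: ...
```

Downstream helpers: `splitBySaturation()` (saturated vs unsaturated
residues), `splitByAbundance()` (abundant vs less-abundant at a threshold in
input units, 0.5 by convention), `percentChangeVsBaseline()` (each treatment
sample against its own subject's baseline), `filterMaxCarbons()`.

`simulateLipidome(seed = ...)` generates deterministic synthetic lipidomes
together with the exact residue table they must reduce to, computed by an
independent allocator — the validation backbone of the test suite.

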