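# iscnkit

Parsing, validation and classification of human karyotype designations
written in the International System for Human Cytogenetic Nomenclature
(ISCN).

Clinical cytogeneticists and researchers record karyotypes as strings such
as `46,XY,del(15)(q11q12)` — a chromosome total, an observed
sex-chromosome complement, and a list of change events with band-level
breakpoints. The convention is expressive but informal: there is no
machine-checkable grammar, so it is hard to validate a designation or to
search a collection for, say, every karyotype with an autosomal gain.
`iscnkit` gives a well-defined ISCN dialect a computable semantics for
exactly those two jobs: validation and bulk querying.

## The model

A karyotype is represented as a **base complement** plus **events**:

* the base is a ploidy (1–4) of the 23-chromosome haploid set with a sex
  complement over {X, Y, N}, where N is an allosome of unknown kind;
* events are the ISCN changes — whole-chromosome gains/losses (`+21`,
  `-Y`) and the nineteen structural kinds (`del`, `dup`, `inv`, `t`,
  `i`, `der`, …) with breakpoints validated against a banded chromosome
  map (an ordered partonomy: band ⊂ arm ⊂ chromosome, with sub-bands at
  finer idiogram resolutions).

Derived quantities are computed, never stored: chromosome counts,
per-chromosome copy numbers (conserved against the count), the band
interval an event affects (`del(1)(p31p21)` affects 1p31, 1p22 and 1p21 —
band order is explicit). Defined karyotype classes (diploid, male/female
*by derivation*, numerical/structural abnormality and their sub-classes)
are decision procedures, so subsumption queries like "is trisomy 21 a
diploid karyotype with an autosomal gain?" are function calls. Sex by
derivation means `45,X,-Y` is male — it derives from 46,XY — while a
congenital `45,X` derives from 46,XN and is neither male nor female.

Band order, which a plain class hierarchy cannot express, is provided by
four interchangeable backends (none, pairwise enumeration, next-link
sequence pattern, integer positions) with an exhaustive cross-backend
equivalence test and a benchmark harness over seeded random karyotypes.

## Worked example

```r
library(iscnkit)

k <- parse_iscn("45,X,-Y")
k
#> <karyotype> 45,X,-Y  (base 46,XY; 1 event field(s))
chromosome_count(k)
#> [1] 45
copy_number(k, "Y")
#> [1] 0
sex_of(k)
#> [1] "male"
classify_karyotype(k)
#> [1] "DiploidKaryotype"               "MaleKaryotype"
#> [3] "NumericalAbnormalKaryotype"     "NumericalAbnormalAllosomalLoss"
```

The designation parses as the normal male base 46,XY with one Y loss: 45
chromosomes, zero copies of Y, yet male — the base, not the observed
complement, decides sex. Band intervals resolve through the ordered map:

```r
bands_between(default_band_map(), "1p31", "1p21")
#> [1] "1p31" "1p22" "1p21"
affected_bands(parse_event("del(15)(q11q12)", default_band_map()),
               default_band_map())
#> [1] "15q11" "15q12"
```

A deletion from 1p31 to 1p21 also removes 1p22 — and only 1p22 — because
that is the only band between the breakpoints.

## Command line

`inst/cli/iscnkit.R` is a thin wrapper over the package:

```sh
Rscript inst/cli/iscnkit.R classify --in karyotypes.txt        # JSON lines
Rscript inst/cli/iscnkit.R generate --n 1000 --seed 42 --out k.txt
Rscript inst/cli/iscnkit.R benchmark --sizes 10,100,1000 --seed 1
Rscript inst/cli/iscnkit.R test-fixtures                        # exit != 0 on failure
```

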