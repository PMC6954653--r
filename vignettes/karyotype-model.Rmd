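---
title: "An event-based computational model of ISCN karyotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An event-based computational model of ISCN karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscnkit)
```

## The problem

Human karyotypes are reported as ISCN designations: structured strings such
as `46,XY,del(15)(q11q12)` that name a chromosome total, an observed
sex-chromosome complement, and a list of change events. The convention is
highly expressive but informally specified, which makes designations hard
to validate mechanically and hard to query in bulk ("find all karyotypes
with an autosomal gain"). `iscnkit` gives a supported ISCN dialect a
computable semantics: strings parse into an explicit model, the model
validates against a band inventory, and membership in defined karyotype
classes is decided by ordinary predicates.

## The model

A `karyotype` is a **base complement** plus an ordered list of **events**.

The base is a ploidy (1--4) times the 23-chromosome haploid set, with a sex
complement over `{X, Y, N}` — `N` denotes an allosome of unknown kind. The
events are interpretative: `45,X,-Y` says the observed complement can be
read as the normal male base 46,XY having lost its Y, not that this loss
was observed happening. An event list is therefore closer to an edit script
against the base than to a history.

Nineteen structural event kinds are modelled (`event_kinds()`): addition,
deletion, derivative, dicentric, duplication, fission, fragile site,
homogeneously staining region, insertion, inversion, isochromosome, marker,
neocentromere, quadruplication, ring, telomeric association, translocation,
tricentric and triplication; whole-chromosome gains and losses (`+21`,
`-Y`) are modelled as separate numerical events. A derivative chromosome
(`der(1)t(1;5)(p22;q31)`) is a container: its chromosomes and breakpoints
are the union over its constituent events, and its own count contribution
is zero.

### Base inference and sex by derivation

The parser reconstructs the base from the designation: the allosomal
gain/loss events are reversed against the observed sex field, and the
ploidy is taken from the declared total net of event deltas. Two special
situations are resolved as follows, both being genuinely open choices:

* **Missing allosome, no event** (`45,X`): the base is padded with `N` and
  an *implicit* loss of `N` is recorded. The karyotype derives from 46,XN —
  we do not know which allosome was lost — so its sex is `undetermined`.
  Implicit events count (the total is 45, the allosomal-loss class holds)
  but are never printed in canonical output, since `-N` is not ISCN.
* **Surplus allosome** (`47,XXY`): the base keeps one of each distinct
  allosome first (X, then Y), surplus copies become gains. `47,XXY` is
  therefore derived from 46,XY and classifies as male.

Sex is decided purely by the base: male iff the base complement contains a
Y (and no `N`), female iff it is all-X, undetermined iff it contains `N`.
This makes `45,X,-Y` male despite having no Y, and leaves `45,X` neither
male nor female. Sex is the one place where three-valued, open-world-style
behaviour is emulated; every other class predicate is a closed-world
boolean.

### Counts and copy numbers

`chromosome_count()` adds per-event deltas to 23 x ploidy: gains/losses
contribute their sign, fission +1 (one chromosome becomes two), dicentric
and telomeric association -1 (two become one), tricentric -2, each marker
+1, everything else 0. ISCN never states these deltas explicitly; the
table is cytogenetic convention and is documented as such.

`copy_number()` is defined so that copies are conserved — the sum over all
chromosome types (plus the unknown allosome `N` and the marker pool `mar`)
always equals `chromosome_count()`. That forces an attribution choice for
the fusing events: a dicentric or telomeric association debits its
second-named chromosome, a tricentric its second and third, a fission
credits its own. The attribution is bookkeeping, not biology (the fused
chromosome contains material of both partners); it exists so conservation
is an invariant rather than an approximation. Classification deliberately
does *not* use this attribution: the numerical-abnormality classes look
only at the net deltas of whole-chromosome gain/loss events, so a
dicentric never classifies as an autosomal loss. `del(c)` with no
breakpoints is accepted as a whole-chromosome deletion and agrees with
`-c` for these classes.

## The band partonomy

Bands live in an ordered part-of hierarchy: band within arm within
chromosome, with dotted sub-bands (`17q21.31` within `17q21`) appearing at
finer idiogram resolutions. The packaged band table covers all 24
chromosome types, with full undotted band lists for chromosomes 1, 2, 5,
15, 17, 21, X and Y, the five sub-bands of 17q21, and minimal `p11`/`q11`
entries elsewhere; any fuller inventory (e.g. a complete 850-band table)
can be dropped in using the same TSV format, in which case the entry count
exceeds 800. Only three ordering relations are treated as normative
anchors for the fixture: 1p22 lies strictly and solely between 1p31 and
1p21; 15q11 is adjacent to 15q12; 17q21 has at least two sub-bands.

Numerical choices:

* **Linearization** is pter-to-qter: p-arm bands in descending designation
  order, then q-arm ascending — forced by ISCN numbering away from the
  centromere.
* **Visibility is cumulative**: a band visible at the 300-band level stays
  visible at 850; at a finer level a divided band is replaced by its
  sub-bands in interval enumeration.
* **Mixed-resolution endpoints**: `bands_between()` expands an endpoint
  that is divided at the query resolution to its first/last visible
  descendant (preserving inclusivity); an endpoint not yet visible at that
  resolution is a resolution error rather than a guess.
* **The centromere** is the boundary between the `p11`-most and `q11`-most
  bands, not a band itself: ISCN breakpoints name bands, and intervals may
  span the boundary freely.
* `bands_between()` defaults to the 300-band level (the undotted
  idiogram); the ordering backends and `affected_bands()` work at the
  finest (850) level so that every stored band is addressable.

`affected_bands()` interprets events against this order: an interstitial
deletion, duplication, triplication, quadruplication or inversion affects
every band between its two breakpoints inclusive; a one-breakpoint
deletion is terminal (breakpoint to the telomere of its arm); an
isochromosome affects the whole arm its breakpoint names; all other events
affect exactly their breakpoint bands.

## Ordering backends

Band order is the one piece of structure a plain subsumption hierarchy
cannot represent, and there is more than one way to encode it. Four
interchangeable backends sit behind `backend_between()`:

1. `no_order` — order is simply absent; interval queries are a capability
   error, not a wrong answer.
2. `enumeration` — every same-chromosome pair's inclusive interval is
   materialized up front; queries are lookups.
3. `sequence_pattern` — bands carry next-links (the sequence design
   pattern); queries walk the chain and never consult numeric positions.
4. `data_property` — bands carry strictly increasing integers; queries
   compare values.

The enumeration backend is the oracle: the other interval-capable backends
are tested exhaustively against it over all same-chromosome band pairs.
`benchmark_backends()` classifies seeded random karyotypes while routing
every band-interval query through each backend, asserts that all backends
agree before any timing is reported, and reports wall times without
asserting them — absolute times are hardware-bound and deliberately carry
no expectations. Backend choice is a runtime knob, so the same trade-off
can be made at deployment time against a large karyotype collection.

## The random-karyotype generator

`generate_karyotypes()` powers the property tests and the scaling runs.
Its defaults are the study conditions: diploid bases (XX/XY equally
likely), zero to three events per karyotype, numerical-event probability
0.3, and uniform weights over all band-level event kinds. Each karyotype
is assembled as ISCN text and pushed through the parser, so every output
parses, validates cleanly and round-trips by construction; a copy-state
tracker ensures no draw removes a chromosome that is not there (including
never losing the last sex chromosome). The generator is deterministic
under its seed and restores the caller's RNG state.

What it emulates is the combinatorial surface of the dialect — every event
kind in a syntactically valid form on existing bands. What it does not
emulate is biology: real aberration spectra are tumour-type specific,
breakpoints cluster at fragile sites, and multi-event karyotypes are
correlated. Passing property tests therefore demonstrates the internal
coherence of parsing, classification and ordering on arbitrary valid
designations, not distributional realism.

The test suite exercises the generator at n = 1000 and the scaling run at
n in {10, 100, 1000, 10000}; these sizes keep the suite comfortably
interactive while still separating the backends' scaling behaviour.

## Supported dialect and known limitations

The parser accepts the numerical `+c`/`-c` forms and all nineteen
structural abbreviations in one- and two-breakpoint (insertion:
three-breakpoint) forms on one to three chromosomes. Multi-cell clones
(`/`), `idem`, uncertainty (`?`) and approximate counts (`45~48`) are
rejected with an explicit unsupported-dialect error — full ISCN is
informal enough that a complete parser is necessarily heuristic, and a
clearly-bounded dialect is more useful than a silently lossy one. Other
limits: no base-pair coordinates or stain intensities; no breakpoint
uncertainty intervals; the 17-plus defined classes are a reconstruction of
the natural query set (ploidy, sex, numerical and structural kinds), not
an externally fixed list; and the marker pool and unknown allosome are
modelling devices (`mar`, `N`) that deliberately have no ISCN spelling of
their own.
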