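Package: iscnkit
Title: Parsing, Validation and Classification of ISCN Karyotype Designations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with human karyotype designations written in
    the International System for Human Cytogenetic Nomenclature (ISCN).
    Provides an ordered partonomy of chromosomes, arms and bands with
    idiogram resolution levels; a parser that turns ISCN strings into an
    event-based karyotype model (a base complement plus interpretative
    change events); derived quantities such as chromosome counts, per
    chromosome copy numbers and the band intervals affected by structural
    events; a registry of defined karyotype classes (ploidy, sex by
    derivation, numerical and structural abnormality) with subsumption
    queries; four interchangeable band-ordering backends with a benchmark
    harness; and a seeded random-karyotype generator for property testing
    and scaling experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
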