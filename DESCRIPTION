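Package: probefold
Title: Probing-Informed RNA Secondary Structure Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A project-oriented pipeline for RNA secondary structure modeling
    informed by chemical probing experiments (SHAPE, DMS). Takes per-nucleotide
    reactivity files through outlier removal and normalization, replicate
    aggregation with consistency checks, multi-condition structure prediction
    by Boltzmann-ensemble stochastic sampling and base-pair-distance
    clustering (optionally augmented by a covariation-scored pseudo-condition
    derived from a multiple sequence alignment), differential-reactivity
    footprinting between two conditions, and structure-model comparison with
    reactivity-class color annotations. Includes a synthetic-data generator
    emulating probe-specific reactivity profiles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
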