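Package: multisol
Title: Solution Multiplicity Screens for Two-Group Expression Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for demonstrating and quantifying solution multiplicity
    (the Rashomon effect) in two-group expression-based classification. Provides
    a from-scratch extreme learning machine (ELM) binary classifier with an
    extractable random hidden-layer weight matrix, per-feature two-sample t-test
    ranking, repeated seeded model screens with cutoff-based solution censuses
    and weight-difference comparison of tied-best models, exhaustive screening
    of all feature triplets drawn from the top-ranked features with
    accuracy/precision/recall censuses and rank-dispersion summaries, and a
    seeded synthetic two-group expression generator with planted informative
    features and redundant correlated blocks so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lattice,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
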