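Package: refinemetrics
Title: Metrics and Rankings for Protein Model Refinement Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing protein model refinement the way CASP
    refinement assessments are run: structure-similarity metrics between
    refined models and experimental targets (sequence-dependent Ca RMSD,
    GDT_TS/GDT_HA, lDDT, SphereGrinder), accuracy self-estimate (ASE)
    scoring of predicted coordinate errors, torsion-angle deviation
    analysis with a 30-degree good/bad region classification, CASP-style
    two-pass z-score group rankings with composite weight presets, and a
    naive-predictor baseline that resubmits the starting model. Includes
    a synthetic-structure generator so every metric and ranking operation
    is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
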