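Package: tlcqsar
Title: QSAR Modelling of Serotoninergic Ligands from Biopartitioning
    Thin-Layer Chromatography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates quantitative structure-activity
    relationship (QSAR) models for serotonin-receptor ligands from
    biopartitioning thin-layer chromatography (TLC) retention data and
    calculated molecular descriptors. Converts retardation factors to the
    Bate-Smith-Westall RM scale, derives control-versus-impregnated-plate
    interaction variables, fits ordinary-least-squares activity models
    under a pairwise collinearity filter with optional forward-stepwise
    selection, and judges predictive power with leave-one-out and
    leave-N-out cross-validation (Q2, PRESS, S_PRESS, SDEP) and the usual
    reliability criteria. Ships the complete study tables as plain-text
    fixtures, a seeded synthetic-data generator for parameter-recovery
    experiments, and report writers that reproduce the study's result
    tables end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
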