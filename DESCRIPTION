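Package: zfscreen
Title: Larval Zebrafish Light-Dark Transition Behavioral Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for larval zebrafish light-dark transition
    locomotor screens. Extracts thirteen formula-defined behavioral endpoints
    from binned distance-moved traces, normalizes them against vehicle controls
    with an optimized Box-Cox power transformation, fits a ten-model
    concentration-response suite with Student-t robust likelihoods to produce a
    continuous hitcall and a benchmark concentration (BMC) with bootstrap
    confidence bounds, and runs the parallel repeated-measures ANOVA analysis
    with Fisher's LSD post hoc. Also provides developmental-toxicity status
    classification, plate-level quality control, dosing-series arithmetic, and
    a seeded synthetic plate generator with known ground truth for validation.
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
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
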