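Package: pewlsim
Title: Clinical Utility of Genomic Prediction for Bariatric Surgery Allocation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation framework for quantifying the clinical
    utility of a modestly accurate genomic predictor of percent excess weight
    loss (PEWL) after bariatric surgery. Simulates a population-scale cohort
    from a bivariate normal height/log-weight model with sex offsets, derives
    the surgery-eligible subset (BMI >= 35), simulates actual and genomically
    predicted PEWL with configurable correlation structure, maps BMI to
    lifetime Type 2 diabetes risk and baseline weight/sex to surgical
    adverse-event risk through calibrated monotone risk models, and evaluates
    decision thresholds on predicted PEWL under a fixed surgical budget,
    reporting population case probabilities and additional cases prevented
    relative to allocation without the genomic test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
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
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
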