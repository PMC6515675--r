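Package: seqbayes
Title: Bayesian Sequential Two-Arm Trial Design, Simulation and Virtual
    Re-Execution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating Bayesian sequential (adaptive)
    two-arm superiority trials with a binary endpoint. Provides conjugate
    beta-binomial inference (posterior probability of superiority, final
    success rules, relative risk with confidence interval, and the
    continuity-corrected two-proportion sample-size formula), posterior
    predictive probabilities of trial success at the current and maximum
    sample sizes for success and futility stopping, encoding of candidate
    interim-analysis designs, simulation of whole trials to estimate operating
    characteristics (type I error, power, expected sample size, stopping
    proportions), threshold calibration over grids, and virtual re-execution
    of a design over a patient-level recruitment stream. Includes a
    synthetic-data generator for patient streams and for constrained fixtures
    that reproduce specified interim counts exactly.
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
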