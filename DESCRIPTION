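Package: dalysim
Title: Individual-Based Simulation of Disease Burden with Frailty Heterogeneity
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Individual-based Monte-Carlo simulation of infectious disease
    burden in disability-adjusted life years (DALYs). Disease natural
    histories are specified as outcome trees (stages with disability weights
    and durations, immediate or annual transition probabilities, optionally
    age-banded). Cohorts of incident cases progress through the tree either
    with population-averaged transition counts (no-heterogeneity variant) or
    with individual gamma-frailty values weighting who transitions, while the
    yearly number of transitions stays constrained to its population-averaged
    expectation. The package computes years lived with disability (YLD),
    years of life lost (YLL) and DALYs against a period life table, summarises
    replicate distributions, derives burden overestimation factors, and runs
    age-targeted vaccination and sensitivity experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
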