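Package: bayesefs
Title: Bayesian Adaptive Single-Arm Trial Design for Event-Free Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and monitoring of single-arm clinical trials with a
    time-to-event endpoint compared against a historical control, aimed at
    de-intensified oncologic treatment settings with low event rates.
    Provides closed-form conjugate inference for the exponential survival
    model under Gamma or Jeffreys priors, posterior-predictive event-free
    survival at a clinical horizon, multi-stage interim analysis with
    stage-wise stopping boundaries (linear stage thresholds and
    error-spending families), a staggered-accrual trial simulator, and
    Monte-Carlo operating characteristics (empirical type I error, power,
    minimal sample size, stopping-time distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
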