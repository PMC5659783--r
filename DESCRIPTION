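Package: valuessm
Title: Sequential-Sampling Accumulator Models for Value-Based Binary Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a family of eight nested connectionist
    sequential-sampling models of two-alternative value-based choice,
    ranging from an independent race and a neural drift-diffusion variant
    to competing accumulators with hierarchical (input- and
    state-dependent) mutual inhibition and a supralinear attentional
    power law. Includes Monte-Carlo chi-square quantile-based fitting
    with Nelder-Mead restarts, null/saturated benchmark predictors,
    likelihood-ratio tests and information criteria, a behavioral
    regression battery for choice accuracy and reaction times, a
    balanced-design synthetic data generator, parameter-recovery
    experiments, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
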