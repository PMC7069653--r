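Package: htpchallenge
Title: Population PK/PD Modelling of the 5-HTP Challenge Test with
    Circadian Cortisol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing 5-hydroxytryptophan (5-HTP) challenge
    trials in which serum 5-HTP, total serum cortisol and saliva cortisol
    are sampled over a study day. Provides the structural models (a
    one-compartment oral model with a transit absorption compartment, a
    cosine-plus-trend circadian cortisol baseline, a linear stimulation
    effect, a power-law saliva-serum cortisol link and the Coolens free
    cortisol calculation), a self-contained Laplace/FOCE nonlinear
    mixed-effects engine with empirical Bayes estimates and finite
    difference standard errors, a staged estimation pipeline with
    period, predictor and functional-form selection by objective
    function value, a crossover trial simulator for parameter-recovery
    studies, and diagnostics (visual predictive checks, goodness-of-fit
    tables, per-subject trellis data).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
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
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    lme4,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
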