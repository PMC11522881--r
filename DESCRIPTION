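Package: dwellsim
Title: Optimal Housing Strategies by Stochastic Dynamic Programming and
    Simulation-Based Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models strategic housing decisions of households as a
    finite-horizon stochastic dynamic program over a discrete state space
    (dwelling type, savings, land tenure, family composition). Provides a
    backward-induction solver for optimal behaviour tensors, a seeded
    forward simulator generating longitudinal agent trajectories and
    cross-sectional household records, dwelling-transition summaries, a
    synthetic-data generator emulating a cross-sectional household survey,
    and an approximate Bayesian computation (ABC) layer with importance
    weighting that fits behavioural probabilities, building costs and
    pay-off scenarios to household summary data, including parameter
    recovery validation and posterior predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
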