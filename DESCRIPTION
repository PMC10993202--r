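Package: discountr
Title: Hierarchical Bayesian Modelling of Delay-Discounting Choice Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the adaptive amount-adjustment (staircase) intertemporal
    choice task, fits five option-based discounting models (exponential and
    hyperbolic, with and without time scaling) and three attribute-wise
    heuristic models (ITCH, DRIFT, TRADE) hierarchically by MCMC under uniform
    hyperpriors, compares them by WAIC on the negative-log scale, runs
    parameter-recovery simulations, and contrasts population discount rates
    between reward conditions via 95% highest density intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
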