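Package: rpscycle
Title: Social Cycling and Conditional-Response Dynamics in Finite-Population Rock-Paper-Scissors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and explaining collective cycling in
    iterated Rock-Paper-Scissors populations under random pairwise
    matching. Implements the rotation-angle / cycling-frequency
    trajectory statistic on the discrete social-state plane, the exact
    finite-population win-lose-tie conditional-response Markov model
    (pairing combinatorics, transition matrix, stationary distribution,
    cycling frequency, tie fraction, expected payoff), an agent-based
    session simulator, empirical estimators of conditional-response
    behaviour with the associated significance tests, and a Monte-Carlo
    study of payoff performance across the strategy simplex.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
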