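Package: commitpd
Title: Evolutionary Dynamics of Commitment Strategies in the One-Shot
    Prisoner's Dilemma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models pre-play commitment proposals in the one-shot
    Prisoner's Dilemma: strategies that propose a costly agreement,
    accept or fake it, or free-ride on it. Derives the pairwise payoff
    matrix from behavioural rules, analyses finite-population imitation
    dynamics under the pairwise-comparison (Fermi) rule (fixation
    probabilities, small-mutation-limit Markov chain, stationary
    distributions, risk-dominance viability boundaries), and
    cross-validates the analytic predictions with an agent-based
    simulation of imitation with mutation. Includes the cost-sharing
    extension of the commitment proposer and a costly-punishment
    comparison model.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
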