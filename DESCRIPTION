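Package: hybridcrd
Title: Evolutionary Dynamics of Cooperation in Hybrid Human-Agent Teams
    Playing the Collective-Risk Dilemma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stationary analysis of social-learning dynamics in a
    finite population of adaptive individuals who play a one-shot
    collective-risk dilemma (a threshold public goods game with
    probabilistic loss) in hybrid groups that also contain fixed-behavior
    stochastic agents. Implements hypergeometric expected fitness, the
    Fermi pairwise-comparison imitation rule with mutation, the tridiagonal
    birth-death Markov chain and its stationary distribution (eigenvector
    solve cross-validated against the closed-form product solution),
    population-level cooperation and group-success metrics, substitution
    and addition control comparisons, parameter sweeps over risk and agent
    cooperativeness with scenario presets, and an agent-based Monte Carlo
    simulator of the same stochastic process used as an independent
    validation oracle. Results are returned as tibbles with broom-style
    tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
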