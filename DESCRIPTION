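Package: selrank
Title: Strategy Abundance Rankings Across Selection Intensities in
    Finite-Population Evolutionary Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Evolutionary game dynamics in finite well-mixed populations
    under rare mutation.  Reduces two-player n-strategy matrix games and
    d-player two-strategy games (including a parametric public goods game
    with punishment) to pairwise invasion profiles, computes fixation
    probabilities for pairwise-comparison (imitation) and Moran processes
    entirely in log space, assembles the embedded Markov chain over
    monomorphic states and its stationary distribution, and tracks how
    the abundance ranking of strategies changes with the intensity of
    selection: rank-crossing detection and refinement along a selection
    gradient, randomized searches for games whose weak- and
    strong-selection rankings disagree with intermediate behaviour, and
    Monte Carlo studies over random payoff matrices.  A compiled
    stochastic simulator of the full mutation-selection process serves as
    an independent check of the small-mutation approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
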