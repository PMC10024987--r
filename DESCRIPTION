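Package: threshpgg
Title: Asymmetric Threshold Public Goods Games: Equilibria, Evolutionary
    Dynamics and Synthetic Behavioural Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the two-player asymmetric threshold public goods
    game, in which players with unequal endowments or productivities must
    jointly reach a contribution threshold to earn a reward. Provides
    exact payoff machinery and enumeration of pure Nash equilibria,
    equilibrium-selection heuristics (equal absolute or relative
    contributions, equal collective contributions, equal payoffs, maximal
    collective payoff), four evolutionary and learning dynamics
    (two-population replicator, best-response, Fermi birth-death,
    introspection) under uniform, random or empirical initial conditions,
    a repeated-game engine over deterministic reactive strategies, and a
    synthetic experiment generator with directional-learning agents plus
    the outcome metrics (success and effectiveness rates, contribution
    summaries, failure categories, conditional responses) needed to
    analyse experiment-shaped session data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
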