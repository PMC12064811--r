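Package: satplan
Title: Planning Strategies and Probability Discounting in a Sequential
    Probabilistic Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulator and model-fitting toolkit for a three-step
    probabilistic planning task in which an agent steers a ship around a
    ring of six planets using a deterministic 'move' and a risky 'jump'
    action under low or high transition noise.  Implements four
    reinforcement-learning planning models (full-breadth planning and
    low-probability pruning, each with optional hyperbolic probability
    discounting), per-mini-block planning-depth mixture likelihoods,
    participant-level maximum-likelihood fitting with analytic depth
    marginalization, agent-based performance benchmarks, and model
    comparison via McFadden pseudo-R-squared and BIC with evidence bands,
    including parameter- and model-recovery simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
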