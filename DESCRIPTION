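Package: spattn
Title: Selective Particle Attention for Feature Gating in Reinforcement
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a soft-attention vector over pre-learned feature channels
    from reward feedback alone, using a sequential importance resampling
    particle filter over binary feature-relevance hypotheses. Each particle
    encodes a hypothesis about which channels are useful for the current
    task; a bottom-up movement step refreshes particles toward highly active
    channels and a top-down observation step weights them by how well their
    induced attention predicts observed returns. Ships small value-learning
    agents (an epsilon-greedy one-step Monte Carlo value network and an
    advantage actor-critic), a synthetic category-signature feature backend
    emulating convolutional feature-map statistics, two revaluation
    benchmarks (a changing-target multiple-choice task and an
    object-collection game with reward or state revaluation), baseline
    attention sources (uniform, frozen random, ideal observer, a trained
    query/key self-attention head), and a tidy experiment layer with tibble
    outputs and ggplot2 plots.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
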