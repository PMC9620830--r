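Package: rankagg
Title: Rank Aggregation of Gene Lists with Simulation-Based Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines ranked and unranked gene lists from multiple studies
    into a consensus ranking and helps choose the right aggregation method
    for a given dataset. Implements Borda statistics (mean, median,
    geometric mean) and their unranked-capable Mix variants, the Stuart and
    robust rank aggregation (RRA) order-statistic methods, Markov-chain
    aggregation (MC3), iterative Bayesian reweighting (BIRRA), iterative
    list weighting by information content (MAIC), vote counting and
    RepeatChoice. Ships a stochastic generator of realistic gene-list
    collections (genome-scale universe, heterogeneous per-list noise and
    lengths, unranked sources, absent genes), an accuracy/recall evaluation
    harness with replicated experiments and confidence intervals, and a
    decision layer that infers quality heterogeneity from MAIC list weights
    and recommends methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
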