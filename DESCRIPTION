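Package: prunenet
Title: Pruning-Based Construction of Distributed Routing Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates synaptic-pruning-inspired algorithms for designing
    efficient and robust distributed routing networks. Networks start
    over-connected, track per-edge usage while routing an online stream of
    source-target pairs, and eliminate low-usage edges on a pruning-rate
    schedule (constant, increasing, decreasing, or ending) down to an edge
    budget. Includes growing and no-learning baselines, efficiency,
    robustness and energy metrics, triad-motif over-representation tests
    against degree-preserving null ensembles, a three-parameter directed
    random-graph theory of the final source-target edge densities, and a
    spline-based pruning-rate statistic with leave-one-out cross-validation
    for developmental synapse-density time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
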