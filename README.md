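# prunenet

Synaptic pruning as a network-design algorithm. Developing cortex builds
circuits by over-producing synapses and then eliminating most of them in
an activity-dependent way. `prunenet` implements that strategy as a
distributed routing-network construction algorithm and provides the tools
to ask whether it is a *good* algorithm: who should use it — researchers
studying network formation, and anyone comparing decentralized network
design heuristics under an edge budget.

## The model

Given `n` nodes and an online stream of source–target pairs
`(s_i, t_i) ~ D`, return a directed graph `G` with at most `B` edges that
is efficient and robust with respect to `D`:

- **efficiency(G)** `= (1/p) Σ d(u, v)` over `p` test pairs, where
  `d(u, v)` is the shortest-path hop distance (disconnected pairs are
  charged a fixed penalty, default `2n`); lower is better.
- **robustness(G)** = mean number of source–target routes at most one hop
  longer than the shortest path, found by iteratively deleting the
  interior nodes of each discovered path; higher is better.

The pruning algorithm starts from the clique, counts per-edge usage while
routing each training pair along a shortest path, and after each of
`K = 10` intervals removes a scheduled fraction `r_i` of the existing
edges, lowest-usage first, down to exactly `B`. Schedules: **constant**
(`(1 - r)^K E0 = B`), **decreasing** / **increasing** (geometric
`r_i = c·γ^(i-1)`, defaults `γ = 0.5` / `2`), and **ending** (one final
collapse). Baselines: a spanning-tree **growing** algorithm and a random
**no-learning** network. A flow-based variant rewards all edges on
surviving routes under 0.65 per-edge signal loss. Companion modules
provide triad-motif Z-scores against randomized ensembles, a
three-parameter directed random-graph theory `ER(p, q, z)` of the final
source/target edge densities, and a spline + leave-one-out statistic for
developmental synapse-density time series.

## Worked example

Compare the algorithms on a two-patch distribution (100 nodes, budget of
2 edges per node, 1000 training and test pairs, 3 replicates):

```r
library(prunenet)
cfg <- experiment_config(
  dist_kind = "two_patch", n = 100L, B = 200L,
  p_train = 1000L, p_test = 1000L, replicates = 3L, seed = 42L,
  cells = list(list(algorithm = "prune", schedule = "decreasing"),
               list(algorithm = "prune", schedule = "constant"),
               list(algorithm = "prune", schedule = "increasing"),
               list(algorithm = "grow",   schedule = NA),
               list(algorithm = "random", schedule = NA)))
run_comparison(cfg)
#> comparison_report: n=100, B=200, 'two_patch', 3 replicate(s)
#>              cell algorithm   schedule efficiency efficiency_sd robustness
#>  prune/decreasing     prune decreasing      12.88         4.415      1.201
#>    prune/constant     prune   constant      20.30         3.313      1.068
#>  prune/increasing     prune increasing     182.90         1.780      0.087
#>              grow      grow       <NA>      10.83         0.899      1.000
#>            random    random       <NA>      84.77        14.430      0.655
#>  robustness_sd unroutable energy
#>       0.042500      44.33  12360
#>       0.029540      82.00  30020
#>       0.008544     914.00  84070
#>       0.000000       0.00   1989
#>       0.079370     408.00    200
```

Reading the table: among the pruning schedules, decreasing rates give the
best efficiency (12.9 hops vs 20.3 constant and 182.9 increasing — the
increasing schedule overfits and strands most test pairs, hence the huge
penalty-driven mean), the most robustness (1.20 routes per pair), the
fewest unroutable pairs, and the lowest energy (12,360 edge-intervals of
maintenance vs 84,070 for increasing). The spanning-tree growing baseline
can never strand a pair (unroutable = 0) and at this scale wins penalized
efficiency, while the random no-learning network is far worse than any
trained pruning schedule.

The developmental statistic on the packaged per-timepoint density table:

```r
series <- read_density_tsv(system.file("extdata",
  "barrel_density_table.tsv", package = "prunenet"))
loo_rate_test(series, k = 2, scheme = "timepoint",
              start_age = 19, end_age = 39)
#> rate_report: 2 intervals over P19-P39, 12 leave-one-timepoint folds
#>   interval 1 [ 19.0,  29.0]:  32.77% pruned (SD 5.03)
#>   interval 2 [ 29.0,  39.0]:   4.99% pruned (SD 2.11)
#>   interval 1 vs 2: t = 17.65, p = 2.56e-11
```

About a third of peak synapse density is lost in the first half of the
pruning period against ~5% in the second — a decreasing pruning rate.

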