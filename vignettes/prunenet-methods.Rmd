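---
title: "Usage-based pruning for distributed network design: models and methods"
author: "prunenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Usage-based pruning for distributed network design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prunenet)
```

## The design problem

During development, cortical circuits massively over-produce synapses and
then eliminate a large fraction of them in an activity-dependent way
("use it or lose it"). `prunenet` treats this as a distributed network
design strategy and asks how well it performs as an algorithm. The
abstract problem: given `n` nodes and an online stream of `p`
source–target pairs drawn from an unknown distribution `D`, output a
directed graph with at most `B` edges that routes pairs from `D`
efficiently and robustly. The budget `B` models the metabolic or material
cost a system can sustain; the online constraint models the fact that
activity arrives one signal at a time, with no batch access.

Four construction algorithms are implemented:

* **Pruning, shortest-path model** (`build_by_pruning`). Start from the
  clique. Route each training pair along a minimum-hop path; every edge on
  the path gains one usage count. After each of `K = 10` intervals (each
  10% of the stream), remove a schedule-determined number of the
  lowest-usage edges, ties broken at random, landing exactly on `B`.
* **Pruning, flow model** (`build_by_flow`). Instead of routing, each pair
  triggers a breadth-first flow episode in which every edge independently
  fails with probability 0.65 (synapse failure); all surviving edges lying
  on a surviving source-to-target route are rewarded one usage count.
* **Growing** (`build_by_growing`). The engineering baseline: install a
  uniformly random spanning tree as reciprocal arc pairs (guaranteeing
  universal routability), then add the most-demanded distance-2 shortcut
  arcs along observed routes, in equal per-block installments up to `B`.
* **No-learning** (`build_no_learning`). `B` uniformly random directed
  edges; ignores the training data.

## Pruning-rate schedules

A schedule is the fraction `r_i` of currently existing edges removed after
interval `i`. Four shapes are provided: *constant* (`r` solves
`(1 - r)^K E0 = B`), *decreasing* and *increasing* (geometric family
`r_i = c * gamma^(i-1)` with default `gamma = 0.5` and `2` respectively,
`c` solved numerically for budget exactness), and *ending* (no removal
until a single final collapse to `B`). The geometric family was chosen
because it matches the qualitative shapes of the schedules it models with
a single interpretable knob; `gamma -> 1/gamma` exactly reverses the rate
sequence, which makes the increasing/decreasing comparison symmetric.
Integer rounding removes `round(r_i * current)` edges per interval,
clamped so the count never dips below `B`, with the final interval forced
to land exactly on `B`.

The *energy* of a schedule is the cumulative number of edges maintained
across intervals — the resource cost of hyper-connectivity. It is ordered
by removal lateness: decreasing < constant < increasing < ending, exactly
and for any `(E0, B, K)` we tested.

```{r energy}
vapply(c("decreasing", "constant", "increasing", "ending"),
       function(sh) schedule_energy(make_schedule(sh, E0 = 9900, B = 200)),
       numeric(1))
```

## Pair distributions

`make_distribution` implements the activity structures: `two_patch`
(half sources, half targets, uniform pairs), `two_s_patch` (a 10%
"selective" subset on each side receives half the traffic, modeling
highly active subnetworks; mixture weight `x = 0.5`),
`two_patch_unbalanced` (three times as many targets), `four_patch`
(two disjoint patch pairs), `four_patch_hw` (the second source set is
shut off halfway through training and its targets are recruited by the
first — a monocular-deprivation analogue), and `empirical` (categorical
over explicit pairs, e.g. an airline origin–destination matrix read by
`read_traffic_csv`, where a city can be both source and target). Sources
occupy the lowest labels deterministically so runs are reproducible from
`(kind, n)` alone.

## Evaluation

With the network frozen, a fresh stream from the same distribution is
scored:

* **Efficiency**: mean shortest-path hops over test pairs; a disconnected
  pair is charged a penalty constant, default `2n` (it must exceed any
  path length, which is at most `n - 1`, while keeping means readable).
* **Robustness**: per pair, count the shortest path, delete its interior
  nodes (for a direct hop, the edge itself), and repeat while routes at
  most one hop longer than the original shortest path survive. The
  primary path is included, so a routable pair scores at least 1. For the
  airline analysis the slack is 0 (alternatives with the *same* hop
  count), matching how that comparison is framed.
* **Unroutable**: the count of disconnected test pairs.

Two conventions deserve a note. First, because the count includes the
primary path and the growing baseline is always fully routable, the mean
robustness ratio between any two algorithms is bounded by roughly the
mean out-degree — order-of-magnitude robustness folds are not expressible
under this convention. Second, deleting an edge always weakly worsens
efficiency, but can *raise* robustness: removing a direct edge raises the
base distance, which can admit two disjoint longer routes into the
one-extra-hop window.

## Motif analysis

`triad_census` counts the 16 directed 3-node isomorphism classes
(via igraph's census, cross-checked in the test suite against a
hand-encoded enumeration oracle), and `motif_zscores` scores each class
against a randomized ensemble; the feed-forward loop is class `030T`.
Two null models are provided: degree-preserving directed edge swaps
(default, 100 × |E| attempted swaps per sample, the convention of the
motif-detection literature) and uniform `G(n, m)`. The choice matters:
degree-preserving nulls ask whether wiring beyond the degree sequence is
special, while `G(n, m)` also credits degree heterogeneity (hubs) to the
network. On networks built by this package's shortest-path pruning, the
feed-forward class is enriched relative to `G(n, m)` under the selective
two-patch distribution but not relative to degree-matched graphs —
single-path routing retains little redundancy (a kept direct edge starves
its own 2-hop bypass of usage), so transitive triangles are carried by
the hub structure rather than by excess wiring. Both nulls are exposed so
users can ask either question.

## Random-graph theory of the final network

Final two-patch networks are approximated by a three-parameter directed
random graph: within-class edges (`S->S`, `T->T`) with probability `p`,
cross edges `S->T` with probability `q`, back edges `T->S` with
probability `z` (which vanishes in optimal sparse networks — back edges
never help route source-to-target traffic).

`expected_efficiency` predicts the expected source-to-target distance by
a layered BFS-exposure recursion on expected frontier sizes. It is a
concentration (annealed) approximation: accurate in the supercritical
regime (class degrees comfortably above 1) and biased near the
percolation threshold, which is stated rather than hidden — the test
suite validates it against Monte-Carlo sampling on a supercritical
`(p, q)` grid. Because disconnection has probability on the order of
1e-3 in these cells while carrying a penalty of `2n`, finite Monte-Carlo
cannot estimate the penalty mass; validation therefore compares the
reachable-conditional mean (an attribute of the return value) and bounds
the disconnection rate separately.

`predict_pq` is a mean-field surrogate for the full simulator: each edge
class carries an expected count over integer usage levels; every interval
adds Poisson usage increments at rates implied by the current densities
(direct hits on cross edges, 2-hop routes through one within-class and
one cross edge, 3-hop routes by type abundance), and the schedule's
removal count is taken from the globally lowest usage levels,
proportionally across classes. This mirrors lowest-usage-first pruning at
the ensemble level. It is validated against the full simulator, not
asserted as a closed form: across the four schedules both give the same
final `q/p` ordering — ending > increasing > decreasing > constant.
Ending memorizes direct edges (maximal `q/p`, the overfit regime);
schedules that prune early force 2-hop routing and so retain relatively
more within-class structure. Note that constant, not decreasing, yields
the smallest `q/p` in both the recurrence and the simulator.

## The developmental pruning-rate statistic

`fit_density_curve` fits a cubic smoothing spline (smoothness by
generalized cross-validation, weighted by per-bin sample counts) through
per-age-bin mean synapse densities; an exact natural-spline interpolation
mode is available. The standard binning merges ages 21+22, 23+24, 32+33
and 34+36 into shared bins, giving 12 bins over P14–P40. No extrapolation
is allowed, except that cross-validation folds may evaluate the fitted
spline's natural extension over the full data range when a boundary bin
is held out — otherwise boundary folds would be undefined.

`percent_pruned` divides the pruning period into `k` equal intervals and
expresses each interval's density drop as a percent of the peak (start)
density, making the statistic invariant to the units of density.
`loo_rate_test` repeats the fit leaving out one sample or one time bin
per fold and reports fold means, fold SDs, and unpaired t-tests between
successive intervals. A caution inherited from the method itself: LOO
folds share almost all their data, so fold SDs underestimate the true
sampling variability and the fold t-test is anti-conservative; the test
suite therefore also checks sign stability across independent synthetic
replicates rather than trusting the p-value under the null.

`adjust_3d` applies the stereological thickness correction
`t / (t + d)` to convert planar profile densities toward 3D number
densities. The exact correction used for the original measurements is not
specified in the available material; this standard Abercrombie-style form
is a clearly labeled surrogate and leaves all percent-pruned statistics
unchanged whenever the object diameter does not vary with age.

```{r table1}
table1 <- read_density_tsv(system.file("extdata",
                                       "barrel_density_table.tsv",
                                       package = "prunenet"))
loo_rate_test(table1, k = 2, scheme = "timepoint",
              start_age = 19, end_age = 39)
```

## Synthetic data generation

`gen_density` produces per-animal density series from exponential,
linear, or piecewise-linear decay shapes plus zero-truncated Gaussian
noise; the defaults (peak 3.3 at P19, plateau 1.6 by P40, noise SD 0.3,
three animals per timepoint, 12 timepoints) mirror the scale of the
packaged empirical per-timepoint table. What the generator does *not*
emulate: classifier detection noise, per-animal staining quality, and
within-animal spatial heterogeneity — passing recovery tests therefore
demonstrates the statistic's behavior under idealized sampling noise, not
under the full measurement process. `gen_traffic` produces Zipf-like
origin–destination matrices (real traffic is heavy-tailed) that parse
through the same reader as empirical data.

## Numerical and design choices

* **Tie-breaking.** Minimum-hop routing samples uniformly among all
  shortest paths (path-count-weighted predecessor sampling), avoiding
  systematic usage bias. This is a genuine modeling choice: consistent
  (routing-table-like) tie-breaking concentrates each node's traffic on
  few edges and can produce markedly more hub-like final networks; the
  uniform choice is the neutral default and the one this package's
  results are based on.
* **Unroutable training pairs** contribute no usage and are counted in
  the trace; nothing routes around disconnection during training.
* **Usage is cumulative** across intervals and is discarded with a pruned
  edge.
* **Seeding.** Stochastic entry points take a `seed` argument; experiment
  grids derive per-cell, per-replicate seeds from the base seed and the
  cell label, so adding cells never perturbs existing cells.
* **Problem sizes.** Simulation-based tests and the acceptance script run
  at `n = 200`, `B = 2n`, `p = 10n`, 10 intervals and 3 replicates;
  theory validation uses 200–400 Monte-Carlo draws per grid cell and
  motif analysis a 1000-sample null ensemble. These sizes keep every
  experiment in seconds-to-minutes on one core while staying inside the
  regime where the comparative orderings are stable across seeds.

## Known limitations

* At `n = 200` with `p = 10n`, usage-based pruning leaves a few percent
  of test pairs unroutable (sources or targets whose last low-usage edges
  fall below the final removal threshold); with the `2n` disconnection
  penalty this dominates mean efficiency, so the spanning-tree growing
  baseline — which can never strand a pair — outperforms constant-rate
  pruning on penalized efficiency at this scale. The comparative claims
  that are stable at desk scale, and asserted in the test suite, are the
  schedule ordering (decreasing < constant < increasing), the unroutable
  and energy orderings, and pruning's advantage over the no-learning
  baseline.
* The robustness convention bounds achievable between-algorithm folds
  (see above).
* `predict_pq` reproduces orderings, not magnitudes; its ratios run about
  a factor of two above the simulator at `n = 200`.
* The flow model's reward is per-episode edge membership in a surviving
  route, not per-path counting; with 0.65 edge failure its usage signal
  collapses once the network is sparse, which favors late-pruning
  schedules at desk scale.
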