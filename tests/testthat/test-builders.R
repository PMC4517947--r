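# builders are exercised at small n so each case runs in well under a second

test_that("pruning keeps exactly the trained direct edges when budget matches", {
  # all training pairs are direct on the clique, so only their edges carry
  # usage; with B equal to the number of distinct pairs the final network
  # is exactly those edges, regardless of seed
  d <- make_distribution("empirical", n = 4,
                         pairs = rbind(c(0, 2), c(1, 3), c(0, 3)),
                         counts = c(5, 5, 5))
  for (seed in 1:5) {
    tr <- build_by_pruning(d, 4, 3, schedule = "ending", p = 15, seed = seed)
    el <- network_edges(tr$network)
    expect_equal(el[order(el[, 1], el[, 2]), , drop = FALSE],
                 cbind(from = c(0L, 0L, 1L), to = c(2L, 3L, 3L)),
                 ignore_attr = TRUE)
    expect_true(all(tr$final_usage > 0))
    expect_equal(sum(tr$final_usage), 15)  # one increment per direct hop
  }
})

test_that("per-interval edge counts follow the schedule exactly", {
  d <- make_distribution("two_patch", n = 30)
  sched <- make_schedule("decreasing", E0 = 870, B = 60, K = 10)
  tr <- build_by_pruning(d, 30, 60, schedule = sched, p = 300, seed = 2)
  expect_equal(tr$edges_during, c(870L, edges_after(sched)[-10]))
  expect_equal(edge_count(tr$network), 60L)
  expect_equal(trace_energy(tr), schedule_energy(sched))
  # minimal stream: one pair per interval
  tr1 <- build_by_pruning(d, 30, 60, schedule = "constant", p = 10, seed = 3)
  expect_equal(edge_count(tr1$network), 60L)
})

test_that("identical seeds reproduce identical build traces", {
  d <- make_distribution("two_s_patch", n = 40)
  a <- build_by_pruning(d, 40, 80, "decreasing", p = 400, seed = 99)
  b <- build_by_pruning(d, 40, 80, "decreasing", p = 400, seed = 99)
  expect_identical(a$network$adj, b$network$adj)
  expect_identical(a$edges_during, b$edges_during)
  f1 <- build_by_flow(d, 40, 80, "constant", p = 200, seed = 5)
  f2 <- build_by_flow(d, 40, 80, "constant", p = 200, seed = 5)
  expect_identical(f1$network$adj, f2$network$adj)
})

test_that("flow episodes reward exactly the edges on surviving routes", {
  # no failures on a clique: every edge lies on an s->t route except those
  # entering the source or leaving the target (verified by enumeration)
  d <- make_distribution("empirical", n = 5, pairs = rbind(c(0, 4)),
                         counts = 1)
  tr <- build_by_flow(d, 5, 19, schedule = "ending", p = 1, fail_prob = 0,
                      seed = 1)
  # reconstruct which surviving edges carry usage
  el <- network_edges(tr$network)
  used <- el[tr$final_usage > 0, , drop = FALSE]
  onpath <- vapply(seq_len(nrow(el)), function(i) {
    u <- el[i, 1] + 1L; v <- el[i, 2] + 1L
    any(vapply(bf_paths(make_clique(5)$adj, 1, 5),
               function(p) any(p[-length(p)] == u & p[-1] == v),
               logical(1)))
  }, logical(1))
  expect_equal(tr$final_usage > 0, onpath)
  expect_equal(sum(tr$final_usage), 13)  # 20 edges minus the 7 into s / out of t
  # near-certain failure: no edge rewarded
  trf <- build_by_flow(d, 5, 19, schedule = "ending", p = 1,
                       fail_prob = 0.999, seed = 1)
  expect_equal(sum(trf$final_usage), 0)
  expect_equal(formals(build_by_flow)$fail_prob, 0.65)
})

test_that("growing installs a doubled spanning tree and never strands a pair", {
  d <- make_distribution("two_patch", n = 25)
  # zero shortcut budget: output is exactly the doubled tree
  tr <- build_by_growing(d, 25, 48, p = 250, seed = 6)
  adj <- tr$network$adj
  expect_equal(sum(adj), 48L)
  expect_true(all(adj == t(adj)))  # every tree edge is a reciprocal arc pair
  g <- as_igraph(tr$network)
  expect_true(igraph::is_connected(g, mode = "strong"))
  # with shortcut budget, exactly B edges and still zero unroutable pairs
  tr2 <- build_by_growing(d, 25, 100, p = 500, seed = 6)
  expect_equal(edge_count(tr2$network), 100L)
  set.seed(31)
  test <- sample_pairs(d, 400)
  expect_equal(unroutable(tr2$network, test), 0L)
  expect_error(build_by_growing(d, 25, 40, p = 100), "infeasible budget")
})

test_that("shortcuts target the demanded distance-2 hops", {
  # single hot pair: every added shortcut must shorten its observed route,
  # i.e. connect nodes two hops apart on it
  d <- make_distribution("empirical", n = 12, pairs = rbind(c(0, 11)),
                         counts = 1)
  tr <- build_by_growing(d, 12, 26, p = 120, seed = 13)  # 22 tree arcs + 4
  base <- build_by_growing(d, 12, 22, p = 120, seed = 13)$network
  extra <- which(tr$network$adj & !base$adj, arr.ind = TRUE)
  expect_gt(nrow(extra), 0)
  # route 0 -> 11 got strictly shorter than in the bare tree
  expect_lt(length(shortest_path(tr$network, 0, 11)),
            length(shortest_path(base, 0, 11)) + 1L)
})

test_that("no-learning selects uniform random edges of the right count", {
  expect_equal(edge_count(build_no_learning(6, 30, seed = 1)$network), 30L)
  expect_identical(build_no_learning(6, 30, seed = 1)$network$adj,
                   make_clique(6)$adj)
  set.seed(10)
  picks <- replicate(1000, network_edges(build_no_learning(2, 1)$network)[1])
  expect_gt(mean(picks == 0), 0.45)
  expect_lt(mean(picks == 0), 0.55)
  # under two_patch roles, ~25% of random edges point targets -> sources
  frac <- mean(replicate(50, {
    el <- network_edges(build_no_learning(40, 100)$network)
    mean(el[, 1] >= 20 & el[, 2] < 20)
  }))
  expect_lt(abs(frac - 100 / 390), 0.02)  # 20*20/(40*39) exact share
})
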