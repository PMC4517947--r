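toy5 <- routing_network(5, rbind(c(0, 1), c(1, 4), c(0, 2), c(2, 3),
                                 c(3, 4)))

test_that("efficiency averages hop counts with a penalty for disconnection", {
  stream <- rbind(c(0, 4), c(0, 3))
  expect_equal(efficiency(make_clique(6), stream), 1.0)
  expect_equal(efficiency(toy5, stream), 2.0)  # both pairs at distance 2
  empty <- routing_network(4)
  expect_equal(efficiency(empty, rbind(c(0, 1)), penalty = 8), 8)
  expect_error(efficiency(make_clique(4), matrix(0, 0, 2)), "empty test")
  expect_error(efficiency(make_clique(4), rbind(c(0, 1)), penalty = 2),
               "exceed n")
  # order invariance: the mean is over a multiset
  set.seed(2)
  net <- random_net(8, 0.3)
  s8 <- sample_pairs(make_distribution("two_patch", n = 8), 50)
  expect_equal(efficiency(net, s8), efficiency(net, s8[sample(50), ]))
})

test_that("unroutable counts disconnected pairs", {
  stream <- rbind(c(0, 1), c(1, 2), c(2, 0))
  expect_equal(unroutable(make_clique(3), stream), 0L)
  expect_equal(unroutable(routing_network(3), stream), 3L)
})

test_that("robustness counts the primary route plus near-shortest survivors", {
  # unique path s -> a -> t
  expect_equal(robustness(routing_network(3, rbind(c(0, 1), c(1, 2))),
                          rbind(c(0, 2))), 1)
  # direct edge plus a 2-hop alternative: both count
  expect_equal(robustness(routing_network(3, rbind(c(0, 2), c(0, 1),
                                                   c(1, 2))),
                          rbind(c(0, 2))), 2)
  # two node-disjoint 2-hop routes, no direct edge
  expect_equal(robustness(routing_network(4, rbind(c(0, 1), c(1, 3),
                                                   c(0, 2), c(2, 3))),
                          rbind(c(0, 3))), 2)
  # slack 0 rejects the one-extra-hop alternative
  expect_equal(robustness(routing_network(3, rbind(c(0, 2), c(0, 1),
                                                   c(1, 2))),
                          rbind(c(0, 2)), slack = 0), 1)
  # disconnected pair scores zero
  expect_equal(robustness(routing_network(3, rbind(c(0, 1))),
                          rbind(c(0, 2))), 0)
})

test_that("robustness matches the exhaustive-enumeration oracle on small graphs", {
  set.seed(77)
  for (trial in 1:60) {
    n <- sample(4:6, 1)
    net <- random_net(n, runif(1, 0.25, 0.7))
    st <- sample(n, 2)
    expect_equal(robustness(net, rbind(st - 1L)),
                 bf_robustness(net$adj, st[1], st[2]),
                 info = sprintf("trial %d", trial))
  }
})

test_that("deleting an edge never improves efficiency", {
  set.seed(12)
  d <- make_distribution("two_patch", n = 10)
  for (trial in 1:25) {
    net <- random_net(10, 0.4)
    test <- sample_pairs(d, 40)
    base <- efficiency(net, test)
    el <- network_edges(net)
    cut <- remove_edges(net, el[sample(nrow(el), 1), , drop = FALSE])
    expect_gte(efficiency(cut, test), base)
  }
})

test_that("evaluate bundles metrics deterministically from a trace", {
  d <- make_distribution("two_patch", n = 30)
  tr <- build_by_pruning(d, 30, 60, "constant", p = 300, seed = 4)
  set.seed(9)
  test <- sample_pairs(d, 200)
  e1 <- evaluate(tr, test)
  e2 <- evaluate(tr, test)
  expect_identical(e1[c("efficiency", "robustness", "unroutable", "energy")],
                   e2[c("efficiency", "robustness", "unroutable", "energy")])
  expect_equal(e1$energy, trace_energy(tr))
  expect_equal(e1$penalty, 60)
  # a clique-budget no-learning network is the clique: efficiency 1
  full <- build_no_learning(10, 90, seed = 1)
  expect_equal(evaluate(full, rbind(c(0, 5), c(3, 9)))$efficiency, 1.0)
})
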