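test_that("partition layouts follow each distribution kind", {
  d <- make_distribution("two_patch", n = 1000)
  expect_length(d$sources, 500)
  expect_length(d$targets, 500)
  expect_equal(pair_probability(d, 0, 999), 1 / 250000)
  expect_equal(pair_probability(d, 999, 0), 0)  # targets never send

  du <- make_distribution("two_patch_unbalanced", n = 800)
  expect_length(du$sources, 200)
  expect_length(du$targets, 600)

  ds <- make_distribution("two_s_patch", n = 100)
  expect_length(ds$sel_sources, 5)
  expect_length(ds$sel_targets, 5)

  d4 <- make_distribution("four_patch", n = 100)
  expect_length(d4$sources1, 25)
  expect_length(d4$targets2, 25)
  expect_equal(length(intersect(d4$sources1, d4$sources2)), 0)

  de <- make_distribution("empirical", n = 2,
                          pairs = rbind(c(0, 1), c(1, 0)), counts = c(3, 1))
  expect_equal(pair_probability(de, 0, 1), 0.75)
  expect_error(make_distribution("empirical", n = 2,
                                 pairs = rbind(c(0, 0)), counts = 5),
               "self-pairs")
  expect_error(make_distribution("two_patch", n = 1), "n >= 2")
})

test_that("sampled pair frequencies match analytic probabilities", {
  set.seed(11)
  for (kind in c("two_patch", "two_s_patch", "two_patch_unbalanced",
                 "four_patch")) {
    d <- make_distribution(kind, n = 20)
    ps <- sample_pairs(d, 1e5)
    tab <- table(factor(paste(ps[, 1], ps[, 2]),
                        levels = {
                          grid <- expand.grid(s = 0:19, t = 0:19)
                          paste(grid$s, grid$t)
                        }))
    grid <- expand.grid(s = 0:19, t = 0:19)
    probs <- mapply(function(s, t) pair_probability(d, s, t),
                    grid$s, grid$t)
    # 3-sigma multinomial bound per cell
    sds <- sqrt(1e5 * probs * (1 - probs))
    expect_true(all(abs(as.numeric(tab) - 1e5 * probs) <=
                      pmax(3 * sds, 1e-9)),
                info = kind)
  }
})

test_that("two_s_patch selective block receives its mixture share", {
  set.seed(3)
  d <- make_distribution("two_s_patch", n = 100)  # x = 0.5, 10% selective
  ps <- sample_pairs(d, 1e5)
  insel <- ps[, 1] %in% d$sel_sources & ps[, 2] %in% d$sel_targets
  expected <- (1 - d$x) + d$x * 0.1^2
  expect_lt(abs(mean(insel) - expected), 3 * sqrt(expected / 1e5) + 0.005)
})

test_that("Hubel-Wiesel shutoff silences the second source set exactly", {
  set.seed(4)
  d <- make_distribution("four_patch_hw", n = 80, shutoff_fraction = 0.5)
  p <- 2000
  ps <- sample_pairs(d, p, phase = "train")
  post <- ps[(p / 2 + 1):p, ]
  expect_equal(sum(post[, 1] %in% d$sources2), 0L)
  # recruited: first sources now reach the second target patch too
  expect_gt(sum(post[, 2] %in% d$targets2), 0L)
  pre <- ps[1:(p / 2), ]
  expect_gt(sum(pre[, 1] %in% d$sources2), 0L)
  # test phase uses the post-shutoff regime throughout
  expect_equal(sum(sample_pairs(d, 500, phase = "test")[, 1] %in%
                     d$sources2), 0L)
  expect_equal(nrow(sample_pairs(d, 1)), 1L)
})

test_that("traffic CSV parsing normalizes counts and rejects bad rows", {
  csv <- c("source,target,count", "A,B,1", "B,A,1", "A,C,2")
  d <- read_traffic_csv(csv)
  expect_equal(d$n, 3L)
  expect_equal(sort(d$prob), c(0.25, 0.25, 0.5))
  expect_equal(d$labels, c("A", "B", "C"))
  expect_error(read_traffic_csv(c("source,target,count", "A,A,5")),
               "row 1: self-pair")
  expect_error(read_traffic_csv(c("source,target,count", "A,B,0")),
               "positive integers")
  # synthetic Zipf matrix over 122 cities parses to a 122-node distribution
  traffic <- gen_traffic(traffic_gen_spec(cities = 122, pairs = 1000),
                         seed = 9)
  dz <- read_traffic_csv(traffic)
  expect_equal(dz$n, 122L)
  expect_equal(nrow(dz$pairs), 1000L)
})
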