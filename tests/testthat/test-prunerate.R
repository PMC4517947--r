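table1 <- read_density_tsv(system.file("extdata", "barrel_density_table.tsv",
                                       package = "prunenet"))

lin_series <- function(ages = seq(19, 39, by = 4), a = 4, b = -0.1) {
  density_series(data.frame(sample_id = paste0("s", seq_along(ages)),
                            age_days = ages,
                            density = a + b * (ages - ages[1])), bin = FALSE)
}

test_that("spline fit reproduces polynomial data and refuses extrapolation", {
  curve <- fit_density_curve(lin_series(), method = "interp")
  at <- seq(19, 39, by = 4)
  expect_lt(max(abs(curve(at) - (4 - 0.1 * (at - 19)))), 1e-6)
  expect_error(curve(45), "outside observed range")
  expect_error(curve(10), "outside observed range")
  expect_warning(fit_density_curve(lin_series(ages = c(19, 29, 39))),
                 "fewer than 4")
})

test_that("the empirical density table yields a decreasing developmental curve", {
  curve <- fit_density_curve(table1)
  expect_gt(curve(19), curve(40))
  pp <- percent_pruned(curve, 19, 39, k = 2)
  expect_gt(pp[1], pp[2])  # early pruning dominates
  expect_gt(pp[1], 0)
})

test_that("percent_pruned is exact on linear decay and scale invariant", {
  curve <- fit_density_curve(lin_series(a = 4, b = -0.1), method = "interp")
  expect_equal(percent_pruned(curve, 19, 39, 2), c(25, 25), tolerance = 1e-9)
  # convex (exponential-like) decay pushes mass into the first interval
  ages <- seq(19, 39, by = 2)
  ex <- density_series(data.frame(sample_id = seq_along(ages),
                                  age_days = ages,
                                  density = 1.6 + 1.7 * exp(-(ages - 19) / 7)),
                       bin = FALSE)
  ppe <- percent_pruned(fit_density_curve(ex, method = "interp"), 19, 39, 2)
  expect_gt(ppe[1], ppe[2])
  # multiplying all densities by a constant changes nothing
  sc <- lin_series(); sc$density <- sc$density * 37.5
  expect_equal(percent_pruned(fit_density_curve(sc, method = "interp"),
                              19, 39, 2),
               percent_pruned(curve, 19, 39, 2), tolerance = 1e-8)
  expect_error(percent_pruned(curve, 39, 19, 2), "precede")
})

test_that("leave-one-timepoint folds cover all 12 standard bins", {
  rep <- loo_rate_test(table1, k = 2, scheme = "timepoint",
                       start_age = 19, end_age = 39)
  expect_equal(rep$n_folds, 12L)
  expect_gt(rep$mean[1], rep$mean[2])
  expect_lt(rep$p_value, 0.01)
})

test_that("LOO recovers generating interval percentages from noisy animals", {
  spec <- density_gen_spec("piecewise", peak = 3.3, plateau = 1.6,
                           peak_age = 19, end_age = 39, noise_sd = 0.3,
                           animals_per_timepoint = 6, timepoints = 11,
                           knot_ages = c(19, 29, 39),
                           knot_densities = c(3.3, 2.2, 1.7))
  truth <- 100 * c(3.3 - 2.2, 2.2 - 1.7) / 3.3
  rep <- loo_rate_test(gen_density(spec, seed = 8), k = 2,
                       scheme = "sample", start_age = 19, end_age = 39,
                       method = "interp")
  # sampling SD of an interval estimate from the generator's noise model:
  # each boundary is a bin mean of 6 animals with noise SD 0.3, scaled to
  # percent of peak (fold SDs alone understate it -- folds share the data)
  se_est <- (100 / 3.3) * 0.3 * sqrt(2 / 6)
  expect_lt(abs(rep$mean[1] - truth[1]), 2 * (rep$sd[1] + se_est))
  expect_lt(abs(rep$mean[2] - truth[2]), 2 * (rep$sd[2] + se_est))
  expect_gt(rep$mean[1], rep$mean[2])
  expect_lt(rep$p_value, 0.01)
})

test_that("a linear decay shows no systematic rate decrease", {
  diffs <- vapply(1:6, function(s) {
    lin <- gen_density(density_gen_spec("linear", peak = 3.3, plateau = 1.6,
                                        peak_age = 19, end_age = 40,
                                        noise_sd = 0.3,
                                        animals_per_timepoint = 3,
                                        timepoints = 12), seed = s)
    r <- loo_rate_test(lin, k = 2, scheme = "sample",
                       start_age = 19, end_age = 39)
    r$mean[1] - r$mean[2]
  }, numeric(1))
  # fold differences scatter around zero instead of a one-sided signal
  expect_lt(abs(mean(diffs)), 5)
  exp_diff <- {
    e <- gen_density(density_gen_spec("exponential", peak = 3.3,
                                      plateau = 1.6, peak_age = 19,
                                      end_age = 40, noise_sd = 0.3,
                                      animals_per_timepoint = 3,
                                      timepoints = 12), seed = 1)
    r <- loo_rate_test(e, k = 2, scheme = "sample",
                       start_age = 19, end_age = 39)
    r$mean[1] - r$mean[2]
  }
  expect_gt(exp_diff, 15)  # the real decreasing-rate signal is far larger
})

test_that("fold dispersion shrinks with more animals per timepoint", {
  sds <- vapply(c(3L, 12L), function(a) {
    spec <- density_gen_spec("exponential", peak = 3.3, plateau = 1.6,
                             peak_age = 19, end_age = 39, noise_sd = 0.3,
                             animals_per_timepoint = a, timepoints = 11)
    loo_rate_test(gen_density(spec, seed = 31), k = 2, scheme = "sample",
                  start_age = 19, end_age = 39)$sd[1]
  }, numeric(1))
  expect_lt(sds[2], sds[1])
})

test_that("3D count adjustment rescales without distorting relative rates", {
  expect_equal(adjust_3d(table1, 50, 0)$density, table1$density)
  adj <- adjust_3d(table1, 50, 0.5)
  expect_equal(adj$density, table1$density * 50 / 50.5)
  expect_equal(percent_pruned(fit_density_curve(adj), 19, 39, 2),
               percent_pruned(fit_density_curve(table1), 19, 39, 2),
               tolerance = 1e-7)
  # age-varying synapse size changes the inferred rates
  vad <- adjust_3d(table1, 50, function(age) 0.2 + 0.02 * age)
  expect_false(isTRUE(all.equal(
    percent_pruned(fit_density_curve(vad), 19, 39, 2),
    percent_pruned(fit_density_curve(table1), 19, 39, 2))))
  expect_error(adjust_3d(table1, -1, 0.5), "positive")
})
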