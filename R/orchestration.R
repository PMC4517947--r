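# Experiment driver: builds, evaluates and aggregates (algorithm x
# schedule) comparison grids, and the airline application on an empirical
# traffic distribution. Replicate seeds are derived cell-wise from the
# base seed so adding cells never perturbs existing cells.

#' Experiment configuration
#'
#' @param dist_kind Pair-distribution kind (see [make_distribution()]), or
#'   a ready `pair_distribution` object.
#' @param n Node count.
#' @param B Edge budget (default `2 * n`: average of 2 connections per
#'   node, the sparse regime).
#' @param cells List of cells to compare; each a
#'   `list(algorithm =, schedule =)` with algorithm in
#'   `prune`/`flow`/`grow`/`random` (schedule ignored for the last two).
#'   Default: the four schedules under `prune`, plus `grow` and `random`.
#' @param K Pruning intervals.
#' @param p_train,p_test Training/test stream sizes (default `10 * n`).
#' @param fail_prob Signal-loss probability for the flow model.
#' @param replicates Simulation runs per cell (default 3).
#' @param seed Base seed.
#' @param penalty,slack Evaluation parameters (defaults `2n` and 1).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(dist_kind = "two_patch", n = 200L, B = 2L * n,
                              cells = NULL, K = 10L, p_train = 10L * n,
                              p_test = p_train, fail_prob = 0.65,
                              replicates = 3L, seed = 1L,
                              penalty = 2 * n, slack = 1L) {
  if (replicates < 1) stop("'replicates' must be >= 1")
  if (is.null(cells))
    cells <- c(lapply(c("constant", "increasing", "decreasing", "ending"),
                      function(s) list(algorithm = "prune", schedule = s)),
               list(list(algorithm = "grow", schedule = NA),
                    list(algorithm = "random", schedule = NA)))
  structure(list(dist_kind = dist_kind, n = as.integer(n),
                 B = as.integer(B), cells = cells, K = as.integer(K),
                 p_train = as.integer(p_train), p_test = as.integer(p_test),
                 fail_prob = fail_prob, replicates = as.integer(replicates),
                 seed = as.integer(seed), penalty = penalty, slack = slack),
            class = "experiment_config")
}

# deterministic 31-bit seed for (cell label, replicate) under a base seed
.cell_seed <- function(base, label, rep) {
  h <- 5381
  for (ch in utf8ToInt(paste0(label, "#", rep)))
    h <- (h * 33 + ch) %% 2147483647
  as.integer(bitwXor(as.integer(base), as.integer(h)) %% 2147483647L)
}

.build_cell <- function(cell, dist, cfg, seed) {
  switch(cell$algorithm,
    prune = build_by_pruning(dist, cfg$n, cfg$B, schedule =
               make_schedule(cell$schedule, E0 = cfg$n * (cfg$n - 1L),
                             B = cfg$B, K = cfg$K),
               p = cfg$p_train, seed = seed),
    flow = build_by_flow(dist, cfg$n, cfg$B, schedule =
               make_schedule(cell$schedule, E0 = cfg$n * (cfg$n - 1L),
                             B = cfg$B, K = cfg$K),
               p = cfg$p_train, fail_prob = cfg$fail_prob, seed = seed),
    grow = build_by_growing(dist, cfg$n, cfg$B, p = cfg$p_train,
                            K = cfg$K, seed = seed),
    random = build_no_learning(cfg$n, cfg$B, seed = seed),
    stop("unknown algorithm: ", cell$algorithm))
}

#' Run an algorithm/schedule comparison experiment
#'
#' For every cell and replicate: build the network on a fresh training
#' stream, evaluate efficiency, robustness, unroutable count and energy
#' on a fresh test stream from the same distribution, and aggregate mean
#' and SD per cell.
#'
#' @param config An [experiment_config()].
#' @return A `comparison_report`: data frame of per-cell aggregates, with
#'   the per-replicate table in `attr(, "replicates")`.
#' @export
run_comparison <- function(config) {
  dist <- if (inherits(config$dist_kind, "pair_distribution"))
    config$dist_kind else make_distribution(config$dist_kind, n = config$n)
  rows <- list()
  for (cell in config$cells) {
    label <- if (cell$algorithm %in% c("prune", "flow"))
      paste0(cell$algorithm, "/", cell$schedule) else cell$algorithm
    for (r in seq_len(config$replicates)) {
      sd_build <- .cell_seed(config$seed, label, r)
      trace <- .build_cell(cell, dist, config, sd_build)
      set.seed(.cell_seed(config$seed, paste0(label, "/test"), r))
      test <- sample_pairs(dist, config$p_test, phase = "test")
      ev <- evaluate(trace, test, penalty = config$penalty,
                     slack = config$slack)
      rows[[length(rows) + 1L]] <-
        data.frame(cell = label, algorithm = cell$algorithm,
                   schedule = if (is.na(cell$schedule %||% NA)) NA_character_
                              else cell$schedule,
                   replicate = r, efficiency = ev$efficiency,
                   robustness = ev$robustness, unroutable = ev$unroutable,
                   energy = ev$energy)
    }
  }
  reps <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(reps, reps$cell), function(d)
    data.frame(cell = d$cell[1], algorithm = d$algorithm[1],
               schedule = d$schedule[1],
               efficiency = mean(d$efficiency), efficiency_sd = sd(d$efficiency),
               robustness = mean(d$robustness), robustness_sd = sd(d$robustness),
               unroutable = mean(d$unroutable), energy = mean(d$energy))))
  agg <- agg[order(match(agg$cell, unique(reps$cell))), ]
  rownames(agg) <- NULL
  structure(agg, replicates = reps, config = config,
            class = c("comparison_report", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.comparison_report <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("comparison_report: n=%d, B=%d, '%s', %d replicate(s)\n",
              cfg$n, cfg$B,
              if (inherits(cfg$dist_kind, "pair_distribution"))
                cfg$dist_kind$kind else cfg$dist_kind,
              cfg$replicates))
  df <- as.data.frame(x)
  for (col in c("efficiency", "efficiency_sd", "robustness",
                "robustness_sd", "unroutable", "energy"))
    df[[col]] <- signif(df[[col]], 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report as JSON and TSV
#'
#' @param report A `comparison_report`.
#' @param json,tsv Output paths (either may be `NULL`).
#' @export
write_report <- function(report, json = NULL, tsv = NULL) {
  if (!is.null(tsv))
    utils::write.table(as.data.frame(report), tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(json)) {
    cfg <- attr(report, "config")
    jsonlite::write_json(list(
      config = cfg[setdiff(names(cfg), "cells")],
      cells = as.data.frame(report),
      replicates = attr(report, "replicates")),
      json, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(report)
}

#' Airline-style application on an empirical traffic distribution
#'
#' Builds pruning networks per schedule on an origin-destination traffic
#' distribution (where a city can be both source and target) and
#' evaluates them with freshly resampled test pairs. Robustness here
#' counts alternative routes with the *same* number of hops
#' (`slack = 0`).
#'
#' @param traffic A traffic CSV path/text (see [read_traffic_csv()]) or a
#'   ready empirical `pair_distribution`.
#' @param B Edge budget (default `3 *` number of cities).
#' @param schedules Schedule shapes to compare.
#' @param replicates Runs per schedule (default 5).
#' @param p_train,p_test Stream sizes (default `10 * n`).
#' @param seed Base seed.
#' @return A `comparison_report`.
#' @export
run_airline <- function(traffic, B = NULL,
                        schedules = c("constant", "increasing", "decreasing"),
                        replicates = 5L, p_train = NULL, p_test = NULL,
                        seed = 1L) {
  dist <- if (inherits(traffic, "pair_distribution")) traffic
          else read_traffic_csv(traffic)
  n <- dist$n
  if (is.null(B)) B <- 3L * n
  cfg <- experiment_config(dist_kind = dist, n = n, B = B,
                           cells = lapply(schedules, function(s)
                             list(algorithm = "prune", schedule = s)),
                           p_train = p_train %||% (10L * n),
                           p_test = p_test %||% (10L * n),
                           replicates = replicates, seed = seed,
                           slack = 0L)
  run_comparison(cfg)
}
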