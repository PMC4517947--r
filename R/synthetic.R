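# Fixture generators: per-animal synapse-density series with controllable
# decay shape and noise, and Zipf-like origin-destination traffic matrices.
# Everything the test suite consumes can be generated here, seeded.

#' Specification for a synthetic density series
#'
#' Describes a decaying-with-plateau developmental density curve plus
#' per-animal Gaussian noise. Shapes: `exponential`
#' (`plateau + (peak - plateau) * exp(-decay_rate * (age - peak_age))`),
#' `linear` (straight line from peak to plateau), and `piecewise`
#' (piecewise-linear through `knot_ages` / `knot_densities`).
#'
#' @param shape `"exponential"`, `"linear"`, or `"piecewise"`.
#' @param peak,plateau Peak and plateau densities, `peak > plateau >= 0`.
#' @param peak_age,end_age Period bounds (days).
#' @param noise_sd Per-measurement Gaussian noise SD (>= 0); draws are
#'   truncated at zero.
#' @param animals_per_timepoint Animals sampled at each timepoint.
#' @param timepoints Number of equally spaced ages, or an explicit age
#'   vector.
#' @param decay_rate Exponential rate; default reaches ~5\% of the drop
#'   by `end_age`.
#' @param knot_ages,knot_densities Knots for `shape = "piecewise"`.
#' @return A `density_gen_spec`.
#' @export
density_gen_spec <- function(shape = c("exponential", "linear", "piecewise"),
                             peak = 3.3, plateau = 1.6,
                             peak_age = 19, end_age = 40,
                             noise_sd = 0.3, animals_per_timepoint = 3L,
                             timepoints = 12L,
                             decay_rate = 3 / (end_age - peak_age),
                             knot_ages = NULL, knot_densities = NULL) {
  shape <- match.arg(shape)
  if (peak <= plateau || plateau < 0) stop("need peak > plateau >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (peak_age >= end_age) stop("'peak_age' must precede 'end_age'")
  ages <- if (length(timepoints) > 1) as.numeric(timepoints)
          else seq(peak_age, end_age, length.out = timepoints)
  if (shape == "piecewise") {
    if (is.null(knot_ages) || is.null(knot_densities))
      stop("piecewise shape needs knot_ages and knot_densities")
    fshape <- approxfun(knot_ages, knot_densities, rule = 2)
  } else if (shape == "linear") {
    fshape <- function(a) peak + (plateau - peak) *
      (a - peak_age) / (end_age - peak_age)
  } else {
    fshape <- function(a) plateau + (peak - plateau) *
      exp(-decay_rate * (a - peak_age))
  }
  structure(list(shape = shape, ages = ages, f = fshape,
                 noise_sd = noise_sd,
                 animals_per_timepoint = as.integer(animals_per_timepoint)),
            class = "density_gen_spec")
}

#' Generate a synthetic per-animal density series
#'
#' @param spec A [density_gen_spec()].
#' @param seed Optional integer seed.
#' @return A `density_series` (one row per animal per timepoint);
#'   `sample_id` is `a<age>_<replicate>`.
#' @export
gen_density <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- expand.grid(rep = seq_len(spec$animals_per_timepoint),
                      age = spec$ages)
  dens <- pmax(0, spec$f(rows$age) + rnorm(nrow(rows), 0, spec$noise_sd))
  density_series(data.frame(
    sample_id = sprintf("a%g_%d", rows$age, rows$rep),
    age_days = rows$age, density = dens), bin = FALSE)
}

#' Specification for a synthetic traffic matrix
#'
#' @param cities Number of cities.
#' @param pairs Number of ordered city pairs with positive traffic
#'   (`<= cities * (cities - 1)`).
#' @param zipf_exponent Rank-frequency exponent (0 = near-uniform).
#' @param total_passengers Approximate total count mass.
#' @return A `traffic_gen_spec`.
#' @export
traffic_gen_spec <- function(cities = 122L, pairs = 1000L,
                             zipf_exponent = 1, total_passengers = 1e6) {
  if (pairs > cities * (cities - 1L)) stop("more pairs than ordered city pairs")
  structure(list(cities = as.integer(cities), pairs = as.integer(pairs),
                 zipf_exponent = zipf_exponent,
                 total_passengers = total_passengers),
            class = "traffic_gen_spec")
}

#' Generate a synthetic origin-destination traffic CSV
#'
#' Samples `pairs` distinct ordered city pairs and assigns Zipf-distributed
#' passenger counts (heavy-tailed, like real origin-destination data). The
#' output parses with [read_traffic_csv()].
#'
#' @param spec A [traffic_gen_spec()].
#' @param seed Optional integer seed.
#' @return Character vector of CSV lines (header `source,target,count`).
#' @export
gen_traffic <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- spec$cities
  labels <- sprintf("CITY%03d", seq_len(nc))
  all_pairs <- which(row(diag(nc)) != col(diag(nc)))
  pick <- sample(all_pairs, spec$pairs)
  s <- (pick - 1L) %% nc + 1L
  t <- (pick - 1L) %/% nc + 1L
  w <- seq_len(spec$pairs)^(-spec$zipf_exponent)
  counts <- pmax(1, round(spec$total_passengers * w / sum(w)))
  # heavy ranks land on random pairs
  counts <- counts[sample.int(spec$pairs)]
  c("source,target,count",
    sprintf("%s,%s,%d", labels[s], labels[t], counts))
}
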