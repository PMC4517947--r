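# Developmental pruning-rate statistic. Synapse-density measurements
# (sample, postnatal age in days, synapses per unit area) are interpolated
# with a spline; the pruning period is divided into equally spaced
# intervals; per-interval percent-pruned (relative to the density at the
# period start) is computed; and leave-one-out cross-validation over
# samples or timepoints yields fold means/SDs and two-sample t-tests
# between successive intervals.

# the standard 12-bin grouping of postnatal ages used for the statistics
.default_bins <- function(age) {
  key <- list(`14` = 14, `17` = 17, `19` = 19, `21.5` = c(21, 22),
              `23.5` = c(23, 24), `26` = 26, `28` = 28, `30` = 30,
              `32.5` = c(32, 33), `35` = c(34, 36), `38` = 38, `40` = 40)
  out <- rep(NA_real_, length(age))
  for (b in names(key)) out[age %in% key[[b]]] <- as.numeric(b)
  out[is.na(out)] <- age[is.na(out)]  # unknown ages bin to themselves
  out
}

#' Construct a synapse-density series
#'
#' @param data Data frame with columns `sample_id`, `age_days`
#'   (positive), `density` (nonnegative).
#' @param bin If `TRUE` (default), attach the standard 12-bin age
#'   grouping (ages 21+22, 23+24, 32+33 and 34+36 share bins); if a
#'   numeric vector of the same length, use it as the bin assignment;
#'   if `FALSE`, every age is its own bin.
#' @return A `density_series` data frame with a `bin` column.
#' @export
density_series <- function(data, bin = TRUE) {
  need <- c("sample_id", "age_days", "density")
  if (!all(need %in% names(data)))
    stop("need columns sample_id, age_days, density")
  if (any(data$age_days <= 0)) stop("ages must be positive")
  if (any(data$density < 0)) stop("densities must be nonnegative")
  if (length(unique(data$age_days)) < 2)
    stop("need at least 2 distinct ages")
  df <- data.frame(sample_id = as.character(data$sample_id),
                   age_days = as.numeric(data$age_days),
                   density = as.numeric(data$density))
  df$bin <- if (isTRUE(bin)) .default_bins(df$age_days)
            else if (identical(bin, FALSE)) df$age_days
            else as.numeric(bin)
  structure(df, class = c("density_series", "data.frame"))
}

#' Read a density table (TSV: sample_id, age_days, density)
#'
#' @param file Path to a tab-separated file with a header.
#' @param ... Passed to [density_series()].
#' @export
read_density_tsv <- function(file, ...) {
  density_series(utils::read.delim(file), ...)
}

#' Fit a continuous density-versus-age curve
#'
#' Fits a cubic smoothing spline (smoothing chosen by generalized
#' cross-validation) through the per-bin mean densities, weighted by the
#' number of measurements per bin; `method = "interp"` gives an exact
#' natural cubic interpolant instead. With fewer than 4 distinct bins the
#' fit falls back to linear interpolation with a warning. The curve is
#' evaluable only within the observed age range (no extrapolation).
#'
#' @param series A `density_series`.
#' @param method `"smooth"` (default) or `"interp"`.
#' @param range Optional evaluable age range overriding the data range
#'   (used by cross-validation folds, which may need the spline's natural
#'   extension just beyond their reduced support).
#' @return A `density_curve`: call it (or `predict`) at ages inside the
#'   observed range.
#' @export
fit_density_curve <- function(series, method = c("smooth", "interp"),
                              range = NULL) {
  method <- match.arg(method)
  agg <- aggregate(density ~ bin, data = series, FUN = mean)
  wt <- as.vector(table(series$bin)[as.character(agg$bin)])
  x <- agg$bin; y <- agg$density
  rng <- if (is.null(range)) base::range(x) else range
  if (length(x) < 4 && !is.null(range))
    stop("linear fallback cannot extend beyond its data range")
  if (length(x) < 4) {
    warning("fewer than 4 distinct ages; falling back to linear fit")
    f <- approxfun(x, y)
  } else if (method == "smooth") {
    fit <- smooth.spline(x, y, w = wt, cv = FALSE)  # GCV smoothing
    f <- function(age) predict(fit, age)$y
  } else {
    f <- splinefun(x, y, method = "natural")
  }
  structure(function(age) {
    if (any(age < rng[1] - 1e-9) || any(age > rng[2] + 1e-9))
      stop(sprintf("age outside observed range [%g, %g]", rng[1], rng[2]))
    f(age)
  }, range = rng, method = method, knots = x, class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  r <- attr(x, "range")
  cat(sprintf("density_curve (%s) over ages [%g, %g], %d knots\n",
              attr(x, "method"), r[1], r[2], length(attr(x, "knots"))))
  invisible(x)
}

#' @export
plot.density_curve <- function(x, ...) {
  r <- attr(x, "range")
  ages <- seq(r[1], r[2], length.out = 200)
  graphics::plot(ages, x(ages), type = "l", col = "red", lwd = 2,
                 xlab = "postnatal age (days)", ylab = "synapse density",
                 ...)
  graphics::points(attr(x, "knots"), x(attr(x, "knots")), pch = 19)
  invisible(x)
}

#' Per-interval percentage of synapses pruned
#'
#' Divides `[start_age, end_age]` into `k` equal intervals and reports,
#' for each, the density drop across the interval as a percentage of the
#' density at `start_age` (the peak). The values sum to
#' `100 * (1 - curve(end) / curve(start))`; negative values indicate a
#' density rise.
#'
#' @param curve A `density_curve`.
#' @param start_age,end_age Period bounds (days), `start < end`.
#' @param k Number of intervals (>= 2 for a rate comparison).
#' @return Numeric vector of length `k` (percent of peak density).
#' @export
percent_pruned <- function(curve, start_age, end_age, k = 2L) {
  if (start_age >= end_age) stop("'start_age' must precede 'end_age'")
  if (k < 1) stop("k must be >= 1")
  bounds <- seq(start_age, end_age, length.out = k + 1L)
  v <- curve(bounds)
  100 * (v[-length(v)] - v[-1]) / v[1]
}

#' Leave-one-out cross-validated pruning-rate test
#'
#' For each fold, one sample (or one age bin) is held out, the density
#' curve is refit on the remainder, and per-interval percent-pruned is
#' recomputed. Reports fold means and standard deviations per interval
#' and an unpaired two-sample t-test between the fold values of each pair
#' of successive intervals; a significantly larger first interval
#' indicates a decreasing pruning rate. Folds whose reduced data cannot
#' support the fit (e.g. the held-out bin was a period boundary) are
#' skipped with a warning.
#'
#' @param series A `density_series`.
#' @param k Number of equal intervals (2 or 5 in the standard analyses).
#' @param scheme `"sample"` (leave one sample out) or `"timepoint"`
#'   (leave one age bin out).
#' @param start_age,end_age Pruning period (defaults: peak-density bin to
#'   the last observed bin).
#' @param method Spline mode passed to [fit_density_curve()].
#' @return A `rate_report`.
#' @export
loo_rate_test <- function(series, k = 2L,
                          scheme = c("sample", "timepoint"),
                          start_age = NULL, end_age = NULL,
                          method = "smooth") {
  scheme <- match.arg(scheme)
  if (is.null(start_age)) {
    agg <- aggregate(density ~ bin, data = series, FUN = mean)
    start_age <- agg$bin[which.max(agg$density)]
  }
  if (is.null(end_age)) end_age <- max(series$bin)
  units <- if (scheme == "sample") unique(series$sample_id)
           else unique(series$bin)
  if (length(units) < 3) stop("need >= 3 folds for the LOO test")
  folds <- matrix(NA_real_, length(units), k)
  for (f in seq_along(units)) {
    keep <- if (scheme == "sample") series$sample_id != units[f]
            else series$bin != units[f]
    sub <- series[keep, , drop = FALSE]
    res <- tryCatch({
      curve <- suppressWarnings(
        fit_density_curve(density_series(sub, bin = sub$bin),
                          method = method, range = range(series$bin)))
      percent_pruned(curve, start_age, end_age, k)
    }, error = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf("fold %s skipped (degenerate after hold-out)",
                      as.character(units[f])))
    } else folds[f, ] <- res
  }
  ok <- stats::complete.cases(folds)
  folds <- folds[ok, , drop = FALSE]
  if (nrow(folds) < 2) stop("fewer than 2 usable folds")
  tests <- lapply(seq_len(k - 1L), function(i)
    t.test(folds[, i], folds[, i + 1L], var.equal = FALSE))
  structure(list(
    k = k, scheme = scheme, start_age = start_age, end_age = end_age,
    boundaries = seq(start_age, end_age, length.out = k + 1L),
    folds = folds, n_folds = nrow(folds),
    mean = colMeans(folds), sd = apply(folds, 2, sd),
    t_stat = vapply(tests, function(t) unname(t$statistic), numeric(1)),
    p_value = vapply(tests, function(t) t$p.value, numeric(1))
  ), class = "rate_report")
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf("rate_report: %d intervals over P%g-P%g, %d leave-one-%s folds\n",
              x$k, x$start_age, x$end_age, x$n_folds, x$scheme))
  for (i in seq_len(x$k))
    cat(sprintf("  interval %d [%5.1f, %5.1f]: %6.2f%% pruned (SD %.2f)\n",
                i, x$boundaries[i], x$boundaries[i + 1], x$mean[i], x$sd[i]))
  for (i in seq_len(x$k - 1L))
    cat(sprintf("  interval %d vs %d: t = %.2f, p = %.3g\n",
                i, i + 1L, x$t_stat[i], x$p_value[i]))
  invisible(x)
}

#' @export
plot.rate_report <- function(x, ...) {
  mids <- (x$boundaries[-1] + x$boundaries[-length(x$boundaries)]) / 2
  bp <- graphics::barplot(x$mean, names.arg = sprintf("P%g-P%g",
                                                      x$boundaries[-(x$k + 1)],
                                                      x$boundaries[-1]),
                          ylab = "% of peak density pruned",
                          ylim = c(min(0, min(x$mean - x$sd)),
                                   max(x$mean + x$sd) * 1.1), ...)
  graphics::arrows(bp, x$mean - x$sd, bp, x$mean + x$sd,
                   angle = 90, code = 3, length = 0.05)
  invisible(x)
}

#' Stereological 3D density adjustment
#'
#' Rescales planar synapse densities by the Abercrombie-style section
#' correction `thickness / (thickness + diameter)`, converting 2D profile
#' counts toward 3D number density. When the object diameter does not
#' change with age, all densities scale by one factor and percent-pruned
#' statistics are unchanged. The exact correction used on the original
#' data is unspecified; this standard surrogate preserves relative
#' comparisons.
#'
#' @param series A `density_series`.
#' @param section_thickness Section thickness (same length unit as
#'   `object_diameter`), positive.
#' @param object_diameter Mean object diameter; a scalar or a function of
#'   age (to model age-dependent synapse size).
#' @return A `density_series` with adjusted densities.
#' @export
adjust_3d <- function(series, section_thickness, object_diameter) {
  if (section_thickness <= 0) stop("'section_thickness' must be positive")
  dia <- if (is.function(object_diameter)) object_diameter(series$age_days)
         else rep(object_diameter, nrow(series))
  if (any(dia < 0)) stop("'object_diameter' must be nonnegative")
  series$density <- series$density *
    section_thickness / (section_thickness + dia)
  series
}
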