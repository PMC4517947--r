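# Pruning-rate schedules. A schedule is the per-interval fraction r_i of the
# *currently existing* edges removed after interval i, i = 1..K; it must
# bring an initial edge count E0 down to exactly the budget B. Four shapes:
#   constant    r_1 = ... = r_K, solving (1 - r)^K E0 = B
#   decreasing  r_i = c * gamma^(i-1), gamma < 1 reversed? no: gamma < 1
#               gives strictly descending removal fractions
#   increasing  same geometric family with gamma > 1 (strictly ascending)
#   ending      r_1..r_{K-1} = 0, the final interval removes down to B
# The proportionality constant c is solved numerically for budget exactness.

#' Construct a pruning-rate schedule
#'
#' @param shape One of `"constant"`, `"increasing"`, `"decreasing"`,
#'   `"ending"`.
#' @param E0 Initial edge count (for clique starts, `n(n-1)`).
#' @param B Final edge budget, `0 < B < E0`.
#' @param K Number of pruning intervals (default 10).
#' @param gamma Geometric ratio of the removal fractions for the monotone
#'   shapes; defaults to 0.5 for `decreasing` and 2 for `increasing`.
#' @return A `prune_schedule` with fields `rates` (r_1..r_K), `removals`
#'   (integer removal counts per interval under the rounding rule), and
#'   `edges` (edge counts after each interval; last element is exactly `B`).
#' @details Integer rounding: interval `i` removes
#'   `round(r_i * current edges)`, clamped so the count never dips below
#'   `B`; the final interval is forced to land exactly on `B`.
#' @examples
#' s <- make_schedule("constant", E0 = 999000, B = 2000, K = 10)
#' round(s$rates[1], 4)
#' @export
make_schedule <- function(shape = c("constant", "increasing", "decreasing",
                                    "ending"),
                          E0, B, K = 10L, gamma = NULL) {
  shape <- match.arg(shape)
  if (B <= 0 || B >= E0) stop("budget must satisfy 0 < B < E0")
  if (K < 1) stop("K must be >= 1")
  E0 <- as.integer(round(E0)); B <- as.integer(round(B)); K <- as.integer(K)
  if (K == 1L) {
    # a single interval can only remove once: every shape degenerates to
    # the ending schedule
    rates <- 1 - B / E0
    shape_used <- shape
  } else if (shape == "ending") {
    rates <- c(rep(0, K - 1L), 1 - B / E0)
    shape_used <- shape
  } else if (shape == "constant") {
    rates <- rep(1 - (B / E0)^(1 / K), K)
    shape_used <- shape
  } else {
    if (is.null(gamma)) gamma <- if (shape == "decreasing") 0.5 else 2
    if (gamma <= 0 || gamma == 1)
      stop("'gamma' must be positive and != 1 for monotone shapes")
    if ((shape == "decreasing") != (gamma < 1))
      stop("'gamma' inconsistent with shape: decreasing needs gamma < 1")
    g <- gamma^(0:(K - 1L))
    cmax <- 1 / max(g)
    surv <- function(cc) prod(pmax(1 - cc * g, 0)) * E0 - B
    sol <- uniroot(surv, c(1e-12, cmax * (1 - 1e-12)), tol = 1e-14)
    rates <- sol$root * g
    if (any(rates >= 1)) stop("infeasible shape: required rate >= 1")
    shape_used <- shape
  }
  removals <- integer(K)
  e <- E0
  for (i in seq_len(K)) {
    rem <- if (i == K) e - B else min(round(rates[i] * e), e - B)
    removals[i] <- as.integer(rem)
    e <- e - rem
  }
  structure(list(shape = shape_used, rates = rates, K = K, E0 = E0, B = B,
                 gamma = if (shape %in% c("increasing", "decreasing")) gamma,
                 removals = removals,
                 edges = E0 - cumsum(removals)),
            class = "prune_schedule")
}

#' Edge counts after each pruning interval
#'
#' @param schedule A `prune_schedule`.
#' @return Integer vector of length `K`: edges remaining after each
#'   interval's removal; nonincreasing, last element equals the budget.
#' @export
edges_after <- function(schedule) schedule$edges

#' Energy consumption of a schedule
#'
#' Energy at interval `i` is the number of edges present in the network
#' while interval `i`'s pairs are processed (i.e., before that interval's
#' pruning step); total energy is the cumulative sum over all intervals,
#' an edge-interval count. Later-removing schedules cost more: for fixed
#' `(E0, B, K)`, decreasing < constant < increasing < ending.
#'
#' @param schedule A `prune_schedule`.
#' @param cumulative If `TRUE` return the per-interval cumulative trace
#'   instead of the total.
#' @return Total edge-intervals (or the length-`K` cumulative trace).
#' @export
schedule_energy <- function(schedule, cumulative = FALSE) {
  present <- c(schedule$E0, schedule$edges[-schedule$K])
  if (cumulative) cumsum(present) else sum(present)
}

#' @export
print.prune_schedule <- function(x, ...) {
  cat(sprintf("prune_schedule '%s': E0=%d -> B=%d over K=%d intervals\n",
              x$shape, x$E0, x$B, x$K))
  cat("  rates:", paste(sprintf("%.4f", x$rates), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.prune_schedule <- function(x, ...) {
  graphics::plot(seq_len(x$K), x$edges, type = "b", pch = 19,
                 xlab = "pruning interval", ylab = "edges remaining",
                 main = sprintf("%s-rate schedule", x$shape), ...)
  graphics::abline(h = x$B, lty = 2)
  invisible(x)
}
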