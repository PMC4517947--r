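# Source-target pair distributions. A pair_distribution assigns node labels
# to roles (source set S, target set T, selective or patch subsets) and
# samples (s, t) pairs; it encodes the activity structure the network must
# learn during construction. Layout is deterministic: sources occupy the
# lowest labels, targets the highest.

#' Construct a source-target pair distribution
#'
#' Supported kinds:
#' \describe{
#'   \item{`two_patch`}{Half the nodes are sources, half targets; pairs are
#'     uniform source x uniform target (odd `n`: `ceiling(n/2)` sources).}
#'   \item{`two_s_patch`}{With probability `x` a uniform two-patch pair;
#'     otherwise a pair from small "selective" subsets (a fraction
#'     `selective_frac` of each side, default 10\%), modeling highly active
#'     cortical subnetworks. Defaults `x = 0.5`.}
#'   \item{`two_patch_unbalanced`}{Three times as many targets as sources.}
#'   \item{`four_patch`}{Two disjoint (source, target) patches; a patch is
#'     chosen uniformly, then a uniform pair within it.}
#'   \item{`four_patch_hw`}{As `four_patch`, but after a shutoff point
#'     (fraction `shutoff_fraction` of the training stream, default 0.5)
#'     the second source set is never drawn again and its targets are
#'     recruited by the first source set (monocular-deprivation analogue).}
#'   \item{`empirical`}{Categorical over explicit pairs proportional to
#'     counts; sources and targets may overlap.}
#' }
#'
#' @param kind Distribution kind (see Details).
#' @param n Node count.
#' @param x Mixture probability of a non-selective pair (`two_s_patch`).
#' @param selective_frac Fraction of each role set that is selective.
#' @param shutoff_fraction Fraction of the training stream after which the
#'   second source patch is disabled (`four_patch_hw`).
#' @param pairs,counts For `empirical`: 2-column 0-based pair matrix and
#'   positive counts.
#' @return A `pair_distribution` object.
#' @examples
#' d <- make_distribution("two_patch", n = 10)
#' length(d$sources)
#' @export
make_distribution <- function(kind = c("two_patch", "two_s_patch",
                                       "two_patch_unbalanced", "four_patch",
                                       "four_patch_hw", "empirical"),
                              n, x = 0.5, selective_frac = 0.1,
                              shutoff_fraction = 0.5,
                              pairs = NULL, counts = NULL) {
  kind <- match.arg(kind)
  d <- list(kind = kind, n = as.integer(n))
  if (kind %in% c("two_patch", "two_s_patch")) {
    if (n < 2) stop("two-patch partition needs n >= 2")
    ns <- ceiling(n / 2)
    d$sources <- 0:(ns - 1L)
    d$targets <- ns:(n - 1L)
    if (kind == "two_s_patch") {
      if (x < 0 || x > 1) stop("'x' must be a probability")
      ks <- max(1L, round(selective_frac * length(d$sources)))
      kt <- max(1L, round(selective_frac * length(d$targets)))
      d$x <- x
      d$sel_sources <- d$sources[seq_len(ks)]
      d$sel_targets <- d$targets[seq_len(kt)]
    }
  } else if (kind == "two_patch_unbalanced") {
    ns <- round(n / 4)
    if (ns < 1 || n - ns < 3) stop("unbalanced partition infeasible for n")
    d$sources <- 0:(ns - 1L)
    d$targets <- ns:(n - 1L)
  } else if (kind %in% c("four_patch", "four_patch_hw")) {
    if (n < 4) stop("four-patch partition needs n >= 4")
    q1 <- floor(n / 4)
    d$sources1 <- 0:(q1 - 1L)
    d$sources2 <- q1:(2L * q1 - 1L)
    half <- 2L * q1
    nt <- n - half
    t1 <- ceiling(nt / 2)
    d$targets1 <- half:(half + t1 - 1L)
    d$targets2 <- (half + t1):(n - 1L)
    d$sources <- c(d$sources1, d$sources2)
    d$targets <- c(d$targets1, d$targets2)
    if (kind == "four_patch_hw") {
      if (shutoff_fraction < 0 || shutoff_fraction > 1)
        stop("'shutoff_fraction' must be in [0,1]")
      d$shutoff_fraction <- shutoff_fraction
    }
  } else { # empirical
    if (is.null(pairs) || is.null(counts))
      stop("empirical distribution needs 'pairs' and 'counts'")
    pairs <- matrix(as.integer(pairs), ncol = 2)
    if (length(counts) != nrow(pairs))
      stop("'counts' length must match pair rows")
    if (any(counts <= 0)) stop("counts must be positive")
    if (any(pairs[, 1] == pairs[, 2])) stop("self-pairs are not allowed")
    if (any(pairs < 0) || any(pairs >= n)) stop("pair labels out of range")
    if (anyDuplicated(paste(pairs[, 1], pairs[, 2]))) stop("duplicate pairs")
    d$pairs <- pairs
    d$prob <- counts / sum(counts)
    d$sources <- sort(unique(pairs[, 1]))
    d$targets <- sort(unique(pairs[, 2]))
  }
  structure(d, class = "pair_distribution")
}

.sample_uniform_pairs <- function(src, tgt, p) {
  cbind(src[sample.int(length(src), p, replace = TRUE)],
        tgt[sample.int(length(tgt), p, replace = TRUE)])
}

#' Sample a stream of source-target pairs
#'
#' Pairs are i.i.d. draws from the distribution (so the same pair may recur),
#' except for `four_patch_hw` where the mixture changes at the shutoff point:
#' positions after `shutoff_fraction * p` never draw from the second source
#' set, whose targets are instead recruited by the first source set. Test
#' streams (`phase = "test"`) use the post-shutoff regime throughout.
#'
#' @param dist A `pair_distribution`.
#' @param p Number of pairs (>= 1).
#' @param phase `"train"` or `"test"`; only `four_patch_hw` distinguishes.
#' @return A `p` x 2 integer matrix of 0-based `(source, target)` rows.
#' @export
sample_pairs <- function(dist, p, phase = c("train", "test")) {
  phase <- match.arg(phase)
  if (p < 1) stop("'p' must be >= 1")
  p <- as.integer(p)
  k <- dist$kind
  if (k %in% c("two_patch", "two_patch_unbalanced"))
    return(.sample_uniform_pairs(dist$sources, dist$targets, p))
  if (k == "two_s_patch") {
    full <- runif(p) < dist$x
    out <- matrix(0L, p, 2)
    if (any(full))
      out[full, ] <- .sample_uniform_pairs(dist$sources, dist$targets,
                                           sum(full))
    if (any(!full))
      out[!full, ] <- .sample_uniform_pairs(dist$sel_sources,
                                            dist$sel_targets, sum(!full))
    return(out)
  }
  if (k == "four_patch")
    return(.sample_four_patch(dist, p, allow_second = TRUE))
  if (k == "four_patch_hw") {
    cut <- if (phase == "test") 0L else floor(dist$shutoff_fraction * p)
    pre <- if (cut > 0) .sample_four_patch(dist, cut, allow_second = TRUE)
    post <- if (p - cut > 0)
      .sample_uniform_pairs(dist$sources1, c(dist$targets1, dist$targets2),
                            p - cut)
    return(rbind(pre, post))
  }
  # empirical
  idx <- sample.int(nrow(dist$pairs), p, replace = TRUE, prob = dist$prob)
  dist$pairs[idx, , drop = FALSE]
}

.sample_four_patch <- function(dist, p, allow_second) {
  patch <- sample.int(2L, p, replace = TRUE)
  out <- matrix(0L, p, 2)
  i1 <- patch == 1L
  if (any(i1))
    out[i1, ] <- .sample_uniform_pairs(dist$sources1, dist$targets1, sum(i1))
  if (any(!i1))
    out[!i1, ] <- .sample_uniform_pairs(dist$sources2, dist$targets2,
                                        sum(!i1))
  out
}

#' Exact pair probability under a distribution
#'
#' Analytic probability of drawing the ordered pair `(s, t)` (post-shutoff
#' regime for `four_patch_hw`). Used mainly for goodness-of-fit checks.
#'
#' @inheritParams sample_pairs
#' @param s,t Node labels.
#' @param phase Regime for `four_patch_hw`.
#' @export
pair_probability <- function(dist, s, t, phase = c("train", "test")) {
  phase <- match.arg(phase)
  k <- dist$kind
  if (k %in% c("two_patch", "two_patch_unbalanced")) {
    return(ifelse(s %in% dist$sources & t %in% dist$targets,
                  1 / (length(dist$sources) * length(dist$targets)), 0))
  }
  if (k == "two_s_patch") {
    pfull <- ifelse(s %in% dist$sources & t %in% dist$targets,
                    dist$x / (length(dist$sources) * length(dist$targets)), 0)
    psel <- ifelse(s %in% dist$sel_sources & t %in% dist$sel_targets,
                   (1 - dist$x) /
                     (length(dist$sel_sources) * length(dist$sel_targets)), 0)
    return(pfull + psel)
  }
  if (k == "four_patch") {
    p1 <- ifelse(s %in% dist$sources1 & t %in% dist$targets1,
                 0.5 / (length(dist$sources1) * length(dist$targets1)), 0)
    p2 <- ifelse(s %in% dist$sources2 & t %in% dist$targets2,
                 0.5 / (length(dist$sources2) * length(dist$targets2)), 0)
    return(p1 + p2)
  }
  if (k == "four_patch_hw") {
    nt <- length(dist$targets1) + length(dist$targets2)
    return(ifelse(s %in% dist$sources1 & t %in% dist$targets,
                  1 / (length(dist$sources1) * nt), 0))
  }
  hit <- dist$pairs[, 1] == s & dist$pairs[, 2] == t
  if (any(hit)) dist$prob[hit] else 0
}

#' Read an origin-destination traffic matrix
#'
#' Parses a CSV with header `source,target,count` (string city names,
#' positive integer counts) into an empirical pair distribution; the
#' name-to-label mapping (alphabetical) is attached as `$labels`. Sources
#' and targets may overlap, as in airline origin-destination data.
#'
#' @param file Path, connection, or character vector of CSV lines.
#' @return A `pair_distribution` of kind `empirical` with a `labels`
#'   character vector mapping label `i` to `labels[i + 1]`.
#' @export
read_traffic_csv <- function(file) {
  if (is.character(file) &&
      (length(file) > 1L || (!file.exists(file) && grepl("\n|,", file))))
    file <- textConnection(paste(file, collapse = "\n"))
  df <- read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "count") %in% names(df)))
    stop("traffic CSV must have columns source,target,count")
  if (any(is.na(df$count)) || any(df$count <= 0) ||
      any(df$count != round(df$count)))
    stop(sprintf("row %d: counts must be positive integers",
                 which(is.na(df$count) | df$count <= 0 |
                         df$count != round(df$count))[1]))
  self <- which(df$source == df$target)
  if (length(self) > 0)
    stop(sprintf("row %d: self-pair '%s'", self[1], df$source[self[1]]))
  cities <- sort(unique(c(df$source, df$target)))
  s <- match(df$source, cities) - 1L
  t <- match(df$target, cities) - 1L
  d <- make_distribution("empirical", n = length(cities),
                         pairs = cbind(s, t), counts = df$count)
  d$labels <- cities
  d
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("pair_distribution '%s' on %d nodes: %d sources, %d targets\n",
              x$kind, x$n, length(x$sources), length(x$targets)))
  invisible(x)
}
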