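# Triad (3-node subgraph) census and motif over-representation Z-scores.
# Classes follow the standard MAN labeling of the 16 directed triad
# isomorphism classes; the feed-forward loop (a->b, a->c, b->c with no
# reciprocation) is class 030T.

.TRIAD_CLASSES <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                    "111U", "030T", "030C", "201", "120D", "120U", "120C",
                    "210", "300")

#' Triad census of a directed network
#'
#' Exact counts of all 16 directed 3-node isomorphism classes (including
#' the disconnected ones) over all `choose(n, 3)` node triples.
#'
#' @param net A `routing_network` with `n >= 3`.
#' @return A `motif_census`: named integer vector over the 16 classes with
#'   attribute `n_triples`.
#' @export
triad_census <- function(net) {
  if (net$n < 3) stop("triad census needs n >= 3")
  counts <- igraph::triad_census(as_igraph(net))
  structure(setNames(as.numeric(counts), .TRIAD_CLASSES),
            n_triples = choose(net$n, 3), class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("motif_census over", attr(x, "n_triples"), "triples:\n")
  print(unclass(x)[unclass(x) > 0])
  invisible(x)
}

# one degree-preserving randomization of a network (directed edge swaps
# keeping every in- and out-degree); falls back to G(n, m) when the graph
# is too sparse to swap
.null_sample <- function(g, method, n, m, swaps) {
  if (method == "swap")
    igraph::rewire(g, igraph::keeping_degseq(niter = swaps))
  else
    igraph::sample_gnm(n, m, directed = TRUE)
}

#' Motif Z-scores against a randomized ensemble
#'
#' Compares the observed triad census to an ensemble of randomized
#' networks. The default null model preserves every node's in- and
#' out-degree via directed edge swaps (100 x |E| attempted swaps per
#' sample); a uniform `G(n, m)` null is available. For each class,
#' `Z = (observed - mean) / sd` over the ensemble and a two-sided
#' empirical p-value are reported; classes whose ensemble variance is
#' zero are flagged rather than scored.
#'
#' @param net A `routing_network` with `n >= 3`.
#' @param ensemble_size Number of null networks (>= 100).
#' @param null `"swap"` (degree-preserving) or `"gnm"`.
#' @param seed Optional integer seed.
#' @return A `motif_report` data frame: observed count, ensemble mean and
#'   sd, `z`, and empirical `p` per class, with the null-model metadata
#'   as attributes.
#' @export
motif_zscores <- function(net, ensemble_size = 1000L,
                          null = c("swap", "gnm"), seed = NULL) {
  null <- match.arg(null)
  if (ensemble_size < 100) stop("'ensemble_size' must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(net)
  m <- igraph::ecount(g)
  if (m < 2 && null == "swap") {
    warning("network too sparse to swap; falling back to G(n,m) null")
    null <- "gnm"
  }
  obs <- as.numeric(igraph::triad_census(g))
  swaps <- 100L * m
  ens <- matrix(0, ensemble_size, 16L)
  for (b in seq_len(ensemble_size)) {
    ens[b, ] <- as.numeric(igraph::triad_census(
      .null_sample(g, null, net$n, m, swaps)))
  }
  mu <- colMeans(ens)
  sdv <- apply(ens, 2, sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  # two-sided empirical p with the +1 correction for finite ensembles
  p_emp <- vapply(seq_len(16L), function(k) {
    hi <- sum(ens[, k] >= obs[k]); lo <- sum(ens[, k] <= obs[k])
    min(1, 2 * (min(hi, lo) + 1) / (ensemble_size + 1))
  }, numeric(1))
  rep <- data.frame(class = .TRIAD_CLASSES, observed = obs, mean = mu,
                    sd = sdv, z = z, p = p_emp)
  structure(rep, ensemble_size = ensemble_size, null = null,
            class = c("motif_report", "data.frame"))
}

#' Feed-forward-loop Z-score
#'
#' Convenience accessor for the `030T` (feed-forward) row of a
#' [motif_zscores()] report.
#'
#' @param report A `motif_report`.
#' @export
feed_forward_z <- function(report) report$z[report$class == "030T"]

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("motif_report: %d-sample %s null\n",
              attr(x, "ensemble_size"), attr(x, "null")))
  df <- as.data.frame(x)
  df$z <- round(df$z, 2)
  df$mean <- round(df$mean, 1)
  df$sd <- round(df$sd, 2)
  print(df[order(-abs(ifelse(is.na(df$z), 0, df$z))), ][1:8, ],
        row.names = FALSE)
  cat("  (top 8 by |Z|; feed-forward loop is class 030T)\n")
  invisible(x)
}
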