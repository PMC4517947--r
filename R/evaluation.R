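# Test-phase metrics on a frozen network: efficiency (mean shortest-path
# hops, penalized for disconnected pairs), robustness (mean count of
# near-shortest alternative routes under iterative node removal),
# unroutable-pair count, and the energy carried in the build trace.

# distances for a set of (1-based) pairs using igraph on the sparse graph
.pair_distances <- function(net, pairs1) {
  g <- as_igraph(net)
  us <- sort(unique(pairs1[, 1]))
  dm <- igraph::distances(g, v = us, mode = "out")
  dm[cbind(match(pairs1[, 1], us), pairs1[, 2])]
}

#' Network efficiency on a test stream
#'
#' Efficiency is the average shortest-path routing distance over the test
#' pairs; a disconnected pair contributes a fixed large `penalty` distance.
#' Lower is better; a clique scores exactly 1.
#'
#' @param net A `routing_network`.
#' @param test Test pair stream: 2-column 0-based matrix.
#' @param penalty Distance charged for a disconnected pair; must exceed
#'   any possible path length. Default `2 * n`.
#' @return Mean hops (a single number).
#' @export
efficiency <- function(net, test, penalty = 2 * net$n) {
  if (NROW(test) == 0) stop("empty test stream")
  if (penalty <= net$n) stop("'penalty' must exceed n")
  d <- .pair_distances(net, matrix(as.integer(test), ncol = 2) + 1L)
  d[is.infinite(d)] <- penalty
  mean(d)
}

#' Count of unroutable test pairs
#'
#' @inheritParams efficiency
#' @return Number of test pairs with no directed source-to-target path.
#' @export
unroutable <- function(net, test) {
  d <- .pair_distances(net, matrix(as.integer(test), ncol = 2) + 1L)
  sum(is.infinite(d))
}

# one pair's robustness: count near-shortest routes by iteratively removing
# the interior nodes of each discovered shortest path (or the edge itself
# for a direct hop). `slack` is the allowed extra hops over the primary
# shortest path (1 in the neural simulations, 0 for same-length routes).
.robustness_pair <- function(adj, si, ti, slack) {
  d0 <- .bfs_dist(adj, si, until = ti)[ti]
  if (is.na(d0)) return(0L)
  count <- 0L
  repeat {
    d <- .bfs_dist(adj, si, until = ti)
    if (is.na(d[ti]) || d[ti] > d0 + slack) break
    # deterministic path extraction: smallest-label predecessor walk-back
    v <- ti
    path <- ti
    for (k in d[ti]:1) {
      prev <- which(!is.na(d) & d == k - 1L)
      preds <- prev[adj[prev, v]]
      v <- preds[1L]
      path <- c(v, path)
    }
    count <- count + 1L
    if (length(path) == 2L) {
      adj[path[1L], path[2L]] <- FALSE  # direct hop: remove the edge
    } else {
      interior <- path[-c(1L, length(path))]
      adj[interior, ] <- FALSE
      adj[, interior] <- FALSE
    }
  }
  count
}

#' Network robustness on a test stream
#'
#' For each test pair the number of alternative routes at most `slack`
#' hops longer than the shortest path is counted: the shortest path is
#' found and counted, its interior nodes are removed (for a direct 1-hop
#' path, the edge itself), the next shortest path is found, and so on
#' until no route within `d0 + slack` hops remains. The primary path is
#' included in the count, so every routable pair scores at least 1;
#' disconnected pairs score 0. Higher is better.
#'
#' @inheritParams efficiency
#' @param slack Extra hops allowed over the primary shortest path
#'   (default 1).
#' @return Mean alternative-route count over the test pairs.
#' @export
robustness <- function(net, test, slack = 1L) {
  test <- matrix(as.integer(test), ncol = 2) + 1L
  counts <- vapply(seq_len(nrow(test)), function(i)
    .robustness_pair(net$adj, test[i, 1], test[i, 2], slack), integer(1))
  mean(counts)
}

#' Evaluate a constructed network
#'
#' Bundles efficiency, robustness, unroutable count and the build's energy
#' into an `evaluation_report`. The network is frozen during testing.
#'
#' @param trace A `build_trace` (or a bare `routing_network`, in which
#'   case energy is `NA`).
#' @param test Test pair stream: 2-column 0-based matrix, drawn from the
#'   same distribution as training.
#' @param penalty Disconnection penalty; default `2 * n`.
#' @param slack Robustness hop slack (default 1).
#' @return An `evaluation_report` list.
#' @export
evaluate <- function(trace, test, penalty = NULL, slack = 1L) {
  net <- if (inherits(trace, "routing_network")) trace else trace$network
  if (is.null(penalty)) penalty <- 2 * net$n
  structure(list(
    efficiency = efficiency(net, test, penalty),
    robustness = robustness(net, test, slack),
    unroutable = unroutable(net, test),
    energy = if (inherits(trace, "build_trace")) trace_energy(trace)
             else NA_real_,
    penalty = penalty, slack = slack, test_pairs = NROW(test),
    algorithm = if (inherits(trace, "build_trace")) trace$algorithm
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report%s (%d test pairs):\n",
              if (!is.null(x$algorithm)) sprintf(" [%s]", x$algorithm)
              else "", x$test_pairs))
  cat(sprintf("  efficiency: %.3f hops (penalty %g for disconnection)\n",
              x$efficiency, x$penalty))
  cat(sprintf("  robustness: %.3f routes within +%d hop(s)\n",
              x$robustness, x$slack))
  cat(sprintf("  unroutable: %d\n", x$unroutable))
  if (!is.na(x$energy)) cat(sprintf("  energy:     %g edge-intervals\n",
                                    x$energy))
  invisible(x)
}
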