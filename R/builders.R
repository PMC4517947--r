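# Network-construction algorithms. All four return a build_trace: the final
# network plus per-interval accounting (edges present while each block of
# training pairs was processed, removals/additions, unroutable pairs), the
# configuration echo, and the seed, so a run is reproducible bit-for-bit.

.split_blocks <- function(p, K) {
  base <- p %/% K
  sizes <- rep(base, K)
  sizes[K] <- sizes[K] + p - base * K
  sizes
}

.new_trace <- function(algorithm, net, dist, schedule = NULL, p = NULL,
                       edges_during = NULL, removed = NULL, added = NULL,
                       unroutable_train = 0L, seed = NULL, extra = list()) {
  structure(c(list(algorithm = algorithm, network = net, n = net$n,
                   B = net$budget, dist_kind = if (!is.null(dist)) dist$kind,
                   schedule = schedule, p_train = p,
                   edges_during = edges_during,
                   removed = removed, added = added,
                   unroutable_train = unroutable_train, seed = seed),
              extra),
            class = "build_trace")
}

# remove `rem` lowest-usage edges from adj, random tie-break; returns list
.prune_lowest <- function(adj, usage, rem) {
  if (rem <= 0) return(list(adj = adj, usage = usage))
  idx <- which(adj)
  u <- usage[idx]
  ord <- order(u, runif(length(u)))
  drop <- idx[ord[seq_len(rem)]]
  adj[drop] <- FALSE
  usage[drop] <- 0
  list(adj = adj, usage = usage)
}

# Route one pair on adj with uniform tie-breaking; returns 1-based node path
# or NULL. Fast path: direct edge.
.route_pair <- function(adj, si, ti) {
  if (adj[si, ti]) return(c(si, ti))
  d <- .bfs_dist(adj, si, until = ti)
  dt <- d[ti]
  if (is.na(dt)) return(NULL)
  layers <- lapply(0:dt, function(k) which(!is.na(d) & d == k))
  sigma <- numeric(nrow(adj))
  sigma[si] <- 1
  for (k in seq_len(dt)) {
    prev <- layers[[k]]; cur <- layers[[k + 1L]]
    sigma[cur] <- as.vector(crossprod(adj[prev, cur, drop = FALSE],
                                      sigma[prev]))
  }
  path <- integer(dt + 1L)
  path[dt + 1L] <- ti
  v <- ti
  for (k in dt:1) {
    prev <- layers[[k]]
    preds <- prev[adj[prev, v]]
    v <- if (length(preds) == 1L) preds
         else preds[sample.int(length(preds), 1L, prob = sigma[preds])]
    path[k] <- v
  }
  path
}

#' Build a network by usage-based pruning (shortest-path model)
#'
#' Starts from the clique on `n` nodes and processes `p` training pairs in
#' `K` blocks. Each pair is routed along a shortest path (uniform among
#' ties) and every edge on the chosen path gains one usage count ("use it
#' or lose it"). After each block, the schedule's removal count of
#' lowest-usage edges is pruned (ties broken at random), ending at exactly
#' `B` edges. Usage accumulates across intervals and an edge's count is
#' discarded when the edge is pruned. Training pairs whose target has
#' become unreachable contribute no usage and are counted in the trace.
#'
#' @param dist A `pair_distribution` on `n` nodes.
#' @param n Node count.
#' @param B Edge budget, `B < n(n-1)`.
#' @param schedule A `prune_schedule` with `E0 = n(n-1)` and budget `B`,
#'   or a shape name, in which case the schedule is built with defaults.
#' @param p Number of training pairs (default `10 * n`).
#' @param seed Optional integer seed (`set.seed` is called if given).
#' @return A `build_trace`; `$network` holds the final `routing_network`.
#' @export
build_by_pruning <- function(dist, n, B, schedule = "constant", p = 10 * n,
                             seed = NULL) {
  .build_prune(dist, n, B, schedule, p, seed, model = "route")
}

#' Build a network by usage-based pruning (flow/BFS model)
#'
#' A biologically-motivated variant of [build_by_pruning()]: instead of
#' routing along one shortest path, each training pair triggers a flow
#' episode in which every edge independently fails with probability
#' `fail_prob` (synapse failure; default 0.65). Every surviving edge that
#' lies on a surviving source-to-target route — computed as the surviving
#' edges forward-reachable from the source and co-reachable to the target,
#' excluding edges entering the source or leaving the target — gains one
#' usage count for the episode. Pruning then proceeds exactly as in the
#' shortest-path model.
#'
#' @inheritParams build_by_pruning
#' @param fail_prob Per-edge signal-loss probability in `[0, 1)`.
#' @export
build_by_flow <- function(dist, n, B, schedule = "constant", p = 10 * n,
                          fail_prob = 0.65, seed = NULL) {
  if (fail_prob < 0 || fail_prob >= 1) stop("'fail_prob' must be in [0,1)")
  .build_prune(dist, n, B, schedule, p, seed, model = "flow",
               fail_prob = fail_prob)
}

.build_prune <- function(dist, n, B, schedule, p, seed, model,
                         fail_prob = 0.65) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  E0 <- n * (n - 1L)
  if (B >= E0) stop("budget must be below the clique size n(n-1)")
  if (p < 1) stop("empty training stream")
  if (is.character(schedule))
    schedule <- make_schedule(schedule, E0 = E0, B = B)
  if (schedule$E0 != E0 || schedule$B != B)
    stop("schedule was built for a different (E0, B)")
  K <- schedule$K
  adj <- make_clique(n)$adj
  usage <- matrix(0, n, n)
  pairs <- sample_pairs(dist, p, phase = "train") + 1L
  sizes <- .split_blocks(p, K)
  edges_during <- integer(K)
  unroutable <- 0L
  pos <- 0L
  tadj <- NULL
  for (i in seq_len(K)) {
    edges_during[i] <- sum(adj)
    if (sizes[i] > 0) {
      for (j in seq_len(sizes[i])) {
        si <- pairs[pos + j, 1]; ti <- pairs[pos + j, 2]
        if (model == "route") {
          path <- .route_pair(adj, si, ti)
          if (is.null(path)) { unroutable <- unroutable + 1L; next }
          from <- path[-length(path)]; to <- path[-1]
          idx <- cbind(from, to)
          usage[idx] <- usage[idx] + 1
        } else {
          eidx <- which(adj)
          surv <- eidx[runif(length(eidx)) >= fail_prob]
          if (length(surv) == 0L) { unroutable <- unroutable + 1L; next }
          asurv <- matrix(FALSE, n, n)
          asurv[surv] <- TRUE
          fwd <- !is.na(.bfs_dist(asurv, si))
          if (!fwd[ti]) { unroutable <- unroutable + 1L; next }
          bwd <- !is.na(.bfs_dist(t(asurv), ti))
          mask <- asurv & outer(fwd, bwd)
          mask[, si] <- FALSE  # edges entering the source never lie on a path
          mask[ti, ] <- FALSE  # nor edges leaving the target
          usage[mask] <- usage[mask] + 1
        }
      }
      pos <- pos + sizes[i]
    }
    res <- .prune_lowest(adj, usage, schedule$removals[i])
    adj <- res$adj; usage <- res$usage
  }
  net <- structure(list(n = n, adj = adj, budget = as.integer(B)),
                   class = "routing_network")
  .new_trace(if (model == "route") "prune" else "flow", net, dist,
             schedule = schedule, p = p, edges_during = edges_during,
             removed = schedule$removals, unroutable_train = unroutable,
             seed = seed,
             extra = c(list(final_usage = t(usage)[t(adj)]),  # network_edges order
                       if (model == "flow") list(fail_prob = fail_prob)))
}

# uniform random labeled tree on n nodes via Pruefer decoding (1-based)
.random_spanning_tree <- function(n) {
  if (n == 2L) return(cbind(1L, 2L))
  pruefer <- sample.int(n, n - 2L, replace = TRUE)
  degree <- rep(1L, n)
  for (v in pruefer) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  ptr <- 1L
  leaves <- which(degree == 1L)
  leaf_heap <- sort(leaves)
  for (i in seq_len(n - 2L)) {
    leaf <- leaf_heap[1L]
    leaf_heap <- leaf_heap[-1L]
    v <- pruefer[i]
    edges[ptr, ] <- c(leaf, v); ptr <- ptr + 1L
    degree[v] <- degree[v] - 1L
    if (degree[v] == 1L) leaf_heap <- sort(c(leaf_heap, v))
  }
  edges[ptr, ] <- leaf_heap
  edges
}

#' Build a network by growing from a spanning tree
#'
#' The engineering baseline: first a uniformly random undirected spanning
#' tree is installed as two directed arcs per tree edge (`2(n-1)` arcs,
#' guaranteeing every pair is routable), then training pairs are processed
#' in `K` blocks. Each routed pair deposits shortcut demand on every
#' ordered node pair at distance 2 along its route; after each block the
#' highest-demand absent arcs (ties random) are added in equal per-block
#' installments until the budget `B` is reached. If fewer demanded
#' shortcuts exist than the installment, the shortfall carries over; the
#' final network has at most `B` edges (exactly `B` when enough candidate
#' shortcuts accumulate).
#'
#' @inheritParams build_by_pruning
#' @param K Number of blocks (default 10).
#' @export
build_by_growing <- function(dist, n, B, p = 10 * n, K = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (B < 2 * (n - 1L)) stop("infeasible budget: growing needs B >= 2(n-1)")
  tree <- .random_spanning_tree(n)
  adj <- matrix(FALSE, n, n)
  adj[tree] <- TRUE
  adj[tree[, 2:1, drop = FALSE]] <- TRUE
  demand <- matrix(0, n, n)
  pairs <- sample_pairs(dist, p, phase = "train") + 1L
  sizes <- .split_blocks(p, K)
  total_add <- B - 2L * (n - 1L)
  quota <- diff(round(total_add * (0:K) / K))
  edges_during <- integer(K)
  added <- integer(K)
  unroutable <- 0L
  pos <- 0L
  deficit <- 0L
  for (i in seq_len(K)) {
    edges_during[i] <- sum(adj)
    for (j in seq_len(sizes[i])) {
      path <- .route_pair(adj, pairs[pos + j, 1], pairs[pos + j, 2])
      if (is.null(path)) { unroutable <- unroutable + 1L; next }
      L <- length(path)
      if (L >= 3L) {
        idx <- cbind(path[1:(L - 2L)], path[3:L])
        demand[idx] <- demand[idx] + 1
      }
    }
    pos <- pos + sizes[i]
    want <- quota[i] + deficit
    if (want > 0) {
      cand <- which(demand > 0 & !adj)
      cand <- cand[((cand - 1L) %/% n + 1L) != ((cand - 1L) %% n + 1L)]
      take <- min(want, length(cand))
      if (take > 0) {
        ord <- order(-demand[cand], runif(length(cand)))
        adj[cand[ord[seq_len(take)]]] <- TRUE
      }
      added[i] <- take
      deficit <- want - take
    }
  }
  net <- structure(list(n = n, adj = adj, budget = as.integer(B)),
                   class = "routing_network")
  .new_trace("grow", net, dist, p = p, edges_during = edges_during,
             added = added, unroutable_train = unroutable, seed = seed)
}

#' No-learning baseline: B uniformly random directed edges
#'
#' Ignores the training data entirely: selects `B` distinct directed edges
#' uniformly without replacement.
#'
#' @inheritParams build_by_pruning
#' @export
build_no_learning <- function(n, B, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (B > n * (n - 1L)) stop("budget exceeds n(n-1)")
  offdiag <- which(row(matrix(0, n, n)) != col(matrix(0, n, n)))
  pick <- sample(offdiag, B)
  adj <- matrix(FALSE, n, n)
  adj[pick] <- TRUE
  net <- structure(list(n = n, adj = adj, budget = as.integer(B)),
                   class = "routing_network")
  .new_trace("random", net, NULL, edges_during = B, seed = seed)
}

#' @export
print.build_trace <- function(x, ...) {
  cat(sprintf("build_trace [%s]: n=%d, B=%d, final edges=%d\n",
              x$algorithm, x$n, x$B, edge_count(x$network)))
  if (!is.null(x$p_train))
    cat(sprintf("  trained on %d pairs from '%s' (%d unroutable)\n",
                x$p_train, x$dist_kind, x$unroutable_train))
  if (!is.null(x$edges_during))
    cat(sprintf("  energy: %d edge-intervals\n", sum(x$edges_during)))
  invisible(x)
}

#' Energy consumed by a construction run
#'
#' The cumulative number of edges present in the network during each
#' interval of the run (the trace's per-interval edge counts summed).
#'
#' @param trace A `build_trace`.
#' @export
trace_energy <- function(trace) sum(trace$edges_during)
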