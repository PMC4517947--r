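#' @importFrom stats runif rnorm rexp rbinom approxfun splinefun smooth.spline
#'   predict t.test uniroot dpois sd aggregate setNames
#' @importFrom utils head read.csv
NULL

# Directed-graph substrate. Networks are dense-integer-labeled (0..n-1) and
# stored as an n x n logical adjacency matrix; row = from, col = to. Node
# labels are stable: removal never relabels.

#' Create a routing network
#'
#' A `routing_network` is an unweighted directed graph on `n` nodes labeled
#' `0..n-1`, optionally carrying the edge budget `B` it was (or will be)
#' constructed under. Self-loops and duplicate edges are rejected.
#'
#' @param n Node count (>= 1; most constructions require >= 2).
#' @param edges Two-column integer matrix of directed edges `(from, to)`,
#'   0-based labels, or `NULL` for an edgeless network.
#' @param budget Optional construction budget `B` stored alongside.
#' @return An object of class `routing_network`.
#' @examples
#' net <- routing_network(3, rbind(c(0, 1), c(1, 2)))
#' edge_count(net)
#' @export
routing_network <- function(n, edges = NULL, budget = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a single positive integer")
  n <- as.integer(n)
  adj <- matrix(FALSE, n, n)
  net <- structure(list(n = n, adj = adj, budget = budget),
                   class = "routing_network")
  if (!is.null(edges) && NROW(edges) > 0) net <- add_edges(net, edges)
  net
}

#' Fully connected directed network (clique)
#'
#' Pruning-based construction starts from a clique: every ordered pair of
#' distinct nodes is connected, giving `n(n-1)` directed edges.
#'
#' @inheritParams routing_network
#' @return A `routing_network` with all `n(n-1)` edges.
#' @examples
#' edge_count(make_clique(3)) # 6
#' @export
make_clique <- function(n, budget = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("clique requires integer n >= 2")
  n <- as.integer(n)
  adj <- matrix(TRUE, n, n)
  diag(adj) <- FALSE
  structure(list(n = n, adj = adj, budget = budget),
            class = "routing_network")
}

.check_edges <- function(net, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (any(is.na(edges))) stop("non-integer edge labels")
  if (any(edges < 0L) || any(edges >= net$n))
    stop("edge labels out of range 0..n-1")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  edges
}

#' @rdname routing_network
#' @param net A `routing_network`.
#' @export
add_edges <- function(net, edges) {
  edges <- .check_edges(net, edges)
  idx <- cbind(edges[, 1] + 1L, edges[, 2] + 1L)
  if (any(net$adj[idx]) || anyDuplicated(idx))
    stop("duplicate edges are not allowed")
  net$adj[idx] <- TRUE
  net
}

#' @rdname routing_network
#' @export
remove_edges <- function(net, edges) {
  edges <- .check_edges(net, edges)
  idx <- cbind(edges[, 1] + 1L, edges[, 2] + 1L)
  if (!all(net$adj[idx])) stop("cannot remove an absent edge")
  net$adj[idx] <- FALSE
  net
}

#' @rdname routing_network
#' @export
has_edge <- function(net, edges) {
  edges <- .check_edges(net, edges)
  net$adj[cbind(edges[, 1] + 1L, edges[, 2] + 1L)]
}

#' @rdname routing_network
#' @export
edge_count <- function(net) sum(net$adj)

#' Edge list of a network
#'
#' @param net A `routing_network`.
#' @return Two-column integer matrix of 0-based `(from, to)` pairs, ordered
#'   by source then target label.
#' @export
network_edges <- function(net) {
  w <- which(t(net$adj))  # transpose so ordering is by row (source) first
  n <- net$n
  cbind(from = (w - 1L) %/% n, to = (w - 1L) %% n)
}

#' Convert to an igraph object
#'
#' @param net A `routing_network`.
#' @return A directed `igraph` graph with vertices `1..n` standing for
#'   labels `0..n-1`.
#' @export
as_igraph <- function(net) {
  el <- network_edges(net)
  igraph::make_graph(as.vector(t(el + 1L)), n = net$n, directed = TRUE)
}

# BFS distances from 1-based source index over a logical adjacency matrix.
# Returns integer vector, NA for unreachable. Stops early once `until`
# (1-based) is reached, if given.
.bfs_dist <- function(adj, s, until = NA_integer_) {
  n <- nrow(adj)
  d <- rep(NA_integer_, n)
  d[s] <- 0L
  frontier <- s
  k <- 0L
  while (length(frontier) > 0L) {
    if (!is.na(until) && !is.na(d[until])) break
    k <- k + 1L
    reach <- if (length(frontier) == 1L) adj[frontier, ]
             else colSums(adj[frontier, , drop = FALSE]) > 0
    nxt <- which(reach & is.na(d))
    d[nxt] <- k
    frontier <- nxt
  }
  d
}

#' Shortest-path routing with uniform tie-breaking
#'
#' Routes a message from source `s` to target `t` along a minimum-hop
#' directed path. When several minimum-hop paths exist, one is drawn
#' uniformly at random among them (via path-count-weighted predecessor
#' sampling on the BFS DAG), so no edge is systematically favored.
#'
#' @param net A `routing_network`.
#' @param s,t Source and target labels (0-based); `s != t`.
#' @return Integer vector of node labels from `s` to `t`, or `NULL` if `t`
#'   is unreachable from `s`.
#' @examples
#' shortest_path(make_clique(4), 0, 3) # c(0, 3)
#' @export
shortest_path <- function(net, s, t) {
  if (s == t) stop("source and target must differ")
  if (s < 0 || t < 0 || s >= net$n || t >= net$n)
    stop("node labels out of range 0..n-1")
  si <- as.integer(s) + 1L; ti <- as.integer(t) + 1L
  adj <- net$adj
  if (adj[si, ti]) return(c(s, t))  # direct edge is the unique 1-hop path
  d <- .bfs_dist(adj, si, until = ti)
  dt <- d[ti]
  if (is.na(dt)) return(NULL)
  # layer-wise shortest-path counts sigma from s
  layers <- vector("list", dt + 1L)
  for (k in 0:dt) layers[[k + 1L]] <- which(!is.na(d) & d == k)
  sigma <- numeric(nrow(adj))
  sigma[si] <- 1
  for (k in seq_len(dt)) {
    prev <- layers[[k]]; cur <- layers[[k + 1L]]
    sub <- adj[prev, cur, drop = FALSE]
    sigma[cur] <- as.vector(crossprod(sub, sigma[prev]))
  }
  # sample backwards, predecessor weighted by its path count
  path <- integer(dt + 1L)
  path[dt + 1L] <- ti
  v <- ti
  for (k in dt:1) {
    prev <- layers[[k]]
    preds <- prev[adj[prev, v]]
    w <- sigma[preds]
    v <- if (length(preds) == 1L) preds
         else preds[sample.int(length(preds), 1L, prob = w)]
    path[k] <- v
  }
  path - 1L
}

#' Read / write edge-list files
#'
#' The on-disk format is one `from<TAB>to` pair per line, 0-based integer
#' labels, with optional `#` comment lines. A header comment records `n`
#' so that isolated high-labeled nodes survive the round trip.
#'
#' @param file Path or connection; for `read_edgelist`, a character vector
#'   of lines is also accepted.
#' @param n Node count; if `NULL`, taken from the `# n=<int>` header or
#'   `max(label) + 1`.
#' @return `read_edgelist` returns a `routing_network`; `write_edgelist`
#'   invisibly returns the lines written.
#' @export
read_edgelist <- function(file, n = NULL) {
  lines <- if (is.character(file) &&
               (length(file) > 1L ||
                  (!file.exists(file) && grepl("[\n\t#]", file))))
    unlist(strsplit(file, "\n", fixed = TRUE))
  else readLines(file)
  header_n <- NA_integer_
  hm <- grep("^#\\s*n=\\d+\\s*$", lines)
  if (length(hm) > 0)
    header_n <- as.integer(sub("^#\\s*n=(\\d+)\\s*$", "\\1", lines[hm[1]]))
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L && is.na(header_n) && is.null(n))
    stop("empty edge list with no node-count header")
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0)
    stop(sprintf("line %d: expected 'u<TAB>v'", lineno[bad[1]]))
  u <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  v <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(u) | is.na(v))
  if (length(bad) > 0)
    stop(sprintf("line %d: non-integer node label", lineno[bad[1]]))
  bad <- which(u == v)
  if (length(bad) > 0)
    stop(sprintf("line %d: self-loop", lineno[bad[1]]))
  dup <- which(duplicated(paste(u, v)))
  if (length(dup) > 0)
    stop(sprintf("line %d: duplicate edge", lineno[dup[1]]))
  if (is.null(n)) n <- if (!is.na(header_n)) header_n
                       else max(c(u, v)) + 1L
  routing_network(n, cbind(u, v))
}

#' @rdname read_edgelist
#' @param net A `routing_network`.
#' @export
write_edgelist <- function(net, file = NULL) {
  el <- network_edges(net)
  lines <- c(sprintf("# n=%d", net$n), sprintf("%d\t%d", el[, 1], el[, 2]))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' @export
print.routing_network <- function(x, ...) {
  cat(sprintf("routing_network: %d nodes, %d directed edges%s\n",
              x$n, edge_count(x),
              if (!is.null(x$budget)) sprintf(" (budget B=%d)", x$budget)
              else ""))
  invisible(x)
}

#' @export
summary.routing_network <- function(object, ...) {
  m <- edge_count(object)
  cat(sprintf("routing_network on %d nodes\n", object$n))
  cat(sprintf("  edges:   %d of %d possible (density %.4f)\n",
              m, object$n * (object$n - 1L),
              m / (object$n * (object$n - 1L))))
  cat(sprintf("  mean out-degree: %.2f\n", m / object$n))
  invisible(object)
}
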