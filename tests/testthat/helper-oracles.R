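# Brute-force oracles used to cross-check the package's graph machinery.
# They rely on exhaustive simple-path enumeration and hand-encoded triad
# representatives only -- independent of the BFS router and of igraph.

# all simple paths s -> t (1-based node indices) over a logical adjacency
bf_paths <- function(adj, s, t, maxlen = nrow(adj) - 1L) {
  out <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible(NULL))
    }
    if (length(path) > maxlen) return(invisible(NULL))
    for (w in which(adj[v, ])) if (!(w %in% path)) recurse(c(path, w))
  }
  recurse(s)
  out
}

bf_dist <- function(adj, s, t) {
  ps <- bf_paths(adj, s, t)
  if (!length(ps)) NA_integer_ else min(lengths(ps)) - 1L
}

# robustness by enumeration: repeatedly pick the shortest surviving path
# (ties: smallest reversed node sequence, mirroring walk-back from the
# target), count it while within d0 + slack, remove its interior nodes
# (or the edge itself for a direct hop)
bf_robustness <- function(adj, s, t, slack = 1L) {
  d0 <- bf_dist(adj, s, t)
  if (is.na(d0)) return(0L)
  count <- 0L
  repeat {
    ps <- bf_paths(adj, s, t)
    if (!length(ps)) break
    len <- lengths(ps) - 1L
    if (min(len) > d0 + slack) break
    sh <- ps[len == min(len)]
    key <- vapply(sh, function(p)
      paste(sprintf("%03d", rev(p)), collapse = ""), "")
    p <- sh[[which.min(rank(key, ties.method = "first"))]]
    count <- count + 1L
    if (length(p) == 2L) {
      adj[p[1], p[2]] <- FALSE
    } else {
      interior <- p[-c(1L, length(p))]
      adj[interior, ] <- FALSE
      adj[, interior] <- FALSE
    }
  }
  count
}

# ---- triad classification oracle ------------------------------------------
# representatives of the 16 directed triad classes, hand-encoded from their
# standard MAN diagrams (nodes a=1, b=2, c=3)
.triad_reps <- list(
  "003"  = cbind(integer(0), integer(0)),
  "012"  = rbind(c(1, 2)),
  "102"  = rbind(c(1, 2), c(2, 1)),
  "021D" = rbind(c(2, 1), c(2, 3)),
  "021U" = rbind(c(1, 2), c(3, 2)),
  "021C" = rbind(c(1, 2), c(2, 3)),
  "111D" = rbind(c(1, 2), c(2, 1), c(3, 2)),
  "111U" = rbind(c(1, 2), c(2, 1), c(2, 3)),
  "030T" = rbind(c(1, 2), c(3, 2), c(1, 3)),
  "030C" = rbind(c(2, 1), c(3, 2), c(1, 3)),
  "201"  = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2)),
  "120D" = rbind(c(2, 1), c(2, 3), c(1, 3), c(3, 1)),
  "120U" = rbind(c(1, 2), c(3, 2), c(1, 3), c(3, 1)),
  "120C" = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 1)),
  "210"  = rbind(c(1, 2), c(2, 3), c(3, 2), c(1, 3), c(3, 1)),
  "300"  = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1))
)

.triad_code <- function(m) {
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  off <- which(row(m) != col(m))
  min(vapply(perms, function(p) {
    mm <- m[p, p]
    sum(2^(seq_along(off) - 1L) * mm[off])
  }, numeric(1)))
}

.triad_code_map <- local({
  codes <- vapply(.triad_reps, function(el) {
    m <- matrix(FALSE, 3, 3)
    if (nrow(el) > 0) m[el] <- TRUE
    .triad_code(m)
  }, numeric(1))
  stats::setNames(names(codes), as.character(codes))
})

# exhaustive triad census over all node triples
bf_triad_census <- function(adj) {
  n <- nrow(adj)
  counts <- stats::setNames(numeric(16), names(.triad_reps))
  trip <- utils::combn(n, 3)
  for (i in seq_len(ncol(trip))) {
    sub <- adj[trip[, i], trip[, i]]
    cls <- .triad_code_map[[as.character(.triad_code(sub))]]
    counts[cls] <- counts[cls] + 1
  }
  counts
}

# random routing_network on n nodes with edge probability pr
random_net <- function(n, pr = 0.4) {
  adj <- matrix(runif(n * n) < pr, n, n)
  diag(adj) <- FALSE
  el <- which(adj, arr.ind = TRUE)
  routing_network(n, el - 1L)
}
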