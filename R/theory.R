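# Three-parameter directed random-graph theory of final network structure
# under the two-patch distribution. The node set splits into sources S and
# targets T (half each); within-class edges (S->S, T->T) exist independently
# with probability p, cross edges S->T with probability q, and back edges
# T->S with probability z (z -> 0 in optimal sparse networks). The module
# provides sampling from the ensemble, a layered-recursion prediction of
# expected source-target routing distance, and a mean-field surrogate for
# how each pruning-rate schedule shapes the final (p, q, z) densities.

#' Three-parameter random-graph ensemble
#'
#' @param p Within-class (`S->S`, `T->T`) edge probability.
#' @param q Cross (`S->T`) edge probability.
#' @param z Back (`T->S`) edge probability.
#' @param n Node count (first half sources, second half targets).
#' @return An `er_triple`.
#' @export
er_triple <- function(p, q, z = 0, n) {
  if (any(c(p, q, z) < 0) || any(c(p, q, z) > 1))
    stop("probabilities must lie in [0, 1]")
  if (n < 2) stop("n must be >= 2")
  structure(list(p = p, q = q, z = z, n = as.integer(n)),
            class = "er_triple")
}

#' @export
print.er_triple <- function(x, ...) {
  cat(sprintf("er_triple: n=%d, p=%.4g q=%.4g z=%.4g (q/p=%.3g)\n",
              x$n, x$p, x$q, x$z,
              if (x$p > 0) x$q / x$p else Inf))
  invisible(x)
}

#' Sample a network from the ER(p, q, z) ensemble
#'
#' Every candidate edge is present independently with its class
#' probability.
#'
#' @param triple An `er_triple`.
#' @param seed Optional integer seed.
#' @return A `routing_network`.
#' @export
sample_er <- function(triple, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- triple$n
  ns <- n %/% 2L
  is_src <- c(rep(TRUE, ns), rep(FALSE, n - ns))
  prob <- matrix(triple$p, n, n)
  prob[is_src, !is_src] <- triple$q
  prob[!is_src, is_src] <- triple$z
  adj <- matrix(runif(n * n), n, n) < prob
  diag(adj) <- FALSE
  structure(list(n = n, adj = adj, budget = NULL),
            class = "routing_network")
}

# class membership of each directed edge of a network under the two-patch
# split (first half sources): returns densities within each class
#' Empirical (p, q, z) densities of a network
#'
#' Measures the within-class, cross, and back edge densities of a network
#' under the two-patch split (lowest-label half are sources), for
#' comparison against [predict_pq()].
#'
#' @param net A `routing_network`.
#' @return An `er_triple` with the observed densities.
#' @export
class_densities <- function(net) {
  n <- net$n
  ns <- n %/% 2L
  is_src <- c(rep(TRUE, ns), rep(FALSE, n - ns))
  adj <- net$adj
  within <- (sum(adj[is_src, is_src]) + sum(adj[!is_src, !is_src])) /
    (ns * (ns - 1L) + (n - ns) * (n - ns - 1L))
  cross <- sum(adj[is_src, !is_src]) / (ns * (n - ns))
  back <- sum(adj[!is_src, is_src]) / (ns * (n - ns))
  er_triple(within, cross, back, n)
}

#' Expected source-target routing distance in the ER(p, q, z) ensemble
#'
#' Predicts the expected shortest-path distance from a uniform source to a
#' uniform target by a hop-layer recursion over the independent-edge
#' ensemble: the target is direct with probability `q`; otherwise
#' reachability spreads through expected BFS layers of sources and
#' targets. Disconnection mass beyond `n` hops is charged the evaluation
#' penalty. The recursion is a concentration (annealed) approximation,
#' validated against Monte-Carlo sampling of the ensemble.
#'
#' @param triple An `er_triple`.
#' @param penalty Distance charged to unreachable targets (default `2n`).
#' @return Expected hops (a single number), with attributes
#'   `conditional_mean` (expectation given the target is reachable) and
#'   `p_unreachable` (predicted disconnection probability). The
#'   conditional quantities are what finite Monte-Carlo samples can check
#'   directly: penalty mass from rare disconnections needs far more draws
#'   than the reachable-path distances.
#' @export
expected_efficiency <- function(triple, penalty = 2 * triple$n) {
  n <- triple$n
  ns <- n %/% 2L
  nt <- n - ns
  p <- triple$p; q <- triple$q; z <- triple$z
  # u_k: P(generic other source unreached within k); v_k: same for a target.
  # A_k/B_k: expected sources/targets newly reached at layer k (A_0 = the
  # source itself). Fresh-edge BFS exposure: each layer only examines edges
  # from newly reached nodes.
  u <- 1; v <- 1
  A <- 1; B <- 0
  Ed <- 0
  Pgt <- 1  # P(d > k), starts at k = 0
  for (k in seq_len(n)) {
    u_new <- u * (1 - p)^A * (1 - z)^B
    v_new <- v * (1 - q)^A * (1 - p)^B
    A_new <- (ns - 1) * (u - u_new)
    B_new <- (nt - 1) * (v - v_new)
    Pgt_new <- Pgt * (1 - q)^A * (1 - p)^B
    Ed <- Ed + k * (Pgt - Pgt_new)
    u <- u_new; v <- v_new; A <- A_new; B <- B_new; Pgt <- Pgt_new
    if (Pgt < 1e-15 || (A < 1e-12 && B < 1e-12)) break
  }
  structure(Ed + penalty * Pgt,
            conditional_mean = if (Pgt < 1) Ed / (1 - Pgt) else NA_real_,
            p_unreachable = Pgt)
}

# Mean-field usage rates per surviving edge of each class for one training
# pair under two-patch routing on the current densities. Returns expected
# per-edge usage increments (rate * m pairs applied by the caller) for
# classes ss (S->S), tt (T->T), st (S->T), ts (T->S).
.usage_rates <- function(p, q, z, ns, nt, Nss, Ntt, Nst, Nts) {
  Ess <- p * Nss; Ett <- p * Ntt; Est <- q * Nst; Ets <- z * Nts
  r <- c(ss = 0, tt = 0, st = 0, ts = 0)
  # direct hit: lands on the specific (s, t) edge when present
  if (Est > 0) r["st"] <- r["st"] + q / Est
  miss <- 1 - q
  # 2-hop routes: via an intermediate source (S->S then S->T) or an
  # intermediate target (S->T then T->T)
  w_s <- (ns - 1) * p * q
  w_t <- (nt - 1) * q * p
  P2 <- 1 - (1 - p * q)^(ns - 1) * (1 - q * p)^(nt - 1)
  if (P2 > 0 && (w_s + w_t) > 0) {
    fs <- w_s / (w_s + w_t); ft <- 1 - fs
    if (Ess > 0) r["ss"] <- r["ss"] + miss * P2 * fs / Ess
    if (Ett > 0) r["tt"] <- r["tt"] + miss * P2 * ft / Ett
    if (Est > 0) r["st"] <- r["st"] + miss * P2 / Est
  }
  # 3-hop routes, by type: SSST (p,p,q), SSTT (p,q,p), STST (q,z,q),
  # STTT (q,p,p); hits allocated by relative route abundance
  miss3 <- miss * (1 - P2)
  w_ssst <- (ns - 1) * (ns - 2) * p * p * q
  w_sstt <- (ns - 1) * (nt - 1) * p * q * p
  w_stst <- (nt - 1) * (ns - 1) * q * z * q
  w_sttt <- (nt - 1) * (nt - 2) * q * p * p
  wtot <- w_ssst + w_sstt + w_stst + w_sttt
  P3 <- 1 - exp(-wtot / max(1, ns))  # crude availability of some 3-hop route
  if (wtot > 0 && miss3 > 0) {
    hit <- miss3 * P3 / wtot
    # each route type uses its class edges once per hop of that class
    if (Ess > 0) r["ss"] <- r["ss"] + hit * (2 * w_ssst + w_sstt) / Ess
    if (Ett > 0) r["tt"] <- r["tt"] + hit * (w_sstt + 2 * w_sttt) / Ett
    if (Est > 0) r["st"] <- r["st"] +
        hit * (w_ssst + w_sstt + 2 * w_stst + w_sttt) / Est
    if (Ets > 0) r["ts"] <- r["ts"] + hit * w_stst / Ets
  }
  r
}

#' Predict final edge-class densities under a pruning schedule
#'
#' A mean-field surrogate for the full pruning simulator under the
#' two-patch distribution. Each edge class (within `S->S`/`T->T`, cross
#' `S->T`, back `T->S`) carries an expected usage distribution over
#' integer usage levels; every interval, Poisson usage increments at the
#' class rates implied by the current densities are applied, and the
#' schedule's removal count is taken from the globally lowest usage levels
#' (ties split proportionally across classes), mirroring
#' lowest-usage-first pruning at the ensemble level. The recurrence is
#' this package's own construction, validated against the full simulator,
#' not a closed-form derivation.
#'
#' @param schedule A `prune_schedule` (or shape name).
#' @param n Node count.
#' @param B Budget (used when `schedule` is a shape name).
#' @param p_pairs Training pairs (default `10 * n`).
#' @return An `er_triple` of predicted final densities.
#' @export
predict_pq <- function(schedule, n, B = NULL, p_pairs = 10 * n) {
  n <- as.integer(n)
  ns <- n %/% 2L; nt <- n - ns
  E0 <- n * (n - 1L)
  if (is.character(schedule)) {
    if (is.null(B)) stop("need 'B' when schedule is given by name")
    schedule <- make_schedule(schedule, E0 = E0, B = B)
  }
  stopifnot(schedule$E0 == E0)
  K <- schedule$K
  m <- p_pairs / K
  Nss <- ns * (ns - 1L); Ntt <- nt * (nt - 1L)
  Nst <- ns * nt; Nts <- nt * ns
  Ntot <- c(ss = Nss, tt = Ntt, st = Nst, ts = Nts)
  umax <- 60L
  # expected edge counts per (class, usage level 0..umax)
  tab <- matrix(0, 4, umax + 1L, dimnames = list(names(Ntot), NULL))
  tab[, 1] <- Ntot
  for (i in seq_len(K)) {
    E <- rowSums(tab)
    dens <- E / Ntot
    p_cur <- sum(tab[c("ss", "tt"), ]) / (Nss + Ntt)
    rate <- .usage_rates(p_cur, dens["st"], dens["ts"], ns, nt,
                         Nss, Ntt, Nst, Nts) * m
    # convolve each class's level distribution with Poisson(rate)
    for (cl in 1:4) {
      if (rate[cl] <= 0) next
      pois <- dpois(0:umax, rate[cl])
      new <- numeric(umax + 1L)
      for (u in 0:umax) {
        w <- tab[cl, u + 1L]
        if (w <= 0) next
        lev <- pmin(u + 0:umax, umax)
        contrib <- w * pois
        for (j in seq_along(lev))
          new[lev[j] + 1L] <- new[lev[j] + 1L] + contrib[j]
      }
      tab[cl, ] <- new
    }
    # remove the schedule's count from the lowest usage levels, splitting
    # each level proportionally across classes
    rem <- schedule$removals[i]
    for (u in 0:umax) {
      if (rem <= 0) break
      lvl <- tab[, u + 1L]
      tot <- sum(lvl)
      if (tot <= 0) next
      take <- min(rem, tot)
      tab[, u + 1L] <- lvl * (1 - take / tot)
      rem <- rem - take
    }
  }
  E <- rowSums(tab)
  er_triple(p = sum(E[c("ss", "tt")]) / (Nss + Ntt),
            q = E["st"] / Nst, z = E["ts"] / Nts, n = n)
}
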