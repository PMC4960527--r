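# Independent reference implementations used as oracles. Everything here is
# deliberately naive (plain R, recompute-from-scratch) so that it shares no
# code path with the package internals it checks.

# adjacency list of present nodes from a ci_graph
oracle_adj <- function(g) {
  n <- g$n_nodes
  adj <- vector("list", n)
  for (r in seq_len(nrow(g$edges))) {
    a <- g$edges[r, 1]; b <- g$edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# BFS distances from i through present nodes (Inf where unreachable)
oracle_dist <- function(adj, present, i) {
  n <- length(present)
  d <- rep(Inf, n)
  d[i] <- 0
  frontier <- i
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) for (w in adj[[v]]) {
      if (present[w] && !is.finite(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
    }
    frontier <- nxt
  }
  d
}

# CI_ell by definition: (k_i - 1) * sum over frontier of (k_j - 1)
oracle_ci <- function(adj, present, ell, i) {
  deg <- vapply(seq_along(present), function(v) {
    if (!present[v]) 0L else sum(present[adj[[v]]])
  }, 1L)
  if (!present[i] || deg[i] == 0) return(0)
  d <- oracle_dist(adj, present, i)
  front <- which(d == ell)
  (deg[i] - 1) * sum(deg[front] - 1)
}

# Naive O(N^2) CI attack: recompute every CI from scratch each step, remove
# the argmax with smallest-id tie-break, until all present nodes are gone.
oracle_ci_attack <- function(g, ell) {
  adj <- oracle_adj(g)
  present <- g$present
  order_removed <- integer(0)
  while (any(present)) {
    live <- which(present)
    ci <- vapply(live, function(i) oracle_ci(adj, present, ell, i), 1.0)
    pick <- live[which.max(ci)]  # which.max takes the first (smallest id) max
    order_removed <- c(order_removed, pick)
    present[pick] <- FALSE
  }
  order_removed
}

# Dense non-backtracking matrix over the 2M directed edges (package edge
# ordering is irrelevant here: only the spectrum is used).
oracle_nb_matrix <- function(g, present = g$present) {
  e <- g$edges
  keep <- present[e[, 1]] & present[e[, 2]]
  e <- e[keep, , drop = FALSE]
  if (nrow(e) == 0) return(matrix(0, 0, 0))
  from <- c(e[, 1], e[, 2])
  to <- c(e[, 2], e[, 1])
  m2 <- length(from)
  B <- matrix(0, m2, m2)
  for (a in seq_len(m2)) for (b in seq_len(m2)) {
    if (to[a] == from[b] && from[a] != to[b]) B[a, b] <- 1
  }
  B
}

oracle_nb_radius <- function(g, present = g$present) {
  B <- oracle_nb_matrix(g, present)
  if (nrow(B) == 0) return(0)
  max(Mod(eigen(B, only.values = TRUE)$values))
}

# Exhaustive minimization of the immunization energy over all 2^N
# occupation configurations (N <= 14 or so).
oracle_energy_min <- function(g, beta, gamma, mu) {
  n <- g$n_nodes
  best <- Inf
  best_occ <- NULL
  for (mask in 0:(2^n - 1)) {
    occ <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    en <- sir_energy(g, occ, beta, gamma, mu)
    if (en < best - 1e-12) { best <- en; best_occ <- occ }
  }
  list(energy = best, occupied = best_occ)
}

# Random tree on n nodes (each node attaches to a uniform earlier node).
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 1) return(ci_graph(matrix(integer(0), 0, 2), n_nodes = 1))
  ci_graph(cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), 1L)),
           n_nodes = n)
}

# Connected-ish sparse random graph for loopy tests.
random_loopy <- function(n, mean_degree = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  generate_er(n, mean_degree, seed = if (is.null(seed)) NULL else seed + 1)
}
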