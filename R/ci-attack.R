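#' Ball frontier and Collective Influence score
#'
#' `frontier()` returns the set of present nodes at shortest-path distance
#' exactly `ell` from node `i` (paths through present nodes only).
#' `ci_value()` evaluates the Collective Influence at radius `ell`,
#' \deqn{CI_\ell(i) = (k_i - 1) \sum_{j \in \partial B(i,\ell)} (k_j - 1),}
#' with live degrees; `ci_values()` does so for every present node.
#'
#' @param graph a [ci_graph()]
#' @param i node id (must be present)
#' @param ell ball radius, an integer >= 1 for CI
#' @return `frontier()`: integer node ids; `ci_value()`: a scalar;
#'   `ci_values()`: numeric vector with `NA` at removed nodes.
#' @examples
#' p <- ci_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))  # path a-b-c-d-e
#' frontier(p, 3, 2)   # the two end nodes
#' ci_value(p, 3, 1)   # (2-1) * ((2-1) + (2-1)) = 2
#' @export
frontier <- function(graph, i, ell) {
  stopifnot(inherits(graph, "ci_graph"), ell >= 0)
  if (!graph$present[i]) stopf("node %d has been removed", i)
  cpp_frontier(graph$n_nodes, graph$edges - 1L, graph$present,
               as.integer(i) - 1L, as.integer(ell)) + 1L
}

#' @rdname frontier
#' @export
ci_value <- function(graph, i, ell) {
  stopifnot(inherits(graph, "ci_graph"), ell >= 1)
  if (!graph$present[i]) stopf("node %d has been removed", i)
  cpp_ci_value(graph$n_nodes, graph$edges - 1L, graph$present,
               as.integer(i) - 1L, as.integer(ell))
}

#' @rdname frontier
#' @export
ci_values <- function(graph, ell) {
  stopifnot(inherits(graph, "ci_graph"), ell >= 1)
  cpp_ci_values(graph$n_nodes, graph$edges - 1L, graph$present,
                as.integer(ell))
}

#' Non-backtracking eigenvalue proxy
#'
#' The attack's stopping monitor
#' \deqn{\lambda(\ell; q) = \left[\frac{\sum_i CI_\ell(i)}{N \langle k
#' \rangle}\right]^{1/(\ell+1)},}
#' an estimate of the largest eigenvalue of the non-backtracking matrix after
#' a fraction q of nodes has been removed. `N` and the mean degree are those
#' of the intact network (q = 0). On tree-like random graphs
#' \eqn{\lambda(\ell; 0) = \kappa - 1} with
#' \eqn{\kappa = \langle k^2 \rangle / \langle k \rangle}; the network is
#' dismantled when \eqn{\lambda} reaches 1. During an attack the sum of live
#' CI scores is maintained incrementally, so the monitor costs nothing extra.
#'
#' @param ci_sum total CI score of the present nodes
#' @param n node count at q = 0
#' @param mean_k0 mean degree at q = 0
#' @param ell CI radius
#' @return the scalar \eqn{\lambda(\ell; q)} (0 when `ci_sum` or `mean_k0`
#'   is 0).
#' @export
lambda_monitor <- function(ci_sum, n, mean_k0, ell) {
  stopifnot(ci_sum >= 0, ell >= 1)
  if (mean_k0 <= 0 || ci_sum <= 0) return(0)
  (ci_sum / (n * mean_k0))^(1 / (ell + 1))
}

record_grid <- function(n, record_every) {
  if (is.null(record_every)) record_every <- max(1L, n %/% 1000L)
  as.integer(max(1L, record_every))
}

make_trace <- function(order, q, lambda, giant, second, n0) {
  data.frame(
    step = seq_along(order),
    node_removed = order,
    q = q,
    giant = giant / n0,
    second = second,
    lambda = lambda
  )
}

#' Adaptive Collective Influence attack
#'
#' Removes nodes one by one in decreasing order of their current
#' \eqn{CI_\ell} score, processed through an indexed max-heap. After each
#' removal only the nodes within distance `ell + 1` of the removed node are
#' updated: the inner layers (distance <= `ell`) are recomputed by BFS, the
#' outer layer loses `(k - 1)` for every neighbor of the removed node on its
#' `ell`-frontier, and each update is followed by a local re-heapification.
#' The attack stops when \eqn{\lambda(\ell; q) \le 1} (the percolation
#' point, without ever computing the giant component per removal) or after a
#' fixed fraction of removals. Component sizes are recorded on a thinned
#' grid of `record_every` removals.
#'
#' @param graph a [ci_graph()]; already-masked nodes are ignored.
#' @param ell ball radius (>= 1; for the degree-based `ell = 0` analogue see
#'   [hda_attack()]).
#' @param stop_rule `"lambda"` (stop at \eqn{\lambda \le 1}) or
#'   `"fixed_fraction"`.
#' @param fixed_q fraction of nodes to remove under `"fixed_fraction"`.
#' @param deterministic_ties break equal scores by smallest node id, making
#'   the removal order reproducible and comparable with a reference
#'   implementation.
#' @param exact_update recompute every node in the ball of radius `ell + 1`
#'   by BFS instead of using the outer-layer shortcut (validation aid).
#' @param record_every spacing of component checks; default
#'   `max(1, N/1000)`.
#' @return An object of class `attack_trace`: list with `trace` (data frame
#'   `step, node_removed, q, giant, second, lambda`; `giant` is a fraction
#'   of N, `second` a node count, `NA` between grid points), `qc_estimate`
#'   (q at the first \eqn{\lambda \le 1}), `removed`, `stop_reason`,
#'   `lambda0`, `graph_after` and method metadata.
#' @examples
#' g <- generate_er(500, 3.5, seed = 4)
#' a <- ci_attack(g, ell = 2, deterministic_ties = TRUE)
#' a$qc_estimate
#' @export
ci_attack <- function(graph, ell = 3, stop_rule = c("lambda", "fixed_fraction"),
                      fixed_q = 1, deterministic_ties = FALSE,
                      exact_update = FALSE, record_every = NULL) {
  stopifnot(inherits(graph, "ci_graph"))
  if (ell < 1) stopf("ell must be >= 1 (use hda_attack() for the ell = 0 limit)")
  stop_rule <- match.arg(stop_rule)
  stopifnot(fixed_q >= 0, fixed_q <= 1)
  rec <- record_grid(graph$n_nodes, record_every)
  r <- cpp_ci_attack(graph$n_nodes, graph$edges - 1L, graph$present,
                     as.integer(ell), if (stop_rule == "lambda") 0L else 1L,
                     fixed_q, isTRUE(deterministic_ties), isTRUE(exact_update),
                     rec)
  after <- graph
  after$present <- r$present
  after <- refresh_mask(after)
  structure(list(
    method = "ci", ell = ell,
    trace = make_trace(r$order + 1L, r$q, r$lambda, r$giant, r$second, r$n0),
    qc_estimate = r$qc_estimate,
    removed = r$order + 1L,
    stop_reason = r$stop_reason,
    lambda0 = r$lambda0, giant0 = r$giant0, second0 = r$second0,
    n0 = r$n0, mean_k0 = r$mean_k0,
    graph_after = after
  ), class = "attack_trace")
}

#' High-degree-adaptive attack
#'
#' Repeatedly removes the present node of highest live degree, using the
#' same heap machinery as [ci_attack()] (HDA is the `ell = 0` analogue of
#' CI: the score is the degree itself). There is no eigenvalue monitor for
#' HDA, so the attack stops when the giant component, checked on the thinned
#' grid, has fallen to `giant_stop` nodes or fewer.
#'
#' @inheritParams ci_attack
#' @param giant_stop size at which the giant component counts as destroyed;
#'   defaults to `max(2, ceiling(2 * log(N)))`, the non-extensive cluster
#'   scale of a random graph.
#' @return An `attack_trace` (the `lambda` column is `NA`); `qc_estimate` is
#'   the removed fraction at which the giant component died.
#' @examples
#' star <- ci_graph(cbind(1, 2:6))
#' hda_attack(star)$removed[1]  # the hub goes first
#' @export
hda_attack <- function(graph, deterministic_ties = FALSE, record_every = NULL,
                       giant_stop = NULL) {
  stopifnot(inherits(graph, "ci_graph"))
  rec <- record_grid(graph$n_nodes, record_every)
  if (is.null(giant_stop))
    giant_stop <- max(2, ceiling(2 * log(max(graph$n_nodes, 2))))
  r <- cpp_hda_attack(graph$n_nodes, graph$edges - 1L, graph$present,
                      isTRUE(deterministic_ties), rec, as.integer(giant_stop))
  after <- graph
  after$present <- r$present
  after <- refresh_mask(after)
  structure(list(
    method = "hda", ell = 0,
    trace = make_trace(r$order + 1L, r$q, NA_real_, r$giant, r$second, r$n0),
    qc_estimate = r$qc_estimate,
    removed = r$order + 1L,
    stop_reason = r$stop_reason,
    lambda0 = NA_real_, giant0 = r$giant0, second0 = r$second0,
    n0 = r$n0,
    graph_after = after
  ), class = "attack_trace")
}

#' @export
print.attack_trace <- function(x, ...) {
  cat(sprintf("%s attack%s: %d removals, qc = %s (%s)\n",
              toupper(x$method),
              if (!is.null(x$ell) && is.finite(x$ell) && x$ell > 0)
                sprintf(" (ell = %d)", as.integer(x$ell)) else "",
              length(x$removed),
              ifelse(is.na(x$qc_estimate), "NA", sprintf("%.4f", x$qc_estimate)),
              x$stop_reason))
  invisible(x)
}
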