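#' Undirected simple graph with a presence mask
#'
#' The container used by all attack and immunization routines: a fixed edge
#' list over nodes `1..n_nodes` plus a boolean presence mask. Node removal is
#' implemented as masking (never physical deletion), so the original
#' adjacency is always available for reinsertion. Live degrees count present
#' neighbors of present nodes only.
#'
#' @param edges two-column integer matrix of undirected edges (1-based node
#'   ids). Self-loops and parallel edges are rejected.
#' @param n_nodes number of nodes; defaults to `max(edges)` (must cover all
#'   endpoints).
#' @return An object of class `ci_graph`: a list with fields `n_nodes`,
#'   `edges`, `present` (logical mask), `degree` (live degrees), `m_edges`
#'   (live undirected edge count) and `mean_degree_initial`.
#' @examples
#' g <- ci_graph(rbind(c(1, 2), c(2, 3)))
#' g$degree
#' @export
ci_graph <- function(edges, n_nodes = NULL) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (anyNA(edges)) stopf("edge list contains non-integer entries")
    if (min(edges) < 1L) stopf("node ids must be >= 1")
    if (any(edges[, 1] == edges[, 2])) stopf("self-loops are not allowed")
  }
  if (is.null(n_nodes)) n_nodes <- if (nrow(edges) > 0) max(edges) else 0L
  n_nodes <- as.integer(n_nodes)
  if (nrow(edges) > 0 && max(edges) > n_nodes)
    stopf("edge endpoint exceeds n_nodes")
  key <- pmin(edges[, 1], edges[, 2]) * (n_nodes + 1) + pmax(edges[, 1], edges[, 2])
  if (anyDuplicated(key)) stopf("parallel edges are not allowed")
  g <- structure(list(
    n_nodes = n_nodes,
    edges = edges,
    present = rep(TRUE, n_nodes),
    degree = integer(n_nodes),
    m_edges = nrow(edges),
    mean_degree_initial = if (n_nodes > 0) 2 * nrow(edges) / n_nodes else 0
  ), class = "ci_graph")
  g$degree <- tabulate(edges, nbins = n_nodes)
  g
}

#' @export
print.ci_graph <- function(x, ...) {
  np <- sum(x$present)
  cat(sprintf("ci_graph: %d nodes (%d present), %d live edges, <k>0 = %.3f\n",
              x$n_nodes, np, x$m_edges, x$mean_degree_initial))
  invisible(x)
}

# refresh degree / m_edges bookkeeping after a mask change
refresh_mask <- function(g) {
  g$degree <- cpp_live_degrees(g$n_nodes, g$edges - 1L, g$present)
  g$m_edges <- sum(g$degree) %/% 2L
  g
}

#' Remove or restore nodes by masking
#'
#' Removal masks nodes out and decrements live degrees; the adjacency is kept
#' so that nodes can later be reinserted. Restoring only re-activates edges
#' whose other endpoint is present.
#'
#' @param graph a [ci_graph()]
#' @param nodes integer node ids
#' @return The modified graph.
#' @export
remove_nodes <- function(graph, nodes) {
  stopifnot(inherits(graph, "ci_graph"))
  graph$present[nodes] <- FALSE
  refresh_mask(graph)
}

#' @rdname remove_nodes
#' @export
restore_nodes <- function(graph, nodes) {
  stopifnot(inherits(graph, "ci_graph"))
  graph$present[nodes] <- TRUE
  refresh_mask(graph)
}

#' Adjacency list of a graph
#'
#' @param graph a [ci_graph()]
#' @param live if `TRUE`, restrict to present nodes.
#' @return list of integer neighbor vectors, one per node.
#' @export
adjacency_list <- function(graph, live = FALSE) {
  n <- graph$n_nodes
  e <- graph$edges
  if (live) {
    keep <- graph$present[e[, 1]] & graph$present[e[, 2]]
    e <- e[keep, , drop = FALSE]
  }
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(n)))
  lapply(adj, as.integer)
}

#' Erdos-Renyi random graph with fixed edge count
#'
#' Samples the G(n, M) model with `M = round(n * mean_degree / 2)` distinct
#' edges, so the average degree is exact by construction. Deterministic for a
#' fixed seed.
#'
#' @param n number of nodes (>= 1)
#' @param mean_degree target average degree
#' @param seed integer seed
#' @return a [ci_graph()]
#' @examples
#' g <- generate_er(1000, 3.5, seed = 1)
#' g$m_edges  # exactly 1750
#' @export
generate_er <- function(n, mean_degree, seed = NULL) {
  stopifnot(n >= 1, mean_degree >= 0)
  m <- round(n * mean_degree / 2)
  if (m > n * (n - 1) / 2)
    stopf("mean_degree %.3f implies more than n(n-1)/2 edges", mean_degree)
  with_seed(seed, {
    codes <- numeric(0)
    while (length(codes) < m) {
      t <- ceiling((m - length(codes)) * 1.3) + 16
      a <- sample.int(n, t, replace = TRUE)
      b <- sample.int(n, t, replace = TRUE)
      keep <- a != b
      lo <- pmin(a[keep], b[keep])
      hi <- pmax(a[keep], b[keep])
      codes <- unique(c(codes, (lo - 1) * n + hi))
    }
    codes <- sort(codes[seq_len(m)])
    hi <- ((codes - 1) %% n) + 1
    lo <- ((codes - 1) %/% n) + 1
    ci_graph(cbind(as.integer(lo), as.integer(hi)), n_nodes = n)
  })
}

#' Random regular graph
#'
#' Pairing (configuration) model with full restart on self-loop or
#' multi-edge collisions: cheap and adequate for small fixed degree.
#'
#' @param n number of nodes; `n * k` must be even
#' @param k degree of every node (`k < n`)
#' @param seed integer seed
#' @param max_restarts restarts before giving up
#' @return a [ci_graph()] in which every node has degree exactly `k`
#' @examples
#' g <- generate_rrg(1000, 3, seed = 1)
#' all(g$degree == 3)
#' @export
generate_rrg <- function(n, k, seed = NULL, max_restarts = 10000) {
  stopifnot(n >= 1, k >= 0)
  if ((n * k) %% 2 != 0) stopf("n * k must be even (handshake parity)")
  if (k >= n) stopf("k must be smaller than n")
  with_seed(seed, {
    for (try in seq_len(max_restarts)) {
      stubs <- rep.int(seq_len(n), k)
      stubs <- stubs[sample.int(n * k)]
      a <- stubs[seq(1, n * k, by = 2)]
      b <- stubs[seq(2, n * k, by = 2)]
      if (any(a == b)) next
      code <- (pmin(a, b) - 1) * n + pmax(a, b)
      if (anyDuplicated(code)) next
      return(ci_graph(cbind(a, b), n_nodes = n))
    }
    stopf("pairing model failed to produce a simple graph in %d restarts",
          max_restarts)
  })
}

#' Read / write whitespace-separated edge lists
#'
#' One `i j` pair per line, 0-based ids, `#` comment lines ignored.
#' Arbitrary integer labels are mapped to dense internal ids; the mapping is
#' stored in `attr(graph, "labels")` and used again on writing. Self-loops,
#' duplicate edges and non-integer tokens are rejected with the offending
#' line number.
#'
#' @param path file path
#' @return [read_edgelist()] returns a [ci_graph()]; [write_edgelist()]
#'   returns `path` invisibly.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad) > 0)
    stopf("line %d: expected two integer tokens", lineno[bad[1]])
  a <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 1L)))
  b <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 2L)))
  nonint <- which(is.na(a) | is.na(b) | a != round(a) | b != round(b))
  if (length(nonint) > 0)
    stopf("line %d: non-integer token", lineno[nonint[1]])
  loops <- which(a == b)
  if (length(loops) > 0)
    stopf("line %d: self-loop '%s'", lineno[loops[1]], lines[loops[1]])
  labels <- sort(unique(c(a, b)))
  ia <- match(a, labels)
  ib <- match(b, labels)
  code <- (pmin(ia, ib) - 1) * length(labels) + pmax(ia, ib)
  dup <- which(duplicated(code))
  if (length(dup) > 0)
    stopf("line %d: duplicate edge '%s'", lineno[dup[1]], lines[dup[1]])
  g <- ci_graph(cbind(ia, ib), n_nodes = length(labels))
  attr(g, "labels") <- labels
  g
}

#' @rdname read_edgelist
#' @param graph a [ci_graph()]; all nodes are written regardless of mask.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "ci_graph"))
  labels <- attr(graph, "labels")
  if (is.null(labels)) labels <- seq_len(graph$n_nodes) - 1
  e <- graph$edges
  writeLines(paste(labels[e[, 1]], labels[e[, 2]]), path)
  invisible(path)
}

#' Connected-component statistics under the presence mask
#'
#' Sizes of the largest and second-largest connected components among present
#' nodes (breadth-first search), plus the component count. The giant
#' component G and the peak of the second-largest cluster are the standard
#' order parameters of a percolation attack.
#'
#' @param graph a [ci_graph()]
#' @return list with `giant_size`, `second_size`, `n_components`.
#' @examples
#' g <- ci_graph(rbind(c(1, 2), c(2, 3), c(4, 5)))
#' components(g)
#' @export
components <- function(graph) {
  stopifnot(inherits(graph, "ci_graph"))
  st <- cpp_components(graph$n_nodes, graph$edges - 1L, graph$present)
  structure(list(giant_size = st[1], second_size = st[2], n_components = st[3]),
            class = "component_stats")
}

#' @export
print.component_stats <- function(x, ...) {
  cat(sprintf("components: giant %d, second %d, count %d\n",
              x$giant_size, x$second_size, x$n_components))
  invisible(x)
}
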