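test_that("ci_graph enforces simple undirected structure", {
  expect_error(ci_graph(rbind(c(1, 1))), "self-loop")
  expect_error(ci_graph(rbind(c(1, 2), c(2, 1))), "parallel")
  g <- ci_graph(rbind(c(1, 2), c(2, 3)))
  expect_equal(g$degree, c(1L, 2L, 1L))
  expect_equal(sum(g$degree), 2 * g$m_edges)
})

test_that("generate_er produces exactly round(n*k/2) simple edges", {
  g0 <- generate_er(10, 0, seed = 1)
  expect_equal(nrow(g0$edges), 0)
  g <- generate_er(1000, 3.5, seed = 3)
  expect_equal(nrow(g$edges), 1750)
  expect_true(all(g$edges[, 1] != g$edges[, 2]))
  key <- pmin(g$edges[, 1], g$edges[, 2]) * 1e6 + pmax(g$edges[, 1], g$edges[, 2])
  expect_equal(anyDuplicated(key), 0L)
  # reproducibility, bit for bit
  g2 <- generate_er(1000, 3.5, seed = 3)
  expect_identical(g$edges, g2$edges)
  expect_error(generate_er(10, 20, seed = 1), "implies")
})

test_that("ER degree moments approach the Poisson limit", {
  g <- generate_er(100000, 3.5, seed = 7)
  k <- g$degree
  kappa_minus_1 <- mean(k^2) / mean(k) - 1
  # Poisson: <k^2>/<k> - 1 = <k>; allow 3 standard errors
  se <- stats::sd(k^2 / mean(k)) / sqrt(length(k))
  expect_lt(abs(kappa_minus_1 - 3.5), 3 * se + 0.02)
})

test_that("generate_rrg is k-regular and respects parity", {
  expect_error(generate_rrg(5, 3, seed = 1), "parity")
  expect_error(generate_rrg(4, 5, seed = 1), "smaller")
  g <- generate_rrg(1000, 3, seed = 2)
  expect_true(all(g$degree == 3))
  expect_equal(nrow(g$edges), 1500)
  # n=4, k=3 forces the complete graph K4
  k4 <- generate_rrg(4, 3, seed = 9)
  expect_equal(nrow(k4$edges), 6)
  expect_true(all(k4$degree == 3))
})

test_that("edge-list io round-trips and rejects malformed lines", {
  path <- withr::local_tempfile()
  writeLines(c("# comment", "0 1", "1 2"), path)
  g <- read_edgelist(path)
  expect_equal(g$n_nodes, 3)
  expect_equal(components(g)$giant_size, 3)

  out <- withr::local_tempfile()
  gg <- generate_er(200, 3, seed = 5)
  write_edgelist(gg, out)
  back <- read_edgelist(out)
  # compare in label space: the reader maps arbitrary labels to dense ids
  lab <- function(g) {
    l <- attr(g, "labels")
    if (is.null(l)) l <- seq_len(g$n_nodes) - 1
    e <- cbind(l[g$edges[, 1]], l[g$edges[, 2]])
    sort(pmin(e[, 1], e[, 2]) * 1e6 + pmax(e[, 1], e[, 2]))
  }
  expect_equal(lab(back), lab(gg))

  writeLines(c("0 1", "2 2"), path)
  expect_error(read_edgelist(path), "line 2")
  writeLines(c("0 1", "1 0"), path)
  expect_error(read_edgelist(path), "duplicate")
  writeLines(c("0 x"), path)
  expect_error(read_edgelist(path), "non-integer")
})

test_that("component statistics match hand counts", {
  # two disjoint cliques of sizes 4 and 3
  cl4 <- t(combn(1:4, 2))
  cl3 <- t(combn(5:7, 2))
  g <- ci_graph(rbind(cl4, cl3))
  st <- components(g)
  expect_equal(st$giant_size, 4)
  expect_equal(st$second_size, 3)
  expect_equal(st$n_components, 2)
  # star with the center removed: 5 isolated leaves
  star <- ci_graph(cbind(1, 2:6))
  star <- remove_nodes(star, 1)
  st2 <- components(star)
  expect_equal(st2$giant_size, 1)
  expect_equal(st2$second_size, 1)
  expect_equal(st2$n_components, 5)
  # empty graph
  e <- remove_nodes(ci_graph(rbind(c(1, 2))), 1:2)
  expect_equal(components(e)$giant_size, 0)
})

test_that("component sizes sum to present nodes; removal monotonicity", {
  g <- generate_er(300, 2.5, seed = 11)
  set.seed(1)
  prev_giant <- components(g)$giant_size
  for (v in sample.int(300, 40)) {
    g <- remove_nodes(g, v)
    st <- components(g)
    expect_lte(st$giant_size, prev_giant)
    prev_giant <- st$giant_size
  }
  g2 <- restore_nodes(g, which(!g$present))
  expect_equal(components(g2)$giant_size, components(generate_er(300, 2.5, seed = 11))$giant_size)
})

test_that("masking keeps degrees and edge counts consistent", {
  g <- generate_rrg(100, 3, seed = 4)
  g <- remove_nodes(g, c(5, 10, 15))
  expect_equal(sum(g$degree) %% 2, 0)
  expect_equal(sum(g$degree), 2 * g$m_edges)
  expect_true(all(g$degree[c(5, 10, 15)] == 0))
  live <- adjacency_list(g, live = TRUE)
  expect_equal(lengths(live)[g$present], g$degree[g$present],
               ignore_attr = TRUE)
})
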