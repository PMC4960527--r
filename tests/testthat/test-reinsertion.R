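test_that("reinsertion prefers nodes joining fewest clusters", {
  # path 1-2-3 and 4-5-6 with candidates: node 7 adjacent to both clusters
  # (joins 2), node 8 adjacent to one (joins 1), node 9 with no present
  # neighbor (joins 0). Expected reinsertion order by criterion: 9, 8, 7.
  g <- ci_graph(rbind(c(1, 2), c(2, 3), c(4, 5), c(5, 6),
                      c(7, 3), c(7, 4), c(8, 1)), n_nodes = 9)
  g <- remove_nodes(g, c(7, 8, 9))
  r <- reinsert(g, batch_fraction = 1 / 9)  # one node per batch
  expect_equal(r$order, c(9, 8, 7))
  # the neighborless node forms its own cluster; paths of 3 stay the giant
  expect_equal(r$curve$giant[1], 3)
})

test_that("full reinsertion restores the original graph", {
  g <- generate_er(500, 3.5, seed = 61)
  orig_giant <- components(g)$giant_size
  a <- ci_attack(g, ell = 2)
  r <- reinsert(a$graph_after)
  expect_true(all(r$graph_after$present))
  expect_equal(r$graph_after$degree, g$degree)
  expect_equal(tail(r$curve$q, 1), 0)
  expect_equal(tail(r$curve$giant, 1), orig_giant)
  # G non-decreasing as q decreases along the reinsertion path
  expect_true(all(diff(r$curve$giant) >= 0))
})

test_that("reinsertion curve lies at or below the forward attack curve", {
  g <- generate_er(2000, 3.5, seed = 62)
  a <- ci_attack(g, ell = 3, record_every = 5)
  r <- reinsert(a$graph_after, batch_fraction = 0.002)
  fwd <- a$trace[!is.na(a$trace$giant), c("q", "giant")]
  fwd$giant <- fwd$giant * 2000
  for (i in seq_len(nrow(r$curve))) {
    qi <- r$curve$q[i]
    j <- which.min(abs(fwd$q - qi))
    if (abs(fwd$q[j] - qi) <= 0.005)
      expect_lte(r$curve$giant[i], fwd$giant[j] + 2000 * 0.01)
  }
})

test_that("results are insensitive to batch fraction below the default", {
  g <- generate_er(1500, 3.5, seed = 63)
  a <- ci_attack(g, ell = 2)
  r1 <- reinsert(a$graph_after, batch_fraction = 0.002)
  r2 <- reinsert(ci_attack(g, ell = 2)$graph_after, batch_fraction = 0.001)
  # compare G at matched q on a grid near the percolation point
  qs <- seq(0.02, max(min(max(r1$curve$q), max(r2$curve$q)), 0.02), by = 0.01)
  g1 <- approx(r1$curve$q, r1$curve$giant, xout = qs, rule = 2)$y
  g2 <- approx(r2$curve$q, r2$curve$giant, xout = qs, rule = 2)$y
  expect_true(all(abs(g1 - g2) <= 0.01 * 1500))
})
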