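path5 <- function() ci_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))

test_that("frontier is the exact-distance shell through present nodes", {
  p <- path5()
  expect_setequal(frontier(p, 3, 2), c(1, 5))
  star <- ci_graph(cbind(1, 2:7))
  expect_setequal(frontier(star, 1, 1), 2:7)
  expect_length(frontier(star, 1, 2), 0)
  # 4-cycle: shortest-path rule gives the single antipodal node, not the
  # tree-unrolled pair
  cyc <- ci_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  expect_equal(frontier(cyc, 1, 2), 3)
  p2 <- remove_nodes(p, 2)
  expect_error(frontier(p2, 2, 1), "removed")
})

test_that("ci_value matches the defining formula", {
  p <- path5()
  expect_equal(ci_value(p, 3, 1), 2)     # (2-1) * ((2-1)+(2-1))
  expect_equal(ci_value(p, 1, 1), 0)     # degree-1 nodes score 0 at any ell
  expect_equal(ci_value(p, 1, 3), 0)
  star <- ci_graph(cbind(1, 2:6))
  expect_equal(ci_value(star, 1, 1), 0)  # K_{1,5} center: leaves have k-1 = 0
  # random graphs against the naive oracle
  set.seed(55)
  for (rep in 1:5) {
    g <- generate_er(40, 3, seed = 500 + rep)
    adj <- oracle_adj(g)
    for (ell in 1:3) {
      want <- vapply(seq_len(40), function(i) oracle_ci(adj, g$present, ell, i), 1.0)
      expect_equal(ci_values(g, ell), want)
    }
  }
})

test_that("lambda at q=0 equals the closed form on regular graphs", {
  r <- generate_rrg(2000, 3, seed = 8)
  # at ell = 1 the frontier is always the k neighbors: lambda = k - 1 exactly
  lam1 <- lambda_monitor(sum(ci_values(r, 1)), 2000, 3, 1)
  expect_equal(lam1, 2)
  expect_equal(lambda_monitor(0, 100, 3.5, 2), 0)
})

test_that("lambda at q=0 approaches kappa - 1 on ER graphs", {
  g <- generate_er(30000, 3.5, seed = 13)
  k <- g$degree
  kappa <- mean(k^2) / mean(k)
  lam <- lambda_monitor(sum(ci_values(g, 3)), g$n_nodes, mean(k), 3)
  expect_lt(abs(lam - (kappa - 1)) / (kappa - 1), 0.05)
})

test_that("heap attack equals the naive recompute-all reference", {
  # trees at several radii; loopy graphs too (the outer-layer update counts
  # frontier multiplicity, so equality is exact beyond trees as well)
  for (rep in 1:6) {
    tr <- random_tree(40, seed = 700 + rep)
    for (ell in c(1, 3)) {
      want <- oracle_ci_attack(tr, ell)
      got <- ci_attack(tr, ell = ell, stop_rule = "fixed_fraction",
                       fixed_q = 1, deterministic_ties = TRUE)$removed
      expect_equal(got, want, info = sprintf("tree rep %d ell %d", rep, ell))
    }
  }
  for (rep in 1:6) {
    g <- generate_er(40, 3, seed = 800 + rep)
    for (ell in 1:2) {
      want <- oracle_ci_attack(g, ell)
      got <- ci_attack(g, ell = ell, stop_rule = "fixed_fraction",
                       fixed_q = 1, deterministic_ties = TRUE)$removed
      expect_equal(got, want, info = sprintf("loopy rep %d ell %d", rep, ell))
    }
  }
})

test_that("exact_update reproduces the shortcut attack", {
  g <- generate_er(60, 3.2, seed = 21)
  a <- ci_attack(g, ell = 2, stop_rule = "fixed_fraction", fixed_q = 1,
                 deterministic_ties = TRUE)
  b <- ci_attack(g, ell = 2, stop_rule = "fixed_fraction", fixed_q = 1,
                 deterministic_ties = TRUE, exact_update = TRUE)
  expect_equal(a$removed, b$removed)
})

test_that("lambda stopping rule behaves at the boundaries", {
  # star: all CI are 0, lambda(0) = 0 <= 1, so nothing is removed
  star <- ci_graph(cbind(1, 2:6))
  a <- ci_attack(star, ell = 1)
  expect_equal(length(a$removed), 0)
  expect_equal(a$qc_estimate, 0)
  # supercritical ER: a nontrivial fraction is removed, lambda decreases
  g <- generate_er(2000, 3.5, seed = 17)
  at <- ci_attack(g, ell = 2, record_every = 10)
  expect_gt(at$lambda0, 1)
  expect_equal(at$stop_reason, "lambda")
  expect_lte(tail(at$trace$lambda, 1), 1)
  expect_gt(at$qc_estimate, 0.05)
  expect_lt(at$qc_estimate, 0.4)
  # q increases by 1/N each step
  expect_equal(diff(at$trace$q), rep(1 / 2000, nrow(at$trace) - 1))
  # ci_sum exhaustion: full removal drives lambda to exactly 0
  full <- ci_attack(g, ell = 2, stop_rule = "fixed_fraction", fixed_q = 1)
  expect_equal(tail(full$trace$lambda, 1), 0)
  expect_true(all(full$trace$lambda >= 0))
})

test_that("ell = 0 is rejected for CI", {
  expect_error(ci_attack(path5(), ell = 0), "ell")
})

test_that("hda removes hubs first and dismantles the graph", {
  star <- ci_graph(cbind(1, 2:6))
  h <- hda_attack(star)
  expect_equal(h$removed[1], 1)
  # regular graph: all degrees tied; deterministic ties make it reproducible
  r <- generate_rrg(60, 3, seed = 30)
  h1 <- hda_attack(r, deterministic_ties = TRUE)
  h2 <- hda_attack(r, deterministic_ties = TRUE)
  expect_identical(h1$removed, h2$removed)
  g <- generate_er(2000, 3.5, seed = 18)
  hh <- hda_attack(g, record_every = 10)
  expect_equal(hh$stop_reason, "giant_zero")
  fin <- tail(hh$trace$giant[!is.na(hh$trace$giant)], 1) * 2000
  expect_lte(fin, max(2, ceiling(2 * log(2000))))
})

test_that("trace io round-trips through TSV", {
  g <- generate_er(400, 3, seed = 40)
  a <- ci_attack(g, ell = 2, record_every = 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(a, path)
  back <- read_trace(path)
  expect_equal(names(back), c("step", "node_removed", "q", "giant", "second", "lambda"))
  expect_equal(back$q, a$trace$q)
  expect_equal(back$node_removed, a$trace$node_removed)
})
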