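test_that("run_config produces trace, summary and is reproducible", {
  dir <- withr::local_tempdir()
  cfg <- list(method = "ci", generator = "er", n = 500, mean_degree = 3.5,
              ell = 2, deterministic_ties = TRUE, seed = 9,
              out_trace = file.path(dir, "t.tsv"),
              out_summary = file.path(dir, "s.json"))
  r1 <- run_config(cfg)
  expect_true(file.exists(cfg$out_trace))
  expect_true(file.exists(cfg$out_summary))
  s <- jsonlite::read_json(cfg$out_summary)
  expect_equal(s$schema_version, 1L)
  expect_equal(s$method, "ci")
  expect_equal(s$qc_estimate, r1$result$qc_estimate)
  # byte-identical trace on a second run with the same config + seed
  bytes1 <- readBin(cfg$out_trace, "raw", file.size(cfg$out_trace))
  run_config(cfg)
  bytes2 <- readBin(cfg$out_trace, "raw", file.size(cfg$out_trace))
  expect_identical(bytes1, bytes2)
})

test_that("run_config accepts a graph file and appends reinsertion", {
  dir <- withr::local_tempdir()
  g <- generate_er(300, 3.5, seed = 10)
  gf <- file.path(dir, "g.edges")
  write_edgelist(g, gf)
  cfg <- list(method = "ci", graph_file = gf, ell = 2, reinsert = TRUE,
              seed = 1, out_trace = file.path(dir, "t.tsv"),
              out_summary = file.path(dir, "s.json"))
  run_config(cfg)
  tr <- read_trace(cfg$out_trace)
  expect_true(all(c("q_reinsert", "giant_reinsert") %in% names(tr)))
})

test_that("bad configs error", {
  expect_error(run_config(list(method = "nope")), "arg")
  expect_error(run_config(list(method = "ci")), "generator")
  expect_error(run_config(list(method = "ci", generator = "er", n = 100,
                               mean_degree = 3, ell = 0, seed = 1)), "ell")
})

test_that("the command-line driver runs end to end", {
  script <- system.file("cli", "ci-immunize.R", package = "ciperc")
  skip_if(script == "", "cli script not installed")
  dir <- withr::local_tempdir()
  rbin <- file.path(R.home("bin"), "Rscript")
  gf <- file.path(dir, "g.edges")
  out <- system2(rbin, c(script, "gen-rrg", "--n", "200", "--k", "3",
                         "--seed", "1", "--out", gf),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(gf))
  tf <- file.path(dir, "trace.tsv")
  out2 <- system2(rbin, c(script, "attack", "--method", "ci", "--ell", "2",
                          "--in", gf, "--out", tf, "--seed", "7"),
                  stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(tf))
  expect_true(file.exists(sub("\\.tsv$", ".json", tf)))
  tr <- read_trace(tf)
  expect_gt(nrow(tr), 0)
})
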