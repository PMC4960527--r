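#' Write / read an attack trace as TSV
#'
#' Tab-separated with header columns `step, node_removed, q, giant, second,
#' lambda` (`giant` a fraction of N, `second` a node count, `NA` off the
#' component-check grid). [reinsert()] results can be appended as the extra
#' columns `q_reinsert`, `giant_reinsert`, padded with `NA` to the trace
#' length.
#'
#' @param trace an `attack_trace` (or its `trace` data frame)
#' @param path output path
#' @param reinsertion optional `reinsertion_curve` to append
#' @return `write_trace()` returns `path` invisibly; `read_trace()` the data
#'   frame.
#' @export
write_trace <- function(trace, path, reinsertion = NULL) {
  df <- if (inherits(trace, "attack_trace")) trace$trace else trace
  if (!is.null(reinsertion)) {
    cv <- reinsertion$curve
    pad <- function(x) c(x, rep(NA, max(0, nrow(df) - length(x))))[seq_len(max(nrow(df), length(x)))]
    if (nrow(cv) > nrow(df)) df[seq(nrow(df) + 1, nrow(cv)), ] <- NA
    df$q_reinsert <- pad(cv$q)
    df$giant_reinsert <- pad(cv$giant_frac)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' Run a fully-specified experiment
#'
#' Single entry point tying generators, attacks, reinsertion and trace
#' output together; the command-line driver is a thin wrapper around it.
#' Every run is reproducible from its configuration plus seed: one seed
#' governs the generator and any algorithmic randomness.
#'
#' @param config a named list (or path to a JSON file) with fields
#'   `method` (`"ci"`, `"hda"`, `"cip"`, `"cibp"`), a graph source (either
#'   `graph_file`, or `generator` = `"er"`/`"rrg"` with `n` and
#'   `mean_degree`/`k`), method parameters (`ell`, `tol`, `mu`, `beta`,
#'   `gamma`, `batch_fraction`), `reinsert` (logical), `seed`, and output
#'   paths `out_trace`, `out_summary`.
#' @return Invisibly, a list with the attack result, the summary list, and
#'   the output paths. The JSON summary (schema version 1) records the
#'   config echo, seed, `qc_estimate`, stop reason, convergence flags and
#'   wall time.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  method <- match.arg(config$method, c("ci", "hda", "cip", "cibp"))
  seed <- config$seed
  t0 <- proc.time()[["elapsed"]]

  g <- if (!is.null(config$graph_file)) {
    read_edgelist(config$graph_file)
  } else if (identical(config$generator, "er")) {
    generate_er(config$n, config$mean_degree, seed = seed)
  } else if (identical(config$generator, "rrg")) {
    generate_rrg(config$n, config$k, seed = seed)
  } else stopf("config needs either graph_file or generator = 'er'/'rrg'")

  ell <- config$ell %||% 3
  res <- switch(method,
    ci = ci_attack(g, ell = ell,
                   stop_rule = config$stop %||% "lambda",
                   fixed_q = config$fixed_q %||% 1,
                   deterministic_ties = isTRUE(config$deterministic_ties)),
    hda = hda_attack(g, deterministic_ties = isTRUE(config$deterministic_ties)),
    cip = ci_p_attack(g, tol = config$tol %||% 1e-7),
    cibp = {
      per <- cibp_percolation(g, seed = seed,
                              beta = config$beta %||% (1 - 1e-12),
                              gamma = config$gamma)
      per
    })

  rein <- NULL
  if (isTRUE(config$reinsert) && method %in% c("ci", "hda", "cip"))
    rein <- reinsert(res$graph_after,
                     batch_fraction = config$batch_fraction %||% 0.002)

  summary <- list(
    schema_version = 1L,
    method = method,
    seed = seed,
    n_nodes = g$n_nodes,
    m_edges = nrow(g$edges),
    config = config[setdiff(names(config), c("out_trace", "out_summary"))],
    wall_time_s = round(proc.time()[["elapsed"]] - t0, 3)
  )
  if (method == "cibp") {
    summary$q_immunized <- res$q
    summary$mu <- res$mu
    summary$giant_after <- res$solution$giant
    summary$converged <- res$solution$converged
  } else {
    summary$qc_estimate <- res$qc_estimate
    summary$stop_reason <- res$stop_reason
    summary$n_removed <- length(res$removed)
    if (!is.null(res$nonconverged_steps))
      summary$nonconverged_steps <- res$nonconverged_steps
  }

  if (!is.null(config$out_trace)) {
    if (method == "cibp") {
      write.table(res$history, config$out_trace, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else {
      write_trace(res, config$out_trace, reinsertion = rein)
    }
  }
  if (!is.null(config$out_summary))
    jsonlite::write_json(summary, config$out_summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(list(result = res, reinsertion = rein, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
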