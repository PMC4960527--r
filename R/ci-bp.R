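#' SIR cavity probabilities
#'
#' Self-consistent cavity messages of the Susceptible-Infected-Recovered
#' outbreak on a locally tree-like network with an immunized set. With
#' `occupied[k]` the indicator that node k is present (not immunized), the
#' message from i to j is
#' \deqn{\nu_{i\to j} = (1-\gamma) \prod_{k \in \partial i \setminus j}
#' \left[1 - \beta\, n_k (1 - \nu_{k \to i})\right],}
#' the probability that i ends susceptible when j is absent; \eqn{\gamma} is
#' the initial infection probability, \eqn{\beta} the transmission
#' probability. Immunized neighbors contribute a factor of 1 (they never
#' transmit). The node marginal \eqn{\nu_i} takes the product over all
#' neighbors. The damped update preserves \eqn{\nu \in [0,1]} analytically;
#' no clipping is applied.
#'
#' @param graph a [ci_graph()]
#' @param occupied logical vector, `TRUE` = present / not immunized
#' @param beta transmission probability in `[0, 1]`
#' @param gamma initial infection probability in `[0, 1]`
#' @param damping weight kept on the old message per sweep
#' @param tol max-change convergence tolerance
#' @param max_sweeps sweep budget; non-convergence is flagged
#' @param nu_init optional warm start (length 2M, [directed_edge_index()]
#'   order)
#' @return list with `nu` (2M cavity messages), `nu_node` (marginals),
#'   `converged`, `sweeps`.
#' @export
sir_cavity <- function(graph, occupied = graph$present, beta, gamma,
                       damping = 0.5, tol = 1e-8, max_sweeps = 2000,
                       nu_init = NULL) {
  stopifnot(inherits(graph, "ci_graph"),
            beta >= 0, beta <= 1, gamma >= 0, gamma <= 1,
            damping >= 0, damping < 1, length(occupied) == graph$n_nodes)
  cpp_sir_nu(graph$n_nodes, graph$edges - 1L, occupied, beta, gamma,
             damping, tol, as.integer(max_sweeps),
             if (is.null(nu_init)) numeric(0) else nu_init)
}

#' Immunization energy
#'
#' The cost functional minimized by the collective immunization algorithm:
#' expected outbreak size plus a chemical potential \eqn{\mu} per immunized
#' node,
#' \deqn{E = \sum_i n_i (1 - \nu_i) + \mu \sum_i (1 - n_i),}
#' with \eqn{\nu_i} the converged susceptibility marginal of [sir_cavity()]
#' for the configuration `occupied`. \eqn{\mu} tunes the immunized fraction.
#'
#' @inheritParams sir_cavity
#' @param mu chemical potential (cost per immunized node)
#' @param nu optional precomputed [sir_cavity()] result for `occupied`
#' @return scalar energy
#' @examples
#' g <- generate_rrg(10, 3, seed = 1)
#' sir_energy(g, rep(FALSE, 10), beta = 1, gamma = 0.1, mu = 0.3)  # mu * N
#' @export
sir_energy <- function(graph, occupied, beta, gamma, mu, nu = NULL) {
  stopifnot(inherits(graph, "ci_graph"))
  if (is.null(nu))
    nu <- sir_cavity(graph, occupied, beta, gamma)
  occ <- as.numeric(occupied)
  sum(occ * (1 - nu$nu_node)) + mu * sum(1 - occ)
}

#' Min-sum field equations for the immunization energy
#'
#' Message-passing minimization of [sir_energy()] with the cavity messages
#' frozen: each node carries one factor coupling its occupation to its
#' neighbors' through the outbreak term. Messages are scalar fields
#' (cost of being present minus cost of being immunized); the node field
#' \eqn{h_i} is the log-likelihood-ratio analogue assembled from the
#' incoming messages plus the \eqn{\mu} term, and the spin decision is
#' \eqn{\sigma_i = \mathrm{sign}(h_i)} with sign(0) = -1 (keep), where
#' \eqn{\sigma_i = +1} means node i is removed/immunized. If the damped
#' iteration does not converge within `max_sweeps`, reinforcement takes
#' over: a self-field of strength `reinforce_rate * t`, aligned with each
#' node's current field, grows until the decision pattern freezes.
#'
#' @inheritParams sir_energy
#' @param nu converged cavity messages (the `nu` element of [sir_cavity()])
#' @param damping,tol,max_sweeps iteration controls
#' @param reinforce_rate growth rate of the reinforcement self-field
#' @param warm optional previous result to warm-start the fields from
#' @return list with `h_edge`, `h_self`, `h_node`, `sigma` (+1 = immunize),
#'   `converged`, `reinforced`, `sweeps`.
#' @export
bp_fields <- function(graph, nu, beta, gamma, mu, damping = 0.5, tol = 1e-6,
                      max_sweeps = 2000, reinforce_rate = 1e-3, warm = NULL) {
  stopifnot(inherits(graph, "ci_graph"))
  cpp_bp_fields(graph$n_nodes, graph$edges - 1L, nu, beta, gamma, mu,
                damping, tol, as.integer(max_sweeps), reinforce_rate,
                if (is.null(warm)) numeric(0) else warm$h_edge,
                if (is.null(warm)) numeric(0) else warm$h_self)
}

#' Collective immunization by belief propagation (CI_BP)
#'
#' The full iterative loop for one value of the chemical potential:
#' initialize the spins and fields at random; iterate the cavity equations
#' to convergence for the current immunized set; iterate the field
#' equations; update the node fields and spins; repeat until the fields
#' \eqn{\{h_i\}} have converged, with reinforcement forcing convergence.
#' The returned configuration immunizes the nodes with \eqn{\sigma_i = +1}.
#' Optimal percolation is recovered in the limits \eqn{\gamma = 1/N \to 0},
#' \eqn{\beta \to 1}: the best immunizers are the nodes whose removal
#' optimally destroys the giant component.
#'
#' @inheritParams bp_fields
#' @param mu chemical potential fixing the immunized fraction
#' @param seed seed for the random initialization of spins and fields
#' @param method `"reinforce"` (default): sum-product field equations at
#'   inverse temperature `30/gamma`, with beliefs (soft occupations) feeding
#'   back into the cavity equations and an always-on reinforcement
#'   self-field of strength `reinforce_rate * gamma * t` polarizing the
#'   system to a hard configuration -- the scheme that tracks coordinated
#'   solutions in the percolation limit. `"alternate"`: hard min-sum
#'   alternation (freeze the cavity messages, minimize, re-threshold the
#'   spins one-shot), reinforcement only as non-convergence fallback.
#' @param invT inverse temperature of the sum-product fields
#'   (`"reinforce"` only); default `30/gamma`, with the `1/gamma` scale making
#'   fields commensurate with expected cluster sizes.
#' @param damping_h weight kept on the old field messages per sweep;
#'   defaults to 0.85 for `"reinforce"`, 0.5 for `"alternate"`.
#' @param max_outer cap on outer iterations (`"alternate"`) or
#'   reinforcement rounds (`"reinforce"`; default 20000)
#' @param tol_outer convergence tolerance on the node fields across outer
#'   iterations (`"alternate"`)
#' @param tol_nu,max_sweeps_nu cavity iteration controls
#' @param tol_h,max_sweeps_h field iteration controls (`"alternate"`)
#' @param polish after the reinforced run, perform one hard alternation
#'   pass seeded from the polarized spins and keep whichever configuration
#'   has the lower exact energy (default `TRUE`; `"reinforce"` only)
#' @return list with `immunized` (node ids), `occupied`, `sigma`, `h_node`,
#'   `nu_node`, `giant` / `second` (components of the occupied subgraph),
#'   and convergence diagnostics (including `polished`: whether the hard
#'   pass improved the energy).
#' @examples
#' g <- generate_rrg(100, 3, seed = 5)
#' s <- cibp_solve(g, beta = 1, gamma = 1 / 100, mu = 0.01, seed = 1)
#' length(s$immunized) / 100
#' @export
cibp_solve <- function(graph, beta, gamma, mu, seed = NULL,
                       method = c("reinforce", "alternate"),
                       damping = 0.5, damping_h = NULL, invT = NULL,
                       tol_nu = 1e-8, max_sweeps_nu = NULL,
                       tol_h = 1e-6, max_sweeps_h = 300,
                       reinforce_rate = 1e-3, max_outer = NULL,
                       tol_outer = 1e-4, polish = TRUE) {
  stopifnot(inherits(graph, "ci_graph"),
            beta >= 0, beta <= 1, gamma > 0, gamma <= 1)
  method <- match.arg(method)
  n <- graph$n_nodes
  m2 <- 2 * nrow(graph$edges)
  if (method == "reinforce") {
    if (is.null(invT)) invT <- 30 / gamma
    if (is.null(damping_h)) damping_h <- 0.85
    if (is.null(max_outer)) max_outer <- 20000
    if (is.null(max_sweeps_nu)) max_sweeps_nu <- 10
    init <- with_seed(seed, list(
      b = runif(n, 0.45, 0.55),
      uf_edge = runif(m2, -0.1, 0.1) * gamma,
      uf_self = runif(n, -0.1, 0.1) * gamma
    ))
    r <- cpp_cibp_soft(n, graph$edges - 1L, beta, gamma, mu, invT,
                       damping, tol_nu, as.integer(max_sweeps_nu),
                       damping_h, reinforce_rate * gamma,
                       as.integer(max_outer), 10L,
                       init$b, init$uf_edge, init$uf_self)
    r$polished <- FALSE
    if (isTRUE(polish)) {
      e1 <- sir_energy(graph, r$occupied, beta, gamma, mu)
      h <- cpp_cibp_solve(n, graph$edges - 1L, beta, gamma, mu,
                          damping, tol_nu, 500L,
                          0.5, tol_h, as.integer(max_sweeps_h),
                          reinforce_rate, 10L, tol_outer,
                          r$sigma, numeric(0), numeric(0))
      e2 <- sir_energy(graph, h$occupied, beta, gamma, mu)
      if (e2 < e1 - 1e-12) {
        keep <- r[c("rounds", "converged")]
        r <- h
        r$rounds <- keep$rounds
        r$converged <- keep$converged
        r$polished <- TRUE
      }
    }
  } else {
    if (is.null(damping_h)) damping_h <- 0.5
    if (is.null(max_outer)) max_outer <- 50
    if (is.null(max_sweeps_nu)) max_sweeps_nu <- 2000
    init <- with_seed(seed, list(
      sigma = sample(c(-1L, 1L), n, replace = TRUE),
      uf_edge = runif(m2, -0.1, 0.1),
      uf_self = runif(n, -0.1, 0.1)
    ))
    r <- cpp_cibp_solve(n, graph$edges - 1L, beta, gamma, mu,
                        damping, tol_nu, as.integer(max_sweeps_nu),
                        damping_h, tol_h, as.integer(max_sweeps_h),
                        reinforce_rate, as.integer(max_outer), tol_outer,
                        init$sigma, init$uf_edge, init$uf_self)
  }
  r$method <- method
  r$immunized <- which(!r$occupied)
  r
}

#' Minimal immunization fraction by bisection on the chemical potential
#'
#' Percolation-mode wrapper around [cibp_solve()]: with \eqn{\beta \to 1}
#' and \eqn{\gamma = 1/N}, bisect \eqn{\mu} for the largest value (hence the
#' smallest immunized fraction) whose residual giant component among
#' occupied nodes does not exceed `giant_target` nodes -- the non-extensive
#' scale `2 log N` by default.
#'
#' @inheritParams cibp_solve
#' @param beta transmission probability; the default stays marginally below
#'   1 to avoid degenerate products in the percolation limit
#' @param gamma initial infection probability; default `1/N`
#' @param bisect_steps number of bisection steps between `mu_lo` and `mu_hi`
#' @param mu_lo,mu_hi bisection bracket
#' @param giant_target residual giant size (in nodes) accepted as "no giant
#'   component"
#' @param ... passed on to [cibp_solve()]
#' @return list with `q` (smallest feasible immunized fraction), `mu`,
#'   `immunized`, `solution` (the accepted [cibp_solve()] result) and
#'   `history` (one row per bisection step).
#' @export
cibp_percolation <- function(graph, seed = NULL, beta = 1 - 1e-12,
                             gamma = NULL, bisect_steps = 20,
                             mu_lo = 0, mu_hi = 1, giant_target = NULL, ...) {
  stopifnot(inherits(graph, "ci_graph"))
  n <- graph$n_nodes
  if (is.null(gamma)) gamma <- 1 / n
  if (is.null(giant_target)) giant_target <- ceiling(2 * log(n))
  best <- NULL
  hist <- data.frame()
  lo <- mu_lo
  hi <- mu_hi
  for (s in seq_len(bisect_steps)) {
    mid <- (lo + hi) / 2
    sol <- cibp_solve(graph, beta = beta, gamma = gamma, mu = mid,
                      seed = seed, ...)
    q <- length(sol$immunized) / n
    feasible <- sol$giant <= giant_target
    hist <- rbind(hist, data.frame(step = s, mu = mid, q = q,
                                   giant = sol$giant,
                                   feasible = feasible,
                                   converged = sol$converged))
    if (feasible) {
      if (is.null(best) || q < best$q) best <- list(q = q, mu = mid, sol = sol)
      lo <- mid   # fewer removals might still work: raise mu
    } else {
      hi <- mid
    }
  }
  if (is.null(best)) {
    # mu_lo itself as last resort (immunization nearly free)
    sol <- cibp_solve(graph, beta = beta, gamma = gamma, mu = mu_lo,
                      seed = seed, ...)
    best <- list(q = length(sol$immunized) / n, mu = mu_lo, sol = sol)
  }
  list(q = best$q, mu = best$mu, immunized = best$sol$immunized,
       solution = best$sol, history = hist)
}
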