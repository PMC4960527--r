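---
title: "Optimal percolation with Collective Influence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal percolation with Collective Influence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciperc)
```

## The problem

The most influential nodes of a network are, by the optimal-percolation
view, the minimal set whose removal fragments the network into
non-extensive pieces: driving the giant component $G$ to zero with the
fewest removals $q_c N$. The same set answers the dual question of optimal
immunization: vaccinating it denies an epidemic its percolating cluster.
Exhaustive search is hopeless (the problem is NP-hard), so this package
implements a family of increasingly global, increasingly expensive
heuristics on top of one graph container:

* `ci_attack()` — the adaptive **Collective Influence** attack, near-linear
  time via an indexed max-heap;
* `hda_attack()` — the high-degree-adaptive baseline (the $\ell = 0$
  analogue of CI);
* `reinsert()` — greedy reinsertion, improving $G(q)$ at budgets below
  $q_c$;
* `ci_p_attack()` — **CI propagation**: non-backtracking message passing,
  the $\ell \to \infty$ limit of CI;
* `cibp_solve()` / `cibp_percolation()` — **collective immunization**:
  belief propagation on the SIR cost function, whose $\gamma \to 0$,
  $\beta \to 1$ limit is optimal percolation.

## Collective Influence and its linear-time processing

The CI score of node $i$ at radius $\ell$ is
$$\mathrm{CI}_\ell(i) = (k_i - 1) \sum_{j \in \partial B(i,\ell)} (k_j - 1),$$
where $\partial B(i,\ell)$ is the shortest-path frontier of the ball around
$i$ and all degrees are live (masked) degrees. The attack repeatedly removes
the current argmax. Three ingredients keep the cost near $O(N \log N)$:

1. **Indexed max-heap.** Scores live in a binary max-heap with a
   node-to-slot map, built bottom-up in $O(N)$. A removal pops the root,
   promotes the rightmost leaf and sifts it down.
2. **Localized updates.** Removing $i$ changes CI only inside
   $B(i, \ell+1)$. Nodes at distance $\le \ell$ are recomputed by BFS; a
   node $j$ on the outer shell loses $(k_j - 1)$ for every neighbor of $i$
   that lies on $j$'s own $\ell$-frontier. On a tree that multiplicity is
   one — the classic "$k - 1$ shortcut" — and counting it explicitly makes
   the update exact on loopy graphs at every radius, which is what the
   oracle-equivalence tests assert. Each single update is followed by a
   local re-heapification of the touched slot (sift-down for decreases,
   with a sift-up fallback because on loopy graphs an inner-shell
   recomputation can raise a score).
3. **Eigenvalue stopping rule.** Instead of recomputing components per
   removal, the attack tracks
   $$\lambda(\ell; q) = \left[\frac{\sum_i \mathrm{CI}_\ell(i)}
   {N \langle k \rangle}\right]^{1/(\ell+1)},$$
   with $N$ and $\langle k \rangle$ frozen at $q = 0$, an estimate of the
   largest eigenvalue of the non-backtracking (NB) matrix. At $q=0$ on
   tree-like graphs it equals $\kappa - 1 = \langle k^2\rangle/\langle
   k\rangle - 1$ (exactly $k - 1$ at $\ell = 1$ on a $k$-regular graph);
   the network is dismantled when it reaches 1. The sum of live scores is
   maintained incrementally, so the monitor is free; component sizes are
   still recorded, but only every `max(1, N/1000)` removals — fine enough
   to resolve the percolation point to $\Delta q = 10^{-3}$.

Ties among equal scores are broken by heap position by default;
`deterministic_ties = TRUE` ranks equal scores by smallest node id, which
is what makes the removal sequence comparable, node for node, with a naive
$O(N^2)$ recompute-everything reference.

$\ell$ defaults to 3: the ball must stay small compared to the graph
(radius well below the diameter), and on the sparse graphs in scope
$\ell \in \{3,\dots,5\}$ changes $q_c$ only marginally while inflating the
update cost geometrically.

HDA uses the same heap machinery with the live degree as score. Because it
has no eigenvalue monitor, "the giant component is zero" needs an explicit
scale: we stop when the giant, checked on the thinned grid, has at most
$\max(2, \lceil 2 \log N \rceil)$ nodes — the non-extensive cluster scale
of a random graph, and the same scale used for the immunization target
below. Literal zero is unreachable while any edge survives, and any
$O(\log N)$ choice moves $q_c$ by less than the grid resolution.

## Reinsertion

Below the percolation point the attack curve can be improved by running the
attack past $q_c$ and then adding nodes back: each batch (0.2 % of $N$ by
default, at least one node) reinserts the still-removed nodes that would
join the *fewest distinct clusters* among their present neighbors —
cluster sizes are deliberately ignored. Membership is tracked by union-find
and candidate counts are recomputed per batch; at desk scale the simple
pass is unambiguous and cheap. Ties go to the smallest node id for
determinism. Halving the batch fraction leaves the curves unchanged within
1 % of $N$, which the test suite checks.

## CI propagation

The NB operator acts on the $2M$ directed edges; its left and right
eigenvectors are iterated as messages
$$L_{i\to j} \gets \sum_{k\in\partial i\setminus j} L_{k\to i}, \qquad
R_{i\to j} \gets \sum_{k\in\partial j\setminus i} R_{j\to k},$$
normalized to unit $\ell_1$ sum per sweep so the pre-normalization growth
factor estimates $\lambda_{\max}$ (averaged over the last 10 sweeps to damp
even-odd oscillation on bipartite-like structures). Exact limits pin the
implementation down: trees give 0 (nilpotent operator), a single cycle 1,
a $k$-regular graph $k-1$; on small graphs the estimate is checked against
a dense eigendecomposition of the explicitly built $2M \times 2M$ matrix.

Near-degenerate or imprimitive (cycle-dominated) spectra make plain power
iteration cycle or stall; `iterate_messages(shift = 1)` iterates
$B + I$ instead — same eigenvectors, aperiodic dynamics — and corrects
the growth factor back, which is how the dense cross-checks reach
$10^{-6}$ relative accuracy.

First-order perturbation of $\lambda_{\max}$ under removal of $i$ involves
exactly the NB edge pairs through $i$, giving the score
$$\mathrm{CI}_P(i) = \sum_{j,k\in\partial i,\; j\ne k} L_{j\to i} R_{i\to k},$$
with the node-independent left-right overlap dropped (only the argmax
matters). The attack alternates convergence (warm-started, tolerance
$10^{-7}$ on the $\ell_1$ change, non-convergence flagged rather than
fatal) with removal of the argmax, until $\lambda_{\max} \le 1$. Because
one removal in $N$ barely perturbs the warm-started messages, the attack
spends at most `relax_sweeps` (20) sweeps per removal while
$\lambda_{\max} > 1.05$, amortizing convergence across steps, and switches
to full tolerance-based convergence (budget 200 sweeps per removal) near
the stopping point, where the eigenvalue estimate matters; the estimate
only needs to track the $\sim 1/N$ per-removal decline of $\lambda$, which
these budgets resolve comfortably. Uniform initialization lies in the cone
of the dominant eigenvector of a non-negative operator, so no randomness
is needed; a seed argument exists for randomized restarts only.

One finite-size caveat, visible in any desk-scale run: $\lambda_{\max}
\le 1$ certifies the destruction of the extensive 2-core, not of
connectivity — the remainder is forest-like and can still contain one
large tree. The removed fraction at the crossing is the quantity the
stopping rule defines and is what the attack reports.

## Collective immunization

In the SIR model with initial infection probability $\gamma$ and
transmission probability $\beta$, the probability that node $i$ ends
susceptible, with neighbor $j$ absent, satisfies the cavity equation
$$\nu_{i\to j} = (1-\gamma) \prod_{k\in\partial i\setminus j}
\left[1 - \beta\, n_k (1 - \nu_{k\to i})\right],$$
where $n_k \in \{0,1\}$ marks immunization ($n_k = 0$); immunized
neighbors contribute a factor 1. The algorithm minimizes
$$E = \sum_i n_i (1 - \nu_i) + \mu \sum_i (1 - n_i),$$
outbreak size plus a chemical potential $\mu$ per vaccine. In the
percolation limit ($\beta \to 1$, $\gamma = 1/N$) the outbreak term
reduces to $\gamma \sum_{\text{clusters}} s^2$, so minimizing $E$ is
dismantling with a per-removal cost.

The published form of the field equations for this energy is not available
to us in closed form, so the package reconstructs them and isolates the
algebra behind one module boundary (`bp_fields()`, `cibp_solve()`), to be
swapped if a different parameterization is preferred. Two schemes are
provided:

* **`method = "alternate"`** — the literal hard loop: freeze the converged
  $\nu$, min-sum-minimize the resulting one-factor-per-node energy
  (messages are scalar fields; the node field $h_i$ is the log-likelihood
  ratio; $\sigma_i = \mathrm{sign}(h_i)$ with sign(0) = keep), re-threshold
  all spins, recompute $\nu$, repeat. Factor messages marginalize exactly
  over neighbor configurations (enumeration capped at 12 strongest-coupled
  neighbors; beyond the cap the rest are folded at their unary optimum).
  Reinforcement is the non-convergence fallback. This scheme is exact-ish
  on small instances but has two trivial attractors in the percolation
  limit (remove-a-cover and keep-all) between which the one-shot
  re-thresholding oscillates.
* **`method = "reinforce"`** (default) — the smooth variant that the
  reinforcement technique presupposes: the same factor messages run as
  sum-product at inverse temperature $30/\gamma$ (the $1/\gamma$ scale
  makes fields commensurate with expected cluster sizes; the extra factor
  sharpens decisions on small dense instances without affecting the
  percolation regime), occupations enter the cavity equations as beliefs
  $b_i \in [0,1]$, and an always-on self-field of strength
  $\texttt{reinforce\_rate}\cdot\gamma\cdot t$, aligned with each node's
  current field, polarizes the system. Iteration stops when the sign
  pattern is stable for 10 rounds; the hard configuration is read off at
  the end. Per round the cavity messages get a short warm-started refresh
  (10 sweeps) — beliefs move slowly, so tighter per-round convergence buys
  nothing. A final energy-gated polish runs one `"alternate"` pass seeded
  from the polarized spins and keeps whichever configuration has the
  lower exact energy; on small dense instances this recovers most of the
  remaining gap to the exhaustive optimum, while in the percolation
  regime it simply never fires.

Damping is 0.5 on $\nu$ (tolerance $10^{-8}$) and 0.85 on the fields;
`reinforce_rate` defaults to $10^{-3}$ (per round, in units of $\gamma$).
$\beta$ stays at $1 - 10^{-12}$ in percolation mode to avoid degenerate
$0 \cdot \infty$ patterns, and $\gamma = 1/N$ exactly.

`cibp_percolation()` finds the smallest immunized fraction whose residual
giant component is "zero" by bisecting $\mu$ (20 steps in $[0,1]$),
accepting a solution when the giant among occupied nodes has at most
$\lceil 2\log N\rceil$ nodes, and reporting the best (smallest) feasible
fraction encountered. The $2\log N$ operationalization is strict: at desk
scale it demands decycling *plus* cutting the leftover forest into
logarithmic pieces, which costs an extra $O(1/\log N)$ fraction of
removals on top of the asymptotic threshold. The measured fraction on a
random cubic graph therefore sits a few hundredths above the
$N \to \infty$ optimum $1/4$; the gap shrinks with $N$ and with a looser
(e.g. $\sqrt N$) notion of "zero". We report what the strict rule
measures.

## Generators and what the synthetic graphs do (not) show

Experiments run on two generators. `generate_er(n, mean_degree, seed)`
samples $G(n, M)$ with $M = \mathrm{round}(n\langle k\rangle/2)$ distinct
edges, so the mean degree is exact by construction and the degree
distribution is asymptotically Poisson. `generate_rrg(n, k, seed)` is the
pairing model with full restart on collisions — cheap for small $k$, and
the mild non-uniformity of restarting is irrelevant for the observables
used here. Both are bit-reproducible for a fixed seed; all randomness in
the package flows through explicit seed arguments and restores the
caller's RNG state.

These graphs are locally tree-like, which is precisely the regime where
the CI score, the $\lambda$ monitor and the cavity equations are justified.
Passing tests on them demonstrates correctness of the algorithms and of
the tree-ansatz predictions, *not* performance on clustered, heavy-tailed
or modular real networks, where short loops bias all three approximations
and the heap update's non-monotone corrections become more frequent.

## Numerical choices and degenerate inputs

* CI scores are integers stored in doubles, so the incremental
  `ci_sum` is exact; $\lambda$ involves one power per removal.
* A removed or isolated node has CI 0 and degree 0; zero-score pops are
  allowed while $\lambda > 1$, so attacks terminate on any input (a star
  at $\ell = 1$ has $\lambda(0) = 0$ and is never attacked at all).
* Messages on edges incident to removed nodes are pinned to exact zeros;
  power iteration returning an all-zero vector is reported as
  $\lambda_{\max} = 0$ (nilpotent case), not as a division error.
* The $\nu$ update preserves $[0,1]$ analytically — no clipping anywhere.
* Graph input is validated: self-loops, parallel edges and non-integer
  tokens are rejected with the offending line number; arbitrary integer
  labels are mapped to dense internal ids with the mapping kept for
  round-tripping.

## Problem sizes

The shipped tests exercise the study conditions at sizes a single CPU
handles comfortably: oracle equivalence on graphs of 30–70 nodes, dense
NB cross-checks up to $\sim$90 nodes, exhaustive-enumeration immunization
oracles at 8–11 nodes, ER attacks at $N = 10^5$ ($\ell = 5$ for the
stopping-rule consistency check), CI propagation at $N = 10^4$, and the
immunization bisection at $N = 5 \times 10^3$. The acceptance script
re-runs the immunization pipeline end-to-end at $N = 5000$.

## Known limitations

* BP components target sparse graphs: factor marginalization enumerates
  neighbor subsets exactly only up to degree 12.
* `cibp_percolation()` reports the strict-threshold fraction discussed
  above; comparing it to the asymptotic $1/4$ conflates two limits.
* CI propagation is $O(N^2)$ once removals are counted — that is the
  point of the CI/heap implementation, and the package deliberately does
  not try to scale CI_P beyond small networks.
* Directed and weighted graphs, scale-free generators, and loop
  corrections to the tree ansatz are out of scope.
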