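#include "ci_common.h"
#include <cmath>
using namespace Rcpp;

// Left/right non-backtracking messages on the 2M directed edges.
// L_{i->j} <- sum_{k in di\j} L_{k->i};  R_{i->j} <- sum_{k in dj\i} R_{j->k}.
// Per-sweep normalization to unit l1 sum turns the iteration into power
// iteration; the pre-normalization growth factor estimates lambda_max.

struct NBWork {
  std::vector<double> inL, outR, Lnew, Rnew;
  NBWork(int n, int m2)
      : inL(n, 0.0), outR(n, 0.0), Lnew(m2, 0.0), Rnew(m2, 0.0) {}
};

// One sweep; returns growth factors of L and R. Messages on edges with a
// removed endpoint stay exactly zero.
static void nb_sweep(const CSRGraph& g, const std::vector<char>& pres,
                     std::vector<double>& L, std::vector<double>& R,
                     NBWork& w, double& growthL, double& growthR,
                     double& diff, double shift) {
  const int n = g.n;
  for (int i = 0; i < n; ++i) {
    double a = 0.0, b = 0.0;
    if (pres[i]) {
      for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s) {
        a += L[g.eid[s] ^ 1];  // incoming k->i
        b += R[g.eid[s]];      // outgoing i->k
      }
    }
    w.inL[i] = a;
    w.outR[i] = b;
  }
  double sL = 0.0, sR = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s) {
      int j = g.adj[s];
      int d = g.eid[s];  // i -> j
      double lv = 0.0, rv = 0.0;
      if (pres[i] && pres[j]) {
        lv = w.inL[i] - L[d ^ 1] + shift * L[d];
        rv = w.outR[j] - R[d ^ 1] + shift * R[d];
        if (lv < 0.0) lv = 0.0;  // guard rounding; exact arithmetic is >= 0
        if (rv < 0.0) rv = 0.0;
      }
      w.Lnew[d] = lv;
      w.Rnew[d] = rv;
      sL += lv;
      sR += rv;
    }
  }
  growthL = sL;
  growthR = sR;
  diff = 0.0;
  const size_t m2 = L.size();
  if (sL > 0.0)
    for (size_t d = 0; d < m2; ++d) w.Lnew[d] /= sL;
  if (sR > 0.0)
    for (size_t d = 0; d < m2; ++d) w.Rnew[d] /= sR;
  for (size_t d = 0; d < m2; ++d) {
    diff += std::fabs(w.Lnew[d] - L[d]) + std::fabs(w.Rnew[d] - R[d]);
    L[d] = w.Lnew[d];
    R[d] = w.Rnew[d];
  }
}

static void nb_init_uniform(const CSRGraph& g, const std::vector<char>& pres,
                            std::vector<double>& L, std::vector<double>& R) {
  int live = 0;
  for (int i = 0; i < g.n; ++i)
    for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s)
      if (pres[i] && pres[g.adj[s]]) ++live;
  double v = live > 0 ? 1.0 / live : 0.0;
  for (int i = 0; i < g.n; ++i)
    for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s) {
      double x = (pres[i] && pres[g.adj[s]]) ? v : 0.0;
      L[g.eid[s]] = x;
      R[g.eid[s]] = x;
    }
}

// Power-iterate to convergence. lam_max is the mean of the L and R growth
// factors averaged over the last (up to) 10 sweeps, damping the even-odd
// oscillation of bipartite-like structures.
static double nb_converge(const CSRGraph& g, const std::vector<char>& pres,
                          std::vector<double>& L, std::vector<double>& R,
                          NBWork& w, double tol, int max_sweeps,
                          bool& converged, int& sweeps_used,
                          double shift = 0.0) {
  double growthL = 0.0, growthR = 0.0, diff = 0.0;
  std::vector<double> recent;
  recent.reserve(10);
  converged = false;
  int t = 0;
  for (; t < max_sweeps; ++t) {
    nb_sweep(g, pres, L, R, w, growthL, growthR, diff, shift);
    double gmean = 0.5 * (growthL + growthR) - shift;
    if (gmean < 0.0) gmean = 0.0;
    if (recent.size() == 10) recent.erase(recent.begin());
    recent.push_back(gmean);
    if (growthL == 0.0 && growthR == 0.0) {
      // messages died out: nilpotent operator (tree/forest), lambda = 0
      converged = true;
      ++t;
      recent.clear();
      break;
    }
    if (diff < tol) { converged = true; ++t; break; }
  }
  sweeps_used = t;
  if (recent.empty()) return 0.0;
  double s = 0.0;
  for (double v : recent) s += v;
  return s / recent.size();
}

// [[Rcpp::export]]
List cpp_nb_iterate(int n, IntegerMatrix edges, LogicalVector present,
                    NumericVector L0, NumericVector R0, double tol,
                    int max_sweeps, double shift) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<char> pres(present.begin(), present.end());
  int m2 = 2 * g.m;
  std::vector<double> L(m2, 0.0), R(m2, 0.0);
  if (L0.size() == m2 && R0.size() == m2) {
    std::copy(L0.begin(), L0.end(), L.begin());
    std::copy(R0.begin(), R0.end(), R.begin());
    // enforce zeros on dead edges
    for (int i = 0; i < n; ++i)
      for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s)
        if (!pres[i] || !pres[g.adj[s]]) L[g.eid[s]] = R[g.eid[s]] = 0.0;
  } else {
    nb_init_uniform(g, pres, L, R);
  }
  NBWork w(n, m2);
  bool conv;
  int used;
  double lam = nb_converge(g, pres, L, R, w, tol, max_sweeps, conv, used, shift);
  return List::create(_["L"] = NumericVector(L.begin(), L.end()),
                      _["R"] = NumericVector(R.begin(), R.end()),
                      _["lam_max"] = lam, _["converged"] = conv,
                      _["sweeps"] = used);
}

// CI_P(i) = sum_{j,k in di, j != k} L_{j->i} R_{i->k}
//         = (sum_j L_{j->i}) (sum_k R_{i->k}) - sum_j L_{j->i} R_{i->j}.
static double cip_score_one(const CSRGraph& g, const std::vector<double>& L,
                            const std::vector<double>& R, int i) {
  double sL = 0.0, sR = 0.0, cross = 0.0;
  for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s) {
    int d = g.eid[s];
    sL += L[d ^ 1];
    sR += R[d];
    cross += L[d ^ 1] * R[d];
  }
  double v = sL * sR - cross;
  return v < 0.0 ? 0.0 : v;
}

// [[Rcpp::export]]
NumericVector cpp_cip_scores(int n, IntegerMatrix edges, LogicalVector present,
                             NumericVector L0, NumericVector R0) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<double> L(L0.begin(), L0.end()), R(R0.begin(), R0.end());
  NumericVector out(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (present[i]) out[i] = cip_score_one(g, L, R, i);
  return out;
}

// Adaptive CI_P attack: converge messages (warm-started), remove the
// highest-scoring present node, zero its messages, repeat until
// lambda_max <= 1. Ties break to the smallest node id.
// While lambda is safely above 1 the warm-started messages get at most
// relax_sweeps sweeps per removal (convergence is amortized across steps);
// full tolerance-based convergence resumes once lambda approaches 1.
// [[Rcpp::export]]
List cpp_cip_attack(int n, IntegerMatrix edges, LogicalVector present0,
                    double tol, int max_sweeps, int record_every,
                    int relax_sweeps) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<char> pres(present0.begin(), present0.end());
  int m2 = 2 * g.m;
  std::vector<double> L(m2, 0.0), R(m2, 0.0);
  nb_init_uniform(g, pres, L, R);
  NBWork w(n, m2);
  BFSBuf work(n);

  double n0 = 0.0;
  for (int i = 0; i < n; ++i) if (pres[i]) n0 += 1.0;

  std::vector<int> order;
  std::vector<double> qv, lamv;
  std::vector<int> giantv, secondv;
  int removed = 0, nonconv = 0;
  double qc = NA_REAL;
  double lam0 = NA_REAL;

  double lam_prev = R_PosInf;
  for (;;) {
    bool conv;
    int used;
    int budget = (lam_prev > 1.05 && removed > 0 && relax_sweeps > 0)
                     ? std::min(relax_sweeps, max_sweeps)
                     : max_sweeps;
    double lam = nb_converge(g, pres, L, R, w, tol, budget, conv, used);
    if (!conv && budget == max_sweeps) ++nonconv;
    lam_prev = lam;
    if (ISNA(lam0)) lam0 = lam;
    if (lam <= 1.0) {
      qc = removed / n0;
      break;
    }
    // argmax CI_P over present nodes, smallest id on ties
    int best = -1;
    double bestv = -1.0;
    for (int i = 0; i < n; ++i) {
      if (!pres[i]) continue;
      double v = cip_score_one(g, L, R, i);
      if (v > bestv) { bestv = v; best = i; }
    }
    if (best < 0) { qc = removed / n0; break; }
    pres[best] = 0;
    for (int s = g.xadj[best]; s < g.xadj[best + 1]; ++s) {
      L[g.eid[s]] = R[g.eid[s]] = 0.0;
      L[g.eid[s] ^ 1] = R[g.eid[s] ^ 1] = 0.0;
    }
    ++removed;
    order.push_back(best);
    qv.push_back(removed / n0);
    lamv.push_back(lam);  // eigenvalue that justified this removal
    if (removed % record_every == 0) {
      CompStats st = component_stats(g, pres, work);
      giantv.push_back(st.giant);
      secondv.push_back(st.second);
    } else {
      giantv.push_back(NA_INTEGER);
      secondv.push_back(NA_INTEGER);
    }
    if (removed % 256 == 0) Rcpp::checkUserInterrupt();
  }
  CompStats fin = component_stats(g, pres, work);
  if (!giantv.empty()) {
    giantv.back() = fin.giant;
    secondv.back() = fin.second;
  }
  return List::create(
      _["order"] = IntegerVector(order.begin(), order.end()),
      _["q"] = NumericVector(qv.begin(), qv.end()),
      _["lambda"] = NumericVector(lamv.begin(), lamv.end()),
      _["giant"] = IntegerVector(giantv.begin(), giantv.end()),
      _["second"] = IntegerVector(secondv.begin(), secondv.end()),
      _["qc_estimate"] = qc,
      _["lambda0"] = lam0,
      _["nonconverged_steps"] = nonconv,
      _["giant_final"] = fin.giant,
      _["n0"] = n0,
      _["present"] = LogicalVector(pres.begin(), pres.end()));
}
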