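#include "ci_common.h"
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Cavity probabilities for the SIR outbreak:
//   nu_{i->j} = (1-gamma) * prod_{k in di\j} [1 - beta n_k (1 - nu_{k->i})]
// with n_k = 1 for present (non-immunized) nodes. Immunized neighbors
// contribute a factor of 1 (they cannot transmit). Damped fixed-point
// iteration; the update preserves nu in [0,1] analytically.
static bool nu_iterate(const CSRGraph& g, const std::vector<char>& occ,
                       double beta, double gamma, double damping, double tol,
                       int max_sweeps, std::vector<double>& nu,
                       std::vector<double>& nu_node, int& sweeps) {
  const int n = g.n;
  std::vector<double> w;       // per-slot factors of the current node
  std::vector<double> suf;     // suffix products
  bool conv = false;
  int t = 0;
  for (; t < max_sweeps; ++t) {
    double maxd = 0.0;
    for (int i = 0; i < n; ++i) {
      int b = g.xadj[i], e = g.xadj[i + 1], di = e - b;
      if (di == 0) continue;
      w.resize(di);
      suf.resize(di + 1);
      for (int s = 0; s < di; ++s) {
        int k = g.adj[b + s];
        double nk = occ[k] ? 1.0 : 0.0;
        w[s] = 1.0 - beta * nk * (1.0 - nu[g.eid[b + s] ^ 1]);
      }
      suf[di] = 1.0;
      for (int s = di - 1; s >= 0; --s) suf[s] = suf[s + 1] * w[s];
      double pre = 1.0;
      for (int s = 0; s < di; ++s) {
        double prod_excl = pre * suf[s + 1];
        double target = (1.0 - gamma) * prod_excl;
        int d = g.eid[b + s];
        double nv = damping * nu[d] + (1.0 - damping) * target;
        double dd = std::fabs(nv - nu[d]);
        if (dd > maxd) maxd = dd;
        nu[d] = nv;
        pre *= w[s];
      }
    }
    if (maxd < tol) { conv = true; ++t; break; }
  }
  sweeps = t;
  for (int i = 0; i < n; ++i) {
    double p = 1.0;
    for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s) {
      int k = g.adj[s];
      double nk = occ[k] ? 1.0 : 0.0;
      p *= 1.0 - beta * nk * (1.0 - nu[g.eid[s] ^ 1]);
    }
    nu_node[i] = (1.0 - gamma) * p;
  }
  return conv;
}

// [[Rcpp::export]]
List cpp_sir_nu(int n, IntegerMatrix edges, LogicalVector occupied,
                double beta, double gamma, double damping, double tol,
                int max_sweeps, NumericVector nu0) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<char> occ(occupied.begin(), occupied.end());
  int m2 = 2 * g.m;
  std::vector<double> nu(m2, 1.0 - gamma);
  if (nu0.size() == m2) std::copy(nu0.begin(), nu0.end(), nu.begin());
  std::vector<double> nu_node(n, 0.0);
  int sweeps = 0;
  bool conv = nu_iterate(g, occ, beta, gamma, damping, tol, max_sweeps,
                         nu, nu_node, sweeps);
  return List::create(_["nu"] = NumericVector(nu.begin(), nu.end()),
                      _["nu_node"] = NumericVector(nu_node.begin(), nu_node.end()),
                      _["converged"] = conv, _["sweeps"] = sweeps);
}

// ---- Min-sum field equations -------------------------------------------
//
// The immunization energy E = sum_i n_i (1 - nu_i) + mu sum_i (1 - n_i)
// becomes, with the cavity messages frozen, a factor per node i coupling
// (n_i, n_{di}):
//   phi_i = mu                                      if n_i = 0
//   phi_i = 1 - (1-gamma) prod_{k} c_k(n_k)         if n_i = 1,
// with c_k(0) = 1 and c_k(1) = 1 - beta (1 - nu_{k->i}).
// Min-sum messages are stored as scalar fields u = cost(n=1) - cost(n=0):
// uf_self[i] is the message from factor i to its own variable, uf_edge on
// directed edge (i->j) is the message from factor i to variable j, and
// h_i = uf_self[i] + sum_{k in di} uf_edge[k->i] + reinforcement field.
// sigma_i = sign(h_i) with sign(0) = -1; sigma = +1 means immunized.

static const int ENUM_CAP = 12;  // exact subset enumeration up to this many
                                 // neighbors; beyond it the weakest-coupled
                                 // neighbors are folded at their unary optimum

struct MinSumState {
  std::vector<double> uf_edge;  // 2M
  std::vector<double> uf_self;  // n
  std::vector<double> rein;     // n
  std::vector<double> h;        // n
};

static void recompute_h(const CSRGraph& g, MinSumState& st) {
  for (int i = 0; i < g.n; ++i) {
    double hh = st.uf_self[i] + st.rein[i];
    for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s)
      hh += st.uf_edge[g.eid[s] ^ 1];  // message from factor adj[s] to i
    st.h[i] = hh;
  }
}

// One Gauss-Seidel sweep with damping; returns max field change.
static double minsum_sweep(const CSRGraph& g, const std::vector<double>& nu,
                           double beta, double gamma, double mu,
                           double damping, MinSumState& st) {
  double maxd = 0.0;
  std::vector<int> en;            // enumerated slots
  std::vector<double> ntv, vv;
  for (int i = 0; i < g.n; ++i) {
    int b = g.xadj[i], e = g.xadj[i + 1], di = e - b;
    ntv.resize(di);
    vv.resize(di);
    double sum_min = 0.0;
    for (int s = 0; s < di; ++s) {
      int k = g.adj[b + s];
      ntv[s] = 1.0 - beta * (1.0 - nu[g.eid[b + s] ^ 1]);
      vv[s] = st.h[k] - st.uf_edge[g.eid[b + s]];
      sum_min += std::min(0.0, vv[s]);
    }
    // pick enumerated slots: strongest couplings first
    en.clear();
    if (di <= ENUM_CAP) {
      for (int s = 0; s < di; ++s) en.push_back(s);
    } else {
      std::vector<int> idx(di);
      for (int s = 0; s < di; ++s) idx[s] = s;
      std::partial_sort(idx.begin(), idx.begin() + ENUM_CAP, idx.end(),
                        [&](int a, int c) { return ntv[a] < ntv[c]; });
      en.assign(idx.begin(), idx.begin() + ENUM_CAP);
      std::sort(en.begin(), en.end());
    }
    std::vector<char> is_en(di, 0);
    for (int s : en) is_en[s] = 1;
    // folded slots contribute fixed terms
    double foldW = 0.0, foldP = 1.0;
    for (int s = 0; s < di; ++s) {
      if (is_en[s]) continue;
      if (vv[s] < 0.0) { foldW += vv[s]; foldP *= ntv[s]; }
    }
    double v_i = st.h[i] - st.uf_self[i];

    // message to own variable
    {
      double A0 = mu + sum_min;
      double A1 = R_PosInf;
      int ne = (int)en.size();
      for (int mask = 0; mask < (1 << ne); ++mask) {
        double P = foldP, W = foldW;
        for (int t2 = 0; t2 < ne; ++t2)
          if (mask & (1 << t2)) { P *= ntv[en[t2]]; W += vv[en[t2]]; }
        double c1 = 1.0 - (1.0 - gamma) * P + W;
        if (c1 < A1) A1 = c1;
      }
      double nv = damping * st.uf_self[i] + (1.0 - damping) * (A1 - A0);
      double dd = std::fabs(nv - st.uf_self[i]);
      if (dd > maxd) maxd = dd;
      st.h[i] += nv - st.uf_self[i];
      st.uf_self[i] = nv;
    }
    // messages to each neighbor
    for (int sj = 0; sj < di; ++sj) {
      int j = g.adj[b + sj];
      int dj = g.eid[b + sj];  // directed i->j
      double fW = foldW, fP = foldP;
      if (!is_en[sj] && vv[sj] < 0.0) { fW -= vv[sj]; fP /= ntv[sj]; }
      double b_ni0 = mu + sum_min - std::min(0.0, vv[sj]);
      double m1 = R_PosInf;  // min_S [ W(S) - (1-gamma) P(S) ], c factored later
      double m1c = R_PosInf; // same with the extra factor nt_j
      int ne = 0;
      static thread_local std::vector<int> ej;
      ej.clear();
      for (int s : en) if (s != sj) ej.push_back(s);
      ne = (int)ej.size();
      double ntj = ntv[sj];
      for (int mask = 0; mask < (1 << ne); ++mask) {
        double P = fP, W = fW;
        for (int t2 = 0; t2 < ne; ++t2)
          if (mask & (1 << t2)) { P *= ntv[ej[t2]]; W += vv[ej[t2]]; }
        double c0 = 1.0 - (1.0 - gamma) * P + W;
        double c1 = 1.0 - (1.0 - gamma) * ntj * P + W;
        if (c0 < m1) m1 = c0;
        if (c1 < m1c) m1c = c1;
      }
      double B0 = std::min(b_ni0, v_i + m1);
      double B1 = std::min(b_ni0, v_i + m1c);
      double nv = damping * st.uf_edge[dj] + (1.0 - damping) * (B1 - B0);
      double dd = std::fabs(nv - st.uf_edge[dj]);
      if (dd > maxd) maxd = dd;
      st.h[j] += nv - st.uf_edge[dj];
      st.uf_edge[dj] = nv;
    }
  }
  return maxd;
}

static IntegerVector sigma_of(const std::vector<double>& h) {
  IntegerVector s(h.size());
  for (size_t i = 0; i < h.size(); ++i) s[i] = h[i] > 0.0 ? 1 : -1;
  return s;
}

// Iterate the field equations; on non-convergence apply reinforcement:
// a self-field of strength reinforce_rate * t aligned with each node's
// current field, growing until the decision pattern freezes.
static List minsum_converge(const CSRGraph& g, const std::vector<double>& nu,
                            double beta, double gamma, double mu,
                            double damping, double tol, int max_sweeps,
                            double reinforce_rate, MinSumState& st) {
  recompute_h(g, st);
  bool conv = false;
  int t = 0;
  for (; t < max_sweeps; ++t) {
    double d = minsum_sweep(g, nu, beta, gamma, mu, damping, st);
    if (d < tol) { conv = true; ++t; break; }
  }
  bool reinforced = false;
  if (!conv) {
    reinforced = true;
    IntegerVector prev = sigma_of(st.h);
    int stable = 0;
    for (int tr = 1; tr <= max_sweeps; ++tr) {
      for (int i = 0; i < g.n; ++i) {
        double sg = st.h[i] > 0.0 ? 1.0 : (st.h[i] < 0.0 ? -1.0 : 0.0);
        double add = reinforce_rate * tr * sg;
        st.rein[i] += add;
        st.h[i] += add;
      }
      minsum_sweep(g, nu, beta, gamma, mu, damping, st);
      IntegerVector cur = sigma_of(st.h);
      bool same = true;
      for (int i = 0; i < g.n; ++i) if (cur[i] != prev[i]) { same = false; break; }
      stable = same ? stable + 1 : 0;
      prev = cur;
      ++t;
      if (stable >= 10) { conv = true; break; }
    }
  }
  return List::create(_["converged"] = conv, _["reinforced"] = reinforced,
                      _["sweeps"] = t);
}

// ---- Soft (sum-product) solver with reinforcement ----------------------
//
// The smooth route to a polarized solution: occupations enter the cavity
// equations as beliefs b_i = P(n_i = 1) in [0,1]; the field equations are
// run as sum-product at the natural inverse temperature 1/gamma (outbreak
// energies are O(gamma * cluster size), so fields are measured in cluster
// size units); and a reinforcement self-field of strength reinforce_rate*t
// aligned with the current field polarizes the beliefs until the decision
// pattern freezes. The hard configuration is read off at the end.

// soft-min at inverse temperature invT (log-sum-exp in energy units)
static inline double softmin2(double a, double b, double invT) {
  double m = std::min(a, b);
  return m - std::log(std::exp(-invT * (a - m)) + std::exp(-invT * (b - m))) / invT;
}

// nu iteration with soft occupations
static void nu_iterate_soft(const CSRGraph& g, const std::vector<double>& b,
                            double beta, double gamma, double damping,
                            double tol, int max_sweeps,
                            std::vector<double>& nu) {
  std::vector<double> w, suf;
  for (int t = 0; t < max_sweeps; ++t) {
    double maxd = 0.0;
    for (int i = 0; i < g.n; ++i) {
      int bg = g.xadj[i], e = g.xadj[i + 1], di = e - bg;
      if (di == 0) continue;
      w.resize(di);
      suf.resize(di + 1);
      for (int s = 0; s < di; ++s)
        w[s] = 1.0 - beta * b[g.adj[bg + s]] * (1.0 - nu[g.eid[bg + s] ^ 1]);
      suf[di] = 1.0;
      for (int s = di - 1; s >= 0; --s) suf[s] = suf[s + 1] * w[s];
      double pre = 1.0;
      for (int s = 0; s < di; ++s) {
        double target = (1.0 - gamma) * pre * suf[s + 1];
        int d = g.eid[bg + s];
        double nv = damping * nu[d] + (1.0 - damping) * target;
        maxd = std::max(maxd, std::fabs(nv - nu[d]));
        nu[d] = nv;
        pre *= w[s];
      }
    }
    if (maxd < tol) break;
  }
}

// One damped sum-product sweep of the field equations at inverse
// temperature invT; returns max field change.
static double sp_sweep(const CSRGraph& g, const std::vector<double>& nu,
                       double beta, double gamma, double mu, double invT,
                       double damping, MinSumState& st) {
  double maxd = 0.0;
  std::vector<int> en;
  std::vector<double> ntv, vv;
  for (int i = 0; i < g.n; ++i) {
    int b = g.xadj[i], e = g.xadj[i + 1], di = e - b;
    ntv.resize(di);
    vv.resize(di);
    double sum_sm = 0.0;  // sum over k of softmin(0, v_k)
    for (int s = 0; s < di; ++s) {
      ntv[s] = 1.0 - beta * (1.0 - nu[g.eid[b + s] ^ 1]);
      vv[s] = st.h[g.adj[b + s]] - st.uf_edge[g.eid[b + s]];
      sum_sm += softmin2(0.0, vv[s], invT);
    }
    en.clear();
    if (di <= ENUM_CAP) for (int s = 0; s < di; ++s) en.push_back(s);
    else {
      std::vector<int> idx(di);
      for (int s = 0; s < di; ++s) idx[s] = s;
      std::partial_sort(idx.begin(), idx.begin() + ENUM_CAP, idx.end(),
                        [&](int a, int c) { return ntv[a] < ntv[c]; });
      en.assign(idx.begin(), idx.begin() + ENUM_CAP);
      std::sort(en.begin(), en.end());
    }
    std::vector<char> is_en(di, 0);
    for (int s : en) is_en[s] = 1;
    double foldW = 0.0, foldP = 1.0;
    for (int s = 0; s < di; ++s)
      if (!is_en[s] && vv[s] < 0.0) { foldW += vv[s]; foldP *= ntv[s]; }
    double v_i = st.h[i] - st.uf_self[i];

    // message to own variable: LSE over neighbor configurations
    {
      double A0 = mu + sum_sm;
      int ne = (int)en.size();
      double acc = R_PosInf;
      for (int mask = 0; mask < (1 << ne); ++mask) {
        double P = foldP, W = foldW;
        for (int t2 = 0; t2 < ne; ++t2)
          if (mask & (1 << t2)) { P *= ntv[en[t2]]; W += vv[en[t2]]; }
        double c1 = 1.0 - (1.0 - gamma) * P + W;
        acc = (acc == R_PosInf) ? c1 : softmin2(acc, c1, invT);
      }
      double nv = damping * st.uf_self[i] + (1.0 - damping) * (acc - A0);
      maxd = std::max(maxd, std::fabs(nv - st.uf_self[i]));
      st.h[i] += nv - st.uf_self[i];
      st.uf_self[i] = nv;
    }
    for (int sj = 0; sj < di; ++sj) {
      int j = g.adj[b + sj];
      int dj = g.eid[b + sj];
      double fW = foldW, fP = foldP;
      if (!is_en[sj] && vv[sj] < 0.0) { fW -= vv[sj]; fP /= ntv[sj]; }
      double b_ni0 = mu + sum_sm - softmin2(0.0, vv[sj], invT);
      static thread_local std::vector<int> ej;
      ej.clear();
      for (int s : en) if (s != sj) ej.push_back(s);
      int ne = (int)ej.size();
      double ntj = ntv[sj];
      double acc0 = R_PosInf, acc1 = R_PosInf;
      for (int mask = 0; mask < (1 << ne); ++mask) {
        double P = fP, W = fW;
        for (int t2 = 0; t2 < ne; ++t2)
          if (mask & (1 << t2)) { P *= ntv[ej[t2]]; W += vv[ej[t2]]; }
        double c0 = 1.0 - (1.0 - gamma) * P + W;
        double c1 = 1.0 - (1.0 - gamma) * ntj * P + W;
        acc0 = (acc0 == R_PosInf) ? c0 : softmin2(acc0, c0, invT);
        acc1 = (acc1 == R_PosInf) ? c1 : softmin2(acc1, c1, invT);
      }
      double B0 = softmin2(b_ni0, v_i + acc0, invT);
      double B1 = softmin2(b_ni0, v_i + acc1, invT);
      double nv = damping * st.uf_edge[dj] + (1.0 - damping) * (B1 - B0);
      maxd = std::max(maxd, std::fabs(nv - st.uf_edge[dj]));
      st.h[j] += nv - st.uf_edge[dj];
      st.uf_edge[dj] = nv;
    }
  }
  return maxd;
}

// [[Rcpp::export]]
List cpp_cibp_soft(int n, IntegerMatrix edges, double beta, double gamma,
                   double mu, double invT, double damping_nu, double tol_nu,
                   int max_sweeps_nu, double damping_h,
                   double reinforce_rate, int max_rounds, int stable_rounds,
                   NumericVector b0, NumericVector uf_edge0,
                   NumericVector uf_self0) {
  CSRGraph g = CSRGraph::build(n, edges);
  int m2 = 2 * g.m;
  std::vector<double> b(n, 0.5);
  if (b0.size() == n) std::copy(b0.begin(), b0.end(), b.begin());
  std::vector<double> nuv(m2, 1.0 - gamma);
  MinSumState st;
  st.uf_edge.assign(m2, 0.0);
  st.uf_self.assign(n, 0.0);
  st.rein.assign(n, 0.0);
  st.h.assign(n, 0.0);
  if (uf_edge0.size() == m2) std::copy(uf_edge0.begin(), uf_edge0.end(), st.uf_edge.begin());
  if (uf_self0.size() == n) std::copy(uf_self0.begin(), uf_self0.end(), st.uf_self.begin());
  recompute_h(g, st);

  IntegerVector prev = sigma_of(st.h);
  int stable = 0, rounds = 0;
  bool conv = false;
  for (int t = 1; t <= max_rounds; ++t) {
    rounds = t;
    nu_iterate_soft(g, b, beta, gamma, damping_nu, tol_nu, max_sweeps_nu, nuv);
    sp_sweep(g, nuv, beta, gamma, mu, invT, damping_h, st);
    // reinforcement: growing self-field aligned with the current field
    for (int i = 0; i < n; ++i) {
      double sg = st.h[i] > 0.0 ? 1.0 : (st.h[i] < 0.0 ? -1.0 : 0.0);
      double add = reinforce_rate * t * sg;
      st.rein[i] += add;
      st.h[i] += add;
    }
    for (int i = 0; i < n; ++i) {
      double x = invT * st.h[i];
      b[i] = 1.0 / (1.0 + std::exp(std::max(-40.0, std::min(40.0, x))));
    }
    IntegerVector cur = sigma_of(st.h);
    bool same = true;
    for (int i = 0; i < n; ++i) if (cur[i] != prev[i]) { same = false; break; }
    stable = same ? stable + 1 : 0;
    prev = cur;
    if (stable >= stable_rounds) { conv = true; break; }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerVector sigma = prev;
  std::vector<char> occ(n);
  for (int i = 0; i < n; ++i) occ[i] = sigma[i] == 1 ? 0 : 1;
  std::vector<double> nu_node(n, 0.0);
  {
    int sw = 0;
    nu_iterate(g, occ, beta, gamma, damping_nu, tol_nu, max_sweeps_nu,
               nuv, nu_node, sw);
  }
  LogicalVector occupied(n);
  for (int i = 0; i < n; ++i) occupied[i] = occ[i] == 1;
  BFSBuf work(n);
  CompStats stc = component_stats(g, occ, work);
  return List::create(
      _["occupied"] = occupied,
      _["sigma"] = sigma,
      _["belief"] = NumericVector(b.begin(), b.end()),
      _["h_node"] = NumericVector(st.h.begin(), st.h.end()),
      _["nu_node"] = NumericVector(nu_node.begin(), nu_node.end()),
      _["rounds"] = rounds,
      _["converged"] = conv,
      _["giant"] = stc.giant,
      _["second"] = stc.second);
}

// [[Rcpp::export]]
List cpp_bp_fields(int n, IntegerMatrix edges, NumericVector nu,
                   double beta, double gamma, double mu, double damping,
                   double tol, int max_sweeps, double reinforce_rate,
                   NumericVector uf_edge0, NumericVector uf_self0) {
  CSRGraph g = CSRGraph::build(n, edges);
  int m2 = 2 * g.m;
  std::vector<double> nuv(nu.begin(), nu.end());
  MinSumState st;
  st.uf_edge.assign(m2, 0.0);
  st.uf_self.assign(n, 0.0);
  st.rein.assign(n, 0.0);
  st.h.assign(n, 0.0);
  if (uf_edge0.size() == m2) std::copy(uf_edge0.begin(), uf_edge0.end(), st.uf_edge.begin());
  if (uf_self0.size() == n) std::copy(uf_self0.begin(), uf_self0.end(), st.uf_self.begin());
  List info = minsum_converge(g, nuv, beta, gamma, mu, damping, tol,
                              max_sweeps, reinforce_rate, st);
  return List::create(
      _["h_edge"] = NumericVector(st.uf_edge.begin(), st.uf_edge.end()),
      _["h_self"] = NumericVector(st.uf_self.begin(), st.uf_self.end()),
      _["h_node"] = NumericVector(st.h.begin(), st.h.end()),
      _["sigma"] = sigma_of(st.h),
      _["converged"] = info["converged"],
      _["reinforced"] = info["reinforced"],
      _["sweeps"] = info["sweeps"]);
}

// Full CI_BP loop for one value of mu:
//  1) occupations from sigma; 2) iterate nu to convergence; 3) iterate the
//  field equations (reinforcement on failure); 4) new sigma from h;
//  5) repeat until the fields {h_i} converge.
// [[Rcpp::export]]
List cpp_cibp_solve(int n, IntegerMatrix edges, double beta, double gamma,
                    double mu, double damping_nu, double tol_nu,
                    int max_sweeps_nu, double damping_h, double tol_h,
                    int max_sweeps_h, double reinforce_rate, int max_outer,
                    double tol_outer, IntegerVector sigma0,
                    NumericVector uf_edge0, NumericVector uf_self0) {
  CSRGraph g = CSRGraph::build(n, edges);
  int m2 = 2 * g.m;
  std::vector<char> occ(n, 1);
  IntegerVector sigma = clone(sigma0);
  std::vector<double> nuv(m2, 1.0 - gamma), nu_node(n, 0.0);
  MinSumState st;
  st.uf_edge.assign(m2, 0.0);
  st.uf_self.assign(n, 0.0);
  st.rein.assign(n, 0.0);
  st.h.assign(n, 0.0);
  if (uf_edge0.size() == m2) std::copy(uf_edge0.begin(), uf_edge0.end(), st.uf_edge.begin());
  if (uf_self0.size() == n) std::copy(uf_self0.begin(), uf_self0.end(), st.uf_self.begin());

  std::vector<double> h_prev(n, R_PosInf);
  bool outer_conv = false;
  bool any_reinforced = false;
  bool all_inner_conv = true;
  int outer = 0;
  int nu_sweeps_total = 0, h_sweeps_total = 0;
  for (; outer < max_outer; ++outer) {
    for (int i = 0; i < n; ++i) occ[i] = sigma[i] == 1 ? 0 : 1;
    int sw = 0;
    bool cnu = nu_iterate(g, occ, beta, gamma, damping_nu, tol_nu,
                          max_sweeps_nu, nuv, nu_node, sw);
    nu_sweeps_total += sw;
    if (!cnu) all_inner_conv = false;
    std::fill(st.rein.begin(), st.rein.end(), 0.0);
    List info = minsum_converge(g, nuv, beta, gamma, mu, damping_h, tol_h,
                                max_sweeps_h, reinforce_rate, st);
    h_sweeps_total += as<int>(info["sweeps"]);
    if (as<bool>(info["reinforced"])) any_reinforced = true;
    if (!as<bool>(info["converged"])) all_inner_conv = false;
    IntegerVector signew = sigma_of(st.h);
    double hd = 0.0;
    for (int i = 0; i < n; ++i)
      hd = std::max(hd, std::fabs(st.h[i] - h_prev[i]));
    bool sig_same = true;
    for (int i = 0; i < n; ++i)
      if (signew[i] != sigma[i]) { sig_same = false; break; }
    std::copy(st.h.begin(), st.h.end(), h_prev.begin());
    sigma = signew;
    if (hd < tol_outer || (sig_same && outer > 0)) {
      outer_conv = true;
      ++outer;
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < n; ++i) occ[i] = sigma[i] == 1 ? 0 : 1;
  // final marginals for the returned configuration
  {
    int sw = 0;
    nu_iterate(g, occ, beta, gamma, damping_nu, tol_nu, max_sweeps_nu,
               nuv, nu_node, sw);
  }
  LogicalVector occupied(n);
  for (int i = 0; i < n; ++i) occupied[i] = occ[i] == 1;
  std::vector<char> pres(occ.begin(), occ.end());
  BFSBuf work(n);
  CompStats stc = component_stats(g, pres, work);
  return List::create(
      _["occupied"] = occupied,
      _["sigma"] = sigma,
      _["h_node"] = NumericVector(st.h.begin(), st.h.end()),
      _["nu_node"] = NumericVector(nu_node.begin(), nu_node.end()),
      _["nu"] = NumericVector(nuv.begin(), nuv.end()),
      _["outer_iters"] = outer,
      _["converged"] = outer_conv,
      _["inner_converged"] = all_inner_conv,
      _["reinforced"] = any_reinforced,
      _["nu_sweeps"] = nu_sweeps_total,
      _["h_sweeps"] = h_sweeps_total,
      _["giant"] = stc.giant,
      _["second"] = stc.second);
}
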