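#include "ci_common.h"
#include <cmath>
using namespace Rcpp;

void ciperc_frontier_bfs(const CSRGraph& g, const std::vector<char>& present,
                         int i, int ell, BFSBuf& buf);
double ciperc_ci_value_one(const CSRGraph& g, const std::vector<char>& present,
                           const std::vector<int>& deg, int i, int ell,
                           BFSBuf& buf);

static double lambda_of(double ci_sum, double n0, double mean_k0, int ell) {
  if (mean_k0 <= 0.0 || ci_sum <= 0.0) return 0.0;
  return std::pow(ci_sum / (n0 * mean_k0), 1.0 / (ell + 1));
}

// Adaptive Collective Influence attack.
// stop_rule: 0 = stop at lambda(ell; q) <= 1, 1 = remove a fixed fraction.
// The update after each removal follows the ball-of-radius-(ell+1) rule:
// nodes at distance <= ell from the removed node are fully recomputed by
// BFS; nodes at distance exactly ell+1 lose (k-1) once for every neighbor
// of the removed node sitting on their ell-frontier (exact on loopy graphs,
// and equal to the single (k-1) decrement on trees).
// [[Rcpp::export]]
List cpp_ci_attack(int n, IntegerMatrix edges, LogicalVector present0,
                   int ell, int stop_rule, double fixed_q,
                   bool det_ties, bool exact_update, int record_every) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<char> pres(present0.begin(), present0.end());
  std::vector<int> deg = live_degrees(g, pres);
  BFSBuf ball(n), work(n);

  double n0 = 0.0, two_m0 = 0.0;
  for (int i = 0; i < n; ++i) if (pres[i]) { n0 += 1.0; two_m0 += deg[i]; }
  double mean_k0 = n0 > 0 ? two_m0 / n0 : 0.0;

  std::vector<double> ci(n, 0.0);
  double ci_sum = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!pres[i]) continue;
    ci[i] = ciperc_ci_value_one(g, pres, deg, i, ell, work);
    ci_sum += ci[i];
  }
  double lam0 = lambda_of(ci_sum, n0, mean_k0, ell);
  CompStats st0 = component_stats(g, pres, work);

  IndexedMaxHeap heap;
  {
    std::vector<double> scores(n, -1.0);  // absent nodes sink to the bottom
    for (int i = 0; i < n; ++i) if (pres[i]) scores[i] = ci[i];
    heap.build(scores, det_ties);
  }

  int target = (int)std::lround(fixed_q * n0);
  std::vector<int> order;
  std::vector<double> qv, lamv;
  std::vector<int> giantv, secondv;  // NA_INTEGER except on the thinned grid
  int removed = 0;
  double qc = NA_REAL;
  double lam = lam0;
  std::string reason = "exhausted";

  if (stop_rule == 0 && lam <= 1.0) {
    qc = 0.0;
    reason = "lambda";
  } else {
    while (!heap.empty()) {
      if (stop_rule == 1 && removed >= target) { reason = "fixed_fraction"; break; }
      std::pair<int, double> top = heap.pop();
      int i = top.first;
      if (!pres[i]) continue;

      // Ball of radius ell+1 around i, in the graph before removal.
      ciperc_frontier_bfs(g, pres, i, ell + 1, ball);

      // Mask i out, decrement live neighbor degrees.
      pres[i] = 0;
      for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s)
        if (pres[g.adj[s]]) deg[g.adj[s]]--;
      deg[i] = 0;
      ci_sum -= ci[i];
      ci[i] = 0.0;

      // Inner layers (distance 1..ell): full recomputation, one node at a
      // time, each followed by its local re-heapification.
      for (int v : ball.queue) {
        if (v == i || !pres[v]) continue;
        int d = ball.dist[v];
        if (d <= ell || exact_update) {
          double nv = ciperc_ci_value_one(g, pres, deg, v, ell, work);
          if (nv != ci[v]) {
            ci_sum += nv - ci[v];
            ci[v] = nv;
            heap.update(v, nv);
          }
        }
      }
      // Outer layer (distance exactly ell+1): each neighbor m of i that
      // lies on the ell-frontier of such a node j removes one unit from
      // j's frontier degree sum, so CI_ell(j) drops by (k_j - 1) per hit.
      if (!exact_update) {
        for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s) {
          int m = g.adj[s];
          if (!pres[m]) continue;
          ciperc_frontier_bfs(g, pres, m, ell, work);
          for (int v : work.queue) {
            if (work.dist[v] != ell || !pres[v]) continue;
            if (!ball.seen(v) || ball.dist[v] != ell + 1) continue;
            double nv = ci[v] - (deg[v] - 1);
            if (nv < 0.0) nv = 0.0;
            if (nv != ci[v]) {
              ci_sum += nv - ci[v];
              ci[v] = nv;
              heap.update(v, nv);
            }
          }
        }
      }
      if (ci_sum < 0.0) ci_sum = 0.0;

      ++removed;
      order.push_back(i);
      double q = removed / n0;
      lam = lambda_of(ci_sum, n0, mean_k0, ell);
      qv.push_back(q);
      lamv.push_back(lam);
      if (removed % record_every == 0) {
        CompStats st = component_stats(g, pres, work);
        giantv.push_back(st.giant);
        secondv.push_back(st.second);
      } else {
        giantv.push_back(NA_INTEGER);
        secondv.push_back(NA_INTEGER);
      }
      if (stop_rule == 0 && lam <= 1.0) {
        qc = q;
        reason = "lambda";
        break;
      }
      if (removed % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    if (stop_rule == 1 && removed >= target) reason = "fixed_fraction";
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
      _["stop_reason"] = reason,
      _["lambda0"] = lam0,
      _["giant0"] = st0.giant,
      _["second0"] = st0.second,
      _["n0"] = n0,
      _["mean_k0"] = mean_k0,
      _["present"] = LogicalVector(pres.begin(), pres.end()));
}

// High-degree-adaptive attack: same heap machinery with score = live degree,
// stopping when the giant component falls to giant_stop nodes or fewer
// (checked on the thinned grid).
// [[Rcpp::export]]
List cpp_hda_attack(int n, IntegerMatrix edges, LogicalVector present0,
                    bool det_ties, int record_every, int giant_stop) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<char> pres(present0.begin(), present0.end());
  std::vector<int> deg = live_degrees(g, pres);
  BFSBuf work(n);

  double n0 = 0.0;
  for (int i = 0; i < n; ++i) if (pres[i]) n0 += 1.0;

  IndexedMaxHeap heap;
  {
    std::vector<double> scores(n, -1.0);
    for (int i = 0; i < n; ++i) if (pres[i]) scores[i] = deg[i];
    heap.build(scores, det_ties);
  }
  CompStats st0 = component_stats(g, pres, work);

  std::vector<int> order;
  std::vector<double> qv;
  std::vector<int> giantv, secondv;
  int removed = 0;
  double qc = NA_REAL;
  std::string reason = "exhausted";

  if (st0.giant <= giant_stop) {
    qc = 0.0;
    reason = "giant_zero";
  } else {
    while (!heap.empty()) {
      std::pair<int, double> top = heap.pop();
      int i = top.first;
      if (!pres[i]) continue;
      pres[i] = 0;
      for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s) {
        int w = g.adj[s];
        if (pres[w]) {
          deg[w]--;
          heap.update(w, deg[w]);
        }
      }
      deg[i] = 0;
      ++removed;
      order.push_back(i);
      double q = removed / n0;
      qv.push_back(q);
      if (removed % record_every == 0) {
        CompStats st = component_stats(g, pres, work);
        giantv.push_back(st.giant);
        secondv.push_back(st.second);
        if (st.giant <= giant_stop) {
          qc = q;
          reason = "giant_zero";
          break;
        }
      } else {
        giantv.push_back(NA_INTEGER);
        secondv.push_back(NA_INTEGER);
      }
      if (removed % 4096 == 0) Rcpp::checkUserInterrupt();
    }
  }
  CompStats fin = component_stats(g, pres, work);
  if (!giantv.empty()) {
    giantv.back() = fin.giant;
    secondv.back() = fin.second;
  }
  return List::create(
      _["order"] = IntegerVector(order.begin(), order.end()),
      _["q"] = NumericVector(qv.begin(), qv.end()),
      _["giant"] = IntegerVector(giantv.begin(), giantv.end()),
      _["second"] = IntegerVector(secondv.begin(), secondv.end()),
      _["qc_estimate"] = qc,
      _["stop_reason"] = reason,
      _["giant0"] = st0.giant,
      _["second0"] = st0.second,
      _["n0"] = n0,
      _["present"] = LogicalVector(pres.begin(), pres.end()));
}
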