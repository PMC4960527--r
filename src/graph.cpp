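#include "ci_common.h"
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_live_degrees(int n, IntegerMatrix edges, LogicalVector present) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<char> pres(present.begin(), present.end());
  std::vector<int> deg = live_degrees(g, pres);
  return IntegerVector(deg.begin(), deg.end());
}

// [[Rcpp::export]]
IntegerVector cpp_components(int n, IntegerMatrix edges, LogicalVector present) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<char> pres(present.begin(), present.end());
  BFSBuf buf(n);
  CompStats st = component_stats(g, pres, buf);
  return IntegerVector::create(st.giant, st.second, st.ncomp);
}

// Nodes at shortest-path distance exactly ell from i, through present nodes.
static void frontier_bfs(const CSRGraph& g, const std::vector<char>& present,
                         int i, int ell, BFSBuf& buf) {
  buf.start();
  buf.visit(i, 0);
  int head = 0;
  while (head < (int)buf.queue.size()) {
    int v = buf.queue[head++];
    int dv = buf.dist[v];
    if (dv == ell) continue;
    for (int s = g.xadj[v]; s < g.xadj[v + 1]; ++s) {
      int w = g.adj[s];
      if (present[w] && !buf.seen(w)) buf.visit(w, dv + 1);
    }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_frontier(int n, IntegerMatrix edges, LogicalVector present,
                           int i, int ell) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<char> pres(present.begin(), present.end());
  BFSBuf buf(n);
  frontier_bfs(g, pres, i, ell, buf);
  std::vector<int> out;
  for (int v : buf.queue)
    if (buf.dist[v] == ell && v != i) out.push_back(v);
  return IntegerVector(out.begin(), out.end());
}

// CI_ell(i) = (k_i - 1) * sum_{j in frontier(i, ell)} (k_j - 1),
// with live degrees. Degree-0 / absent handling is done by callers.
static double ci_value_one(const CSRGraph& g, const std::vector<char>& present,
                           const std::vector<int>& deg, int i, int ell,
                           BFSBuf& buf) {
  if (deg[i] == 0) return 0.0;
  frontier_bfs(g, present, i, ell, buf);
  double s = 0.0;
  for (int v : buf.queue)
    if (buf.dist[v] == ell && v != i) s += deg[v] - 1;
  return (deg[i] - 1) * s;
}

// [[Rcpp::export]]
double cpp_ci_value(int n, IntegerMatrix edges, LogicalVector present,
                    int i, int ell) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<char> pres(present.begin(), present.end());
  std::vector<int> deg = live_degrees(g, pres);
  BFSBuf buf(n);
  return ci_value_one(g, pres, deg, i, ell, buf);
}

// [[Rcpp::export]]
NumericVector cpp_ci_values(int n, IntegerMatrix edges, LogicalVector present,
                            int ell) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<char> pres(present.begin(), present.end());
  std::vector<int> deg = live_degrees(g, pres);
  BFSBuf buf(n);
  NumericVector out(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (pres[i]) out[i] = ci_value_one(g, pres, deg, i, ell, buf);
  return out;
}

// Shared with attack.cpp.
void ciperc_frontier_bfs(const CSRGraph& g, const std::vector<char>& present,
                         int i, int ell, BFSBuf& buf) {
  frontier_bfs(g, present, i, ell, buf);
}
double ciperc_ci_value_one(const CSRGraph& g, const std::vector<char>& present,
                           const std::vector<int>& deg, int i, int ell,
                           BFSBuf& buf) {
  return ci_value_one(g, present, deg, i, ell, buf);
}
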