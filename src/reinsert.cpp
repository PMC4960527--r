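#include "ci_common.h"
#include <algorithm>
using namespace Rcpp;

struct UnionFind {
  std::vector<int> parent, size;
  explicit UnionFind(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

// Greedy reinsertion: per batch, every still-removed node is scored by the
// number of distinct present-neighbor clusters it would join (sizes are
// ignored); the batch with the smallest counts is reinserted at once,
// restoring only edges to already-present neighbors.
// tie_rule: 0 = smallest node id; 1 = random (order supplied by caller).
// [[Rcpp::export]]
List cpp_reinsert(int n, IntegerMatrix edges, LogicalVector present0,
                  int batch_n, IntegerVector scan_order) {
  CSRGraph g = CSRGraph::build(n, edges);
  std::vector<char> pres(present0.begin(), present0.end());
  if (batch_n < 1) batch_n = 1;

  UnionFind uf(n);
  for (int e = 0; e < g.m; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    if (pres[u] && pres[v]) uf.unite(u, v);
  }
  std::vector<int> removed;
  for (int idx = 0; idx < scan_order.size(); ++idx) {
    int v = scan_order[idx];
    if (!pres[v]) removed.push_back(v);
  }
  double n0 = n;
  std::vector<double> qv;
  std::vector<int> giantv;
  std::vector<int> order;
  std::vector<int> roots;
  roots.reserve(64);

  while (!removed.empty()) {
    // Score all candidates: distinct clusters among present neighbors.
    std::vector<std::pair<int, int>> scored;  // (count, position in removed)
    scored.reserve(removed.size());
    for (int idx = 0; idx < (int)removed.size(); ++idx) {
      int v = removed[idx];
      roots.clear();
      int cnt = 0;
      for (int s = g.xadj[v]; s < g.xadj[v + 1]; ++s) {
        int w = g.adj[s];
        if (!pres[w]) continue;
        int r = uf.find(w);
        bool seen = false;
        for (int rr : roots) if (rr == r) { seen = true; break; }
        if (!seen) { roots.push_back(r); ++cnt; }
      }
      scored.push_back({cnt, idx});
    }
    int take = std::min<int>(batch_n, (int)scored.size());
    std::partial_sort(scored.begin(), scored.begin() + take, scored.end());
    std::vector<char> picked(removed.size(), 0);
    for (int t = 0; t < take; ++t) {
      int v = removed[scored[t].second];
      picked[scored[t].second] = 1;
      pres[v] = 1;
      for (int s = g.xadj[v]; s < g.xadj[v + 1]; ++s)
        if (pres[g.adj[s]]) uf.unite(v, g.adj[s]);
      order.push_back(v);
    }
    std::vector<int> rest;
    rest.reserve(removed.size() - take);
    for (int idx = 0; idx < (int)removed.size(); ++idx)
      if (!picked[idx]) rest.push_back(removed[idx]);
    removed.swap(rest);

    int giant = 0;
    for (int i = 0; i < n; ++i)
      if (pres[i] && uf.find(i) == i && uf.size[i] > giant) giant = uf.size[i];
    qv.push_back(removed.size() / n0);
    giantv.push_back(giant);
    Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["q"] = NumericVector(qv.begin(), qv.end()),
      _["giant"] = IntegerVector(giantv.begin(), giantv.end()),
      _["order"] = IntegerVector(order.begin(), order.end()));
}
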