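#ifndef CIPERC_COMMON_H
#define CIPERC_COMMON_H

#include <Rcpp.h>
#include <vector>
#include <utility>

// Compressed sparse adjacency over a fixed node set 0..n-1.
// adj holds neighbor ids; eid holds the directed-edge id of slot s,
// with edge row e of the input matrix mapping to directed ids 2e (u->v)
// and 2e+1 (v->u); reverse(d) == d ^ 1.
struct CSRGraph {
  int n;
  int m;                      // undirected edges
  std::vector<int> xadj;      // n+1
  std::vector<int> adj;       // 2m
  std::vector<int> eid;       // 2m, directed edge ids

  static CSRGraph build(int n, const Rcpp::IntegerMatrix& edges) {
    CSRGraph g;
    g.n = n;
    g.m = edges.nrow();
    g.xadj.assign(n + 1, 0);
    g.adj.assign(2 * (size_t)g.m, 0);
    g.eid.assign(2 * (size_t)g.m, 0);
    for (int e = 0; e < g.m; ++e) {
      g.xadj[edges(e, 0) + 1]++;
      g.xadj[edges(e, 1) + 1]++;
    }
    for (int i = 0; i < n; ++i) g.xadj[i + 1] += g.xadj[i];
    std::vector<int> fill(g.xadj.begin(), g.xadj.end() - 1);
    for (int e = 0; e < g.m; ++e) {
      int u = edges(e, 0), v = edges(e, 1);
      g.adj[fill[u]] = v; g.eid[fill[u]++] = 2 * e;
      g.adj[fill[v]] = u; g.eid[fill[v]++] = 2 * e + 1;
    }
    return g;
  }

  int deg_slot_begin(int i) const { return xadj[i]; }
  int deg_slot_end(int i) const { return xadj[i + 1]; }
};

// Reusable BFS buffer with stamped visitation (no O(n) reinit per call).
struct BFSBuf {
  std::vector<int> dist;
  std::vector<int> stamp;
  std::vector<int> queue;
  int cur;
  explicit BFSBuf(int n) : dist(n, 0), stamp(n, -1), queue(), cur(0) {
    queue.reserve(64);
  }
  void start() { ++cur; queue.clear(); }
  bool seen(int v) const { return stamp[v] == cur; }
  void visit(int v, int d) { stamp[v] = cur; dist[v] = d; queue.push_back(v); }
};

// Live degrees under a presence mask.
inline std::vector<int> live_degrees(const CSRGraph& g,
                                     const std::vector<char>& present) {
  std::vector<int> deg(g.n, 0);
  for (int i = 0; i < g.n; ++i) {
    if (!present[i]) continue;
    int d = 0;
    for (int s = g.xadj[i]; s < g.xadj[i + 1]; ++s)
      if (present[g.adj[s]]) ++d;
    deg[i] = d;
  }
  return deg;
}

// Largest / second-largest component among present nodes.
struct CompStats { int giant; int second; int ncomp; };

inline CompStats component_stats(const CSRGraph& g,
                                 const std::vector<char>& present,
                                 BFSBuf& buf) {
  CompStats st{0, 0, 0};
  buf.start();
  std::vector<int>& q = buf.queue;
  for (int r = 0; r < g.n; ++r) {
    if (!present[r] || buf.seen(r)) continue;
    st.ncomp++;
    int head = (int)q.size();
    buf.visit(r, 0);
    int sz = 0;
    while (head < (int)q.size()) {
      int v = q[head++];
      ++sz;
      for (int s = g.xadj[v]; s < g.xadj[v + 1]; ++s) {
        int w = g.adj[s];
        if (present[w] && !buf.seen(w)) buf.visit(w, 0);
      }
    }
    if (sz > st.giant) { st.second = st.giant; st.giant = sz; }
    else if (sz > st.second) st.second = sz;
  }
  return st;
}

// Indexed binary max-heap over node scores with node -> slot positions.
// Ties: with det_ties, equal scores rank the smaller node id first.
struct IndexedMaxHeap {
  std::vector<int> node_at;   // slot -> node
  std::vector<int> pos;       // node -> slot, -1 if not in heap
  std::vector<double> val;    // node -> score
  int sz;
  bool det;

  bool beats(int a, int b) const {
    if (val[a] != val[b]) return val[a] > val[b];
    return det && a < b;
  }
  void swap_slots(int s1, int s2) {
    std::swap(node_at[s1], node_at[s2]);
    pos[node_at[s1]] = s1;
    pos[node_at[s2]] = s2;
  }
  void sift_down(int s) {
    for (;;) {
      int l = 2 * s + 1, r = l + 1, best = s;
      if (l < sz && beats(node_at[l], node_at[best])) best = l;
      if (r < sz && beats(node_at[r], node_at[best])) best = r;
      if (best == s) break;
      swap_slots(s, best);
      s = best;
    }
  }
  void sift_up(int s) {
    while (s > 0) {
      int p = (s - 1) / 2;
      if (!beats(node_at[s], node_at[p])) break;
      swap_slots(s, p);
      s = p;
    }
  }
  // Bottom-up O(N) build over nodes 0..n-1 with given scores.
  void build(const std::vector<double>& scores, bool det_ties) {
    int n = (int)scores.size();
    det = det_ties;
    val = scores;
    node_at.resize(n);
    pos.resize(n);
    for (int i = 0; i < n; ++i) { node_at[i] = i; pos[i] = i; }
    sz = n;
    for (int s = n / 2 - 1; s >= 0; --s) sift_down(s);
  }
  bool empty() const { return sz == 0; }
  std::pair<int, double> pop() {
    int root = node_at[0];
    double v = val[root];
    pos[root] = -1;
    sz--;
    if (sz > 0) {
      node_at[0] = node_at[sz];
      pos[node_at[0]] = 0;
      sift_down(0);
    }
    return {root, v};
  }
  // Write a new score and restore the heap property locally:
  // decreases sift the slot down; increases sift it up.
  void update(int node, double newval) {
    int s = pos[node];
    if (s < 0) return;  // node already removed from heap
    double old = val[node];
    val[node] = newval;
    if (newval < old) sift_down(s);
    else if (newval > old) sift_up(s);
  }
  bool valid() const {
    for (int s = 0; s < sz; ++s) {
      int l = 2 * s + 1, r = l + 1;
      if (l < sz && val[node_at[l]] > val[node_at[s]]) return false;
      if (r < sz && val[node_at[r]] > val[node_at[s]]) return false;
      if (pos[node_at[s]] != s) return false;
    }
    return true;
  }
};

#endif
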