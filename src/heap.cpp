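#include "ci_common.h"
using namespace Rcpp;

// R-facing handle for the indexed max-heap (nodes are 1-based in R).

// [[Rcpp::export]]
SEXP cpp_heap_new(NumericVector scores, bool det_ties) {
  IndexedMaxHeap* h = new IndexedMaxHeap();
  std::vector<double> v(scores.begin(), scores.end());
  h->build(v, det_ties);
  XPtr<IndexedMaxHeap> p(h, true);
  return p;
}

// [[Rcpp::export]]
int cpp_heap_size(SEXP hp) {
  XPtr<IndexedMaxHeap> h(hp);
  return h->sz;
}

// [[Rcpp::export]]
List cpp_heap_peek(SEXP hp) {
  XPtr<IndexedMaxHeap> h(hp);
  if (h->empty()) stop("heap is empty");
  int node = h->node_at[0];
  return List::create(_["node"] = node + 1, _["score"] = h->val[node]);
}

// [[Rcpp::export]]
List cpp_heap_pop(SEXP hp) {
  XPtr<IndexedMaxHeap> h(hp);
  if (h->empty()) stop("heap is empty");
  std::pair<int, double> r = h->pop();
  return List::create(_["node"] = r.first + 1, _["score"] = r.second);
}

// [[Rcpp::export]]
void cpp_heap_update(SEXP hp, int node, double score) {
  XPtr<IndexedMaxHeap> h(hp);
  if (node < 1 || node > (int)h->pos.size() || h->pos[node - 1] < 0)
    stop("node %d is not in the heap", node);
  h->update(node - 1, score);
}

// [[Rcpp::export]]
bool cpp_heap_valid(SEXP hp) {
  XPtr<IndexedMaxHeap> h(hp);
  return h->valid();
}

// [[Rcpp::export]]
double cpp_heap_score(SEXP hp, int node) {
  XPtr<IndexedMaxHeap> h(hp);
  if (node < 1 || node > (int)h->pos.size() || h->pos[node - 1] < 0)
    stop("node %d is not in the heap", node);
  return h->val[node - 1];
}
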