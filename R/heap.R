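#' Indexed binary max-heap over node scores
#'
#' The data structure behind the adaptive attacks: a binary max-heap storing
#' `(node, score)` pairs together with the inverse node-to-slot map, so the
#' slot of any node can be re-heapified locally after its score changes.
#' Built bottom-up in O(N); `heap_pop_max()` replaces the root with the
#' rightmost leaf and sifts it down; `heap_update()` sifts down after a
#' decrease and falls back to sifting up on the (rare, loopy-graph) increase
#' rather than silently violating the heap property.
#'
#' @param scores numeric vector; node `i` of the heap is index `i` of
#'   `scores`.
#' @param deterministic_ties if `TRUE`, equal scores rank the smaller node id
#'   first, making pop order reproducible.
#' @return an object of class `ci_heap` (external pointer).
#' @examples
#' h <- indexed_max_heap(c(a = 3, b = 1, c = 4, d = 1, e = 5))
#' heap_pop_max(h)$score  # 5
#' @export
indexed_max_heap <- function(scores, deterministic_ties = FALSE) {
  stopifnot(is.numeric(scores), all(is.finite(scores)))
  h <- cpp_heap_new(as.numeric(scores), isTRUE(deterministic_ties))
  class(h) <- "ci_heap"
  h
}

#' @rdname indexed_max_heap
#' @param heap a `ci_heap`
#' @return `heap_pop_max()` and `heap_peek()` return `list(node, score)`.
#' @export
heap_pop_max <- function(heap) cpp_heap_pop(heap)

#' @rdname indexed_max_heap
#' @export
heap_peek <- function(heap) cpp_heap_peek(heap)

#' @rdname indexed_max_heap
#' @param node node id whose score changes
#' @param score the new score
#' @export
heap_update <- function(heap, node, score) {
  cpp_heap_update(heap, as.integer(node), as.numeric(score))
  invisible(heap)
}

#' @rdname indexed_max_heap
#' @export
heap_size <- function(heap) cpp_heap_size(heap)

#' @rdname indexed_max_heap
#' @details `heap_is_valid()` scans every slot and checks the max-heap
#'   property and the position map; it exists for test-mode assertions.
#' @export
heap_is_valid <- function(heap) cpp_heap_valid(heap)

#' @export
print.ci_heap <- function(x, ...) {
  cat(sprintf("indexed max-heap, %d live entries\n", heap_size(x)))
  invisible(x)
}
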