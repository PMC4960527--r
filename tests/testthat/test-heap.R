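test_that("heap orders pops and stays valid", {
  h <- indexed_max_heap(c(3, 1, 4, 1, 5))
  top <- heap_pop_max(h)
  expect_equal(top$score, 5)
  expect_equal(top$node, 5)
  expect_true(heap_is_valid(h))
  expect_equal(heap_pop_max(h)$score, 4)
  expect_equal(heap_size(h), 3)
})

test_that("popping a heap of random scores yields non-increasing order", {
  set.seed(20)
  sc <- runif(1000)
  h <- indexed_max_heap(sc)
  popped <- vapply(seq_len(1000), function(i) heap_pop_max(h)$score, 1.0)
  expect_equal(popped, sort(sc, decreasing = TRUE))
  expect_error(heap_pop_max(h), "empty")
})

test_that("equal scores satisfy the heap property in any arrangement", {
  h <- indexed_max_heap(rep(2, 17))
  expect_true(heap_is_valid(h))
  expect_equal(heap_pop_max(h)$score, 2)
  expect_true(heap_is_valid(h))
})

test_that("deterministic ties pop smallest node id first", {
  h <- indexed_max_heap(c(1, 7, 7, 7, 0), deterministic_ties = TRUE)
  expect_equal(heap_pop_max(h)$node, 2)
  expect_equal(heap_pop_max(h)$node, 3)
  expect_equal(heap_pop_max(h)$node, 4)
})

test_that("score updates re-heapify locally in both directions", {
  h <- indexed_max_heap(c(9, 5, 7, 1, 2))
  heap_update(h, 1, 0)   # decrease the root below everything
  expect_true(heap_is_valid(h))
  expect_equal(heap_peek(h)$score, 7)
  heap_update(h, 4, 100) # a leaf overtakes: sift-up fallback
  expect_true(heap_is_valid(h))
  expect_equal(heap_peek(h)$node, 4)
  expect_error(heap_update(h, 99, 1), "not in the heap")
})

test_that("random decrease sequences end in sorted pop order", {
  set.seed(31)
  for (rep in 1:5) {
    sc <- runif(60, 10, 20)
    h <- indexed_max_heap(sc)
    for (j in 1:40) {
      node <- sample.int(60, 1)
      sc[node] <- sc[node] * runif(1, 0.1, 0.9)
      heap_update(h, node, sc[node])
      expect_true(heap_is_valid(h))
    }
    popped <- vapply(seq_len(60), function(i) heap_pop_max(h)$score, 1.0)
    expect_equal(popped, sort(sc, decreasing = TRUE))
  }
})
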