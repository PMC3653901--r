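# Exact maximum-weight matching used for strong-adjacency inference.

test_that("matching weight equals brute force on random multigraphs", {
  set.seed(53)
  for (trial in 1:30) {
    V <- sample(3:7, 1)
    ne <- sample(2:10, 1)
    v1 <- integer(0); v2 <- integer(0)
    for (k in seq_len(ne)) {
      ab <- sort(sample(V, 2))
      v1 <- c(v1, ab[1]); v2 <- c(v2, ab[2])
    }
    w <- sample(1:5, ne, replace = TRUE)
    sel <- DCJAliquot:::.maxWeightMatching(v1, v2, w)
    # selected edges form a matching
    expect_false(anyDuplicated(c(v1[sel], v2[sel])) > 0)
    expect_equal(sum(w[sel]), bruteMaxWeightMatching(v1, v2, w))
  }
})

test_that("degenerate inputs", {
  expect_equal(DCJAliquot:::.maxWeightMatching(integer(0), integer(0),
                                               numeric(0)), integer(0))
  expect_equal(DCJAliquot:::.maxWeightMatching(1L, 2L, 5), 1L)
})
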