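# Disjoint path search and pair scoring.

# single black cycle over vertex ids 1..L (labels via .feLabel), unit mult
makeCycleGraph <- function(L) {
  e1 <- seq_len(L)
  e2 <- c(seq_len(L - 1L) + 1L, 1L)
  sw <- e1 > e2
  tmp <- e1[sw]; e1[sw] <- e2[sw]; e2[sw] <- tmp
  edges <- data.frame(
    end1 = DCJAliquot:::.feLabel(e1), end2 = DCJAliquot:::.feLabel(e2),
    color = "black", multiplicity = 1L, stringsAsFactors = FALSE)
  new("ContractedGraph", edges = edges,
      provenance = replicate(L, cbind(copy1 = 1L, copy2 = 1L),
                             simplify = FALSE))
}

test_that("a lone direct black edge is a single path of length 1", {
  edges <- data.frame(end1 = "1t", end2 = "1h", color = "black",
                      multiplicity = 1L, stringsAsFactors = FALSE)
  g <- new("ContractedGraph", edges = edges,
           provenance = list(cbind(copy1 = 1L, copy2 = 1L)))
  ps <- findPathSet(g, "1t", "1h", maxPaths = 2)
  expect_equal(ps@lengths, 1L)
  expect_true(isTRUE(validatePathSet(g, ps)))
})

test_that("adjacent vertices on a black 6-cycle yield paths {1, 5}", {
  g <- makeCycleGraph(6)
  ps <- findPathSet(g, DCJAliquot:::.feLabel(1L), DCJAliquot:::.feLabel(2L),
                    maxPaths = 2)
  expect_equal(sort(ps@lengths), c(1L, 5L))
  expect_true(isTRUE(validatePathSet(g, ps)))
})

test_that("every pair on a single black cycle has N_p = 2 and the halving C_p", {
  for (L in 3:10) {
    g <- makeCycleGraph(L)
    for (sep in 1:(L - 1)) {
      sc <- scorePair(g, DCJAliquot:::.feLabel(1L),
                      DCJAliquot:::.feLabel(1L + sep), maxPaths = 2)
      expect_equal(sc@np, 2L)
      expected <-
        if (L %% 2 == 0 && sep %% 2 == 1) (L + 2) / (2 * L)
        else if (L %% 2 == 0)             0.5
        else                              (L + 1) / (2 * L)
      expect_equal(sc@cp, expected)
      expect_equal(sc@wp, 0.5 * 2 + 0.5 * expected)
    }
    # the paper's preference order between the three cases
    expect_gt((L + 2) / (2 * L), (L + 1) / (2 * L))
    expect_gt((L + 1) / (2 * L), 0.5)
  }
})

test_that("find_path matches exhaustive enumeration on random graphs", {
  set.seed(41)
  for (trial in 1:40) {
    rg <- randomPathGraph()
    got <- packagePathSet(rg$A, rg$matched, rg$u, rg$v, maxPaths = 2L)
    want <- oraclePathSet(rg$A, rg$matched, rg$u, rg$v, maxPaths = 2L,
                          maxLen = sum(rg$A$mult))
    expect_equal(got, want)
  }
})

test_that("adding an edge never decreases the maximal path count", {
  set.seed(43)
  for (trial in 1:20) {
    rg <- randomPathGraph()
    before <- packagePathSet(rg$A, rg$matched, rg$u, rg$v, maxPaths = 3L)
    A2 <- rg$A
    ab <- sort(sample(max(c(rg$A$e1, rg$A$e2, 2L)), 2L))
    A2$e1 <- c(A2$e1, ab[1]); A2$e2 <- c(A2$e2, ab[2])
    A2$color <- c(A2$color, 0L); A2$mult <- c(A2$mult, 1L)
    A2$prov <- c(A2$prov, list(NULL))
    after <- packagePathSet(A2, rg$matched, rg$u, rg$v, maxPaths = 3L)
    expect_gte(after["np"], before["np"])
  }
})

test_that("pairs with no valid path score zero", {
  edges <- data.frame(end1 = "1t", end2 = "1h", color = "gray",
                      multiplicity = 1L, stringsAsFactors = FALSE)
  g <- new("ContractedGraph", edges = edges,
           provenance = list(cbind(copy1 = 1L, copy2 = 1L)))
  sc <- scorePair(g, "1t", "1h")
  expect_equal(sc@np, 0L)
  expect_equal(sc@cp, 0)
  expect_equal(sc@wp, 0)
})

test_that("absent vertices are rejected", {
  g <- makeCycleGraph(4)
  expect_error(findPathSet(g, "9t", "1t"), "absent")
})
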