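# The aliquoting heuristic: pair processing mechanics, the main loop,
# linearization, and small-instance optimality.

# hand-built aliquoting state: n families at duplicated size r, graph B
# given as a list of partner pairs over labelled extremities (caps above
# 2*r*n, tail of family f copy c = ((f-1)*r + c - 1)*2 + 1, head + 1)
makeTestState <- function(n, r, bpPairs) {
  st <- new.env(parent = emptyenv())
  st$n <- as.integer(n); st$r <- as.integer(r)
  st$capBase <- 2L * r * n
  nCaps <- sum(unlist(bpPairs) > st$capBase)
  bp <- rep(NA_integer_, st$capBase + nCaps)
  for (p in bpPairs) { bp[p[1]] <- p[2]; bp[p[2]] <- p[1] }
  st$bp <- bp
  st$H <- list()
  st$matchedOnce <- logical(2L * n)
  st$uf <- seq_len(2L * n)
  for (f in seq_len(n)) DCJAliquot:::.ufUnion(st, 2L * f - 1L, 2L * f)
  st$pObs <- integer(st$capBase)
  st
}

contractEdges <- function(st) {
  A <- DCJAliquot:::.stateContract(st)
  sprintf("%d-%d:m%d", A$e1, A$e2, A$mult)
}

test_that("a direct strong edge contracts to closed cycles that vanish", {
  # two copies of the chromosome (1 2): B edges (1h.c, 2t.c) plus caps
  st <- makeTestState(2, 2, list(c(2, 5), c(4, 7), c(1, 9), c(3, 10),
                                 c(6, 11), c(8, 12)))
  DCJAliquot:::.processMatchedPair(st, 2L, 3L, matrix(c(2L, 3L), 1L))
  H <- do.call(rbind, st$H)
  expect_equal(H[order(H[, 1]), ], rbind(c(2L, 5L), c(4L, 7L)))
  # only telomeric evidence remains
  expect_true(all(DCJAliquot:::.stateContract(st)$e1 == 0L))
  expect_true(all(is.na(st$bp[c(2, 4, 5, 7)])))
})

test_that("an odd path (u, a, b, v) contracts into a new black edge (a, b)", {
  # B: (1h.1-2t.1), (2t.2-2h.1), (2h.2-3t.1); the rest telomeric
  st <- makeTestState(3, 2, list(c(2, 5), c(7, 6), c(8, 9),
                                 c(1, 13), c(3, 14), c(4, 15),
                                 c(10, 16), c(11, 17), c(12, 18)))
  DCJAliquot:::.processMatchedPair(st, 2L, 5L, matrix(c(2L, 5L), 1L))
  H <- do.call(rbind, st$H)
  # the odd path 1h-2t-2h-3t pairs (1h.1, 3t.1); leftovers pair ascending
  expect_true(any(H[, 1] == 2L & H[, 2] == 9L))
  edges <- contractEdges(st)
  expect_true("3-4:m2" %in% edges)   # (2t, 2h) reinforced by the contraction
})

test_that("two even paths contract into two new black edges", {
  st <- makeTestState(3, 2, list(c(2, 5), c(7, 9),
                                 c(1, 13), c(3, 14), c(4, 15), c(6, 16),
                                 c(8, 17), c(10, 18), c(11, 19), c(12, 20)))
  DCJAliquot:::.processMatchedPair(st, 2L, 5L, matrix(c(2L, 5L), 1L))
  H <- do.call(rbind, st$H)
  expect_equal(nrow(H), 2L)
  # crossed copy pairing: (1h.1, 3t.2) and (1h.2, 3t.1)
  expect_setequal(paste(H[, 1], H[, 2]), c("2 11", "4 9"))
  expect_true("0-3:m2" %in% contractEdges(st))
})

test_that("an unrearranged duplication is recovered exactly", {
  anc <- Genome(list(c(1, -2, 3), c(4, 5)), name = "anc")
  gobs <- wgd(anc, 3)
  res <- aliquot(gobs, 3)
  expect_equal(res@distance, 0)
  expect_true(isPerfectlyDuplicated(res@gdup, 3))
  expect_setequal(DCJAliquot:::.chromCanonicalKeys(res@ganc),
                  DCJAliquot:::.chromCanonicalKeys(anc))
})

test_that("strong-edge matching selects the only strong candidate", {
  A <- list(e1 = c(1L, 1L, 3L), e2 = c(2L, 4L, 4L),
            color = c(0L, 0L, 0L), mult = c(2L, 1L, 1L),
            prov = list(NULL, NULL, NULL))
  st <- makeTestState(2, 2, list())
  pairs <- DCJAliquot:::.step1Matching(A, st)
  expect_equal(unname(pairs), cbind(1L, 2L))
  A$mult <- c(1L, 1L, 1L)
  expect_null(DCJAliquot:::.step1Matching(A, st))
})

test_that("strong adjacencies inferred first carry multiplicity >= 2", {
  set.seed(83)
  for (i in 1:50) {
    gobs <- applyRandomDcj(wgd(randomSingleCopyGenome(30, 2), 3),
                           sample.int(12, 1))
    st <- DCJAliquot:::.initAliquotState(gobs, 3L)
    A0 <- DCJAliquot:::.stateContract(st)
    key0 <- paste(A0$e1, A0$e2)
    pairs <- DCJAliquot:::.step1Matching(A0, st)
    if (is.null(pairs)) next
    for (j in seq_len(nrow(pairs))) {
      uv <- pairs[j, ]; if (uv[1] == 0L) uv <- uv[2:1]
      DCJAliquot:::.processMatchedPair(st, uv[1], uv[2],
                                       pairs[j:nrow(pairs), , drop = FALSE])
    }
    H <- do.call(rbind, st$H)
    fe <- cbind(DCJAliquot:::.feOf(H[, 1], st), DCJAliquot:::.feOf(H[, 2], st))
    for (j in seq_len(nrow(fe))) {
      k <- match(paste(min(fe[j, ]), max(fe[j, ])), key0)
      expect_gte(A0$mult[k], 2L)
    }
  }
})

test_that("linearization splits a free circular chromosome at zero cost", {
  anc <- Genome(list(c(1, 2, 3)), name = "anc")
  gobs <- wgd(anc, 2)
  st <- DCJAliquot:::.initAliquotState(gobs, 2L)
  # H = G_dup with each copy circularised by the extra (3h, 1t) join
  pH <- integer(st$capBase)
  join <- function(a, b) { pH[a] <<- b; pH[b] <<- a }
  join(2L, 5L); join(6L, 9L); join(10L, 1L)    # copy 1
  join(4L, 7L); join(8L, 11L); join(12L, 3L)   # copy 2
  expect_equal(DCJAliquot:::.dcjDistancePartners(st$pObs, pH), 2L)
  out <- DCJAliquot:::.linearizeCircular(st, pH)
  expect_equal(DCJAliquot:::.dcjDistancePartners(st$pObs, out), 0L)
  comps <- DCJAliquot:::.familyComponents(st, out)
  expect_true(all(!vapply(comps, `[[`, logical(1), "circular")))
})

test_that("no circular chromosomes means linearization is the identity", {
  anc <- Genome(list(c(1, 2)), name = "anc")
  gobs <- wgd(anc, 2)
  st <- DCJAliquot:::.initAliquotState(gobs, 2L)
  pH <- st$pObs
  expect_equal(DCJAliquot:::.linearizeCircular(st, pH), pH)
})

test_that("tiny halving instances reach the exhaustive optimum", {
  set.seed(89)
  cands <- allHalvedPartnerVectors(3)
  for (i in 1:6) {
    gobs <- applyRandomDcj(wgd(randomSingleCopyGenome(3, 2), 2),
                           sample.int(6, 1))
    res <- aliquot(gobs, 2)
    expect_equal(as.integer(res@distance), oracleAliquotMin(gobs, cands))
  }
})

test_that("invalid inputs are rejected and runs are deterministic", {
  bad <- readGenomes(text = c(">g", "1.1 1.2 2.1 $"))[[1]]
  expect_error(aliquot(bad, 2), "family sizes")
  g <- wgd(Genome(list(c(1, 2))), 2)
  expect_error(aliquot(g, 1), "duplicated size")
  set.seed(97)
  gobs <- applyRandomDcj(wgd(randomSingleCopyGenome(12, 2), 3), 10)
  r1 <- aliquot(gobs, 3)
  r2 <- aliquot(gobs, 3)
  expect_identical(writeGenomes(r1@gdup), writeGenomes(r2@gdup))
  expect_identical(r1@distance, r2@distance)
})
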