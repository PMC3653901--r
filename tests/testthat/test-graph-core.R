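# Partial graph, contracted graph, DCJ distance.

test_that("partial graph edge counts follow the adjacency identity", {
  g <- Genome(list(1))
  pg <- partialGraph(g)
  expect_equal(nrow(pg@edges), 2L)         # one gene, two telomeres
  set.seed(3)
  for (i in 1:20) {
    gg <- applyRandomDcj(wgd(randomSingleCopyGenome(sample(3:7, 1), 2), 2),
                         sample.int(5, 1))
    K <- sum(!vapply(gg@chromosomes, `[[`, logical(1), "circular"))
    pgg <- partialGraph(gg)
    expect_equal(nrow(pgg@edges), nGenes(gg) + K)
    # each extremity participates in exactly one adjacency
    ext <- c(paste(pgg@edges$family1, pgg@edges$kind1, pgg@edges$copy1),
             paste(pgg@edges$family2, pgg@edges$kind2, pgg@edges$copy2))
    ext <- ext[!grepl("^0 ", ext)]
    expect_false(anyDuplicated(ext) > 0)
  }
})

test_that("contraction collapses parallel adjacencies with provenance", {
  g <- Genome(list(c(1, 2), c(1, 2)))
  cg <- contractGraph(partialGraph(g))
  validObject(cg)
  e <- cg@edges
  i <- which(e$end1 == "1h" & e$end2 == "2t")
  expect_length(i, 1L)
  expect_equal(e$multiplicity[i], 2L)
  expect_equal(cg@provenance[[i]], cbind(copy1 = c(1L, 2L),
                                         copy2 = c(1L, 2L)))
  # a single-copy genome has no strong edges
  cg1 <- contractGraph(partialGraph(Genome(list(c(1, 2, 3)))))
  expect_true(all(cg1@edges$multiplicity == 1L))
})

test_that("total multiplicity equals the adjacency count on simulated genomes", {
  set.seed(17)
  for (i in 1:100) {
    g <- applyRandomDcj(wgd(randomSingleCopyGenome(sample(3:8, 1), 2),
                            sample(2:3, 1)), sample.int(8, 1))
    cg <- contractGraph(partialGraph(g))
    expect_equal(sum(cg@edges$multiplicity), nrow(adjacencies(g)))
  }
})

test_that("DCJ distance basics", {
  g <- Genome(list(c(1, 2, 3)))
  expect_equal(dcjDistance(g, g), 0L)
  expect_equal(dcjDistance(g, Genome(list(c(1, -2, 3)))), 1L)
  expect_error(dcjDistance(g, Genome(list(c(1, 2)))), "content")
  # circular chromosomes are accepted
  expect_equal(dcjDistance(g, Genome(list(c(1, 2, 3)), circular = TRUE)), 1L)
})

test_that("DCJ distance equals BFS depth over the operation graph", {
  set.seed(29)
  for (i in 1:12) {
    a <- applyRandomDcj(wgd(randomSingleCopyGenome(2, 1), 2),
                        sample.int(3, 1))
    b <- applyRandomDcj(a, sample(0:3, 1))
    pa <- genomePartnerVec(a)
    pb <- genomePartnerVec(b, a)
    expect_equal(dcjDistance(a, b), bfsDcjDistance(pa, pb))
  }
})

test_that("DCJ distance behaves like a metric and moves by at most 1 per op", {
  set.seed(31)
  for (i in 1:15) {
    base <- wgd(randomSingleCopyGenome(4, 2), 2)
    a <- applyRandomDcj(base, sample.int(5, 1))
    b <- applyRandomDcj(base, sample.int(5, 1))
    c_ <- applyRandomDcj(base, sample.int(5, 1))
    expect_equal(dcjDistance(a, b), dcjDistance(b, a))
    expect_lte(dcjDistance(a, c_), dcjDistance(a, b) + dcjDistance(b, c_))
    expect_gte(dcjDistance(a, b), 0L)
    a1 <- applyRandomDcj(a, 1)
    expect_lte(abs(dcjDistance(a, base) - dcjDistance(a1, base)), 1L)
  }
})

test_that("breakpoint graph counts drive the distance formula", {
  a <- Genome(list(c(1, 2, 3)))
  b <- Genome(list(c(1, -2, 3)))
  bg <- breakpointGraph(a, b)
  expect_equal(bg@n, 3L)
  expect_equal(bg@n - bg@cycles - bg@oddPaths %/% 2L, 1L)
})

test_that("relative distance is the normalised DCJ distance", {
  expect_equal(relativeDistance(0, 3, 100), 0)
  expect_equal(relativeDistance(300, 3, 100), 1)
  expect_equal(relativeDistance(150, 3, 100), 0.5)
})
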