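# Simulation of ancestors, duplications and random DCJ rearrangements.

test_that("random single-copy ancestors cover 1..n in order", {
  set.seed(61)
  g <- randomSingleCopyGenome(5, 1)
  expect_equal(length(g@chromosomes), 1L)
  expect_equal(g@chromosomes[[1]]$family, 1:5)
  expect_error(randomSingleCopyGenome(3, 5), "exceed")
  for (i in 1:50) {
    gg <- randomSingleCopyGenome(10, 3)
    expect_equal(unlist(lapply(gg@chromosomes, `[[`, "family")), 1:10)
    expect_true(all(unlist(lapply(gg@chromosomes, `[[`, "sign")) == 1L))
  }
})

test_that("chromosome counts are uniform on [1, m0]", {
  set.seed(67)
  counts <- replicate(2000, length(randomSingleCopyGenome(10, 3)@chromosomes))
  tab <- table(factor(counts, levels = 1:3))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("wgd produces a perfectly duplicated genome with copy IDs 1..r", {
  g <- wgd(Genome(list(c(1, 2)), name = "a"), 2)
  expect_equal(lapply(g@chromosomes, `[[`, "copy"),
               list(c(1L, 1L), c(2L, 2L)))
  expect_true(isPerfectlyDuplicated(g, 2))
  expect_equal(dcjDistance(g, g), 0L)
  expect_error(wgd(g, 2), "single-copy")
})

test_that("random DCJ operations keep content and linearity, move by <= 1 each", {
  set.seed(71)
  g0 <- wgd(randomSingleCopyGenome(6, 2), 2)
  expect_identical(applyRandomDcj(g0, 0), g0)
  for (i in 1:200) {
    k <- sample.int(6, 1)
    g1 <- applyRandomDcj(g0, k)
    expect_lte(dcjDistance(g0, g1), k)
    expect_true(all(!vapply(g1@chromosomes, `[[`, logical(1), "circular")))
    expect_equal(DCJAliquot:::.contentTable(g1), DCJAliquot:::.contentTable(g0))
  }
  for (i in 1:20)
    expect_lte(dcjDistance(g0, applyRandomDcj(g0, 1)), 1L)
})

test_that("datasets are reproducible and respect the distance bound", {
  d1 <- simulateDataset(8, n = 15, m0 = 2, r = 2, seed = 99)
  d2 <- simulateDataset(8, n = 15, m0 = 2, r = 2, seed = 99)
  expect_equal(d1$table, d2$table)
  expect_equal(writeGenomes(d1$records[[3]]$gobs),
               writeGenomes(d2$records[[3]]$gobs))
  expect_true(all(d1$table$simD <= d1$table$dN))
  expect_true(all(d1$table$simRel >= 0 & d1$table$simRel <= 1))
  for (rec in d1$records) {
    expect_true(isPerfectlyDuplicated(rec$gdup, 2))
    expect_equal(unique(unname(familySizes(rec$gobs))), 2L)
  }
})

test_that("uniform D_N has mean relative operation count near 0.5", {
  d <- simulateDataset(300, n = 20, m0 = 2, r = 2, seed = 123)
  relDN <- d$table$dN / (2 * 20)
  expect_lt(abs(mean(relDN) - 0.5), 0.06)
})
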