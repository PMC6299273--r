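test_that("every generator is a pure function of its seed", {
  a <- makeAnnotatedGenome(seed = 17, pStartShift = 0.5, pDuplicate = 0.3)
  b <- makeAnnotatedGenome(seed = 17, pStartShift = 0.5, pDuplicate = 0.3)
  expect_identical(genomeSequence(a$truth), genomeSequence(b$truth))
  expect_identical(gbFeatures(a$corrupted), gbFeatures(b$corrupted))
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.1,C:0.3,D:0.3);")
  expect_identical(as.character(simulateCodonAlignment(tr, 0.5, 2,
                                                       nCodons = 50, seed = 4)),
                   as.character(simulateCodonAlignment(tr, 0.5, 2,
                                                       nCodons = 50, seed = 4)))
  o <- geneOrder(paste0("+", 1:10), anchor = "1")
  expect_identical(orderSymbols(scrambleGeneOrder(o, 3, 2, seed = 6)$order),
                   orderSymbols(scrambleGeneOrder(o, 3, 2, seed = 6)$order))
  expect_identical(ape::write.tree(makeClockTree(5, seed = 9)$tree),
                   ape::write.tree(makeClockTree(5, seed = 9)$tree))
  ## and the caller's RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(makeAnnotatedGenome(seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("disabled corruption returns an identical annotation", {
  sim <- makeAnnotatedGenome(seed = 21)
  expect_identical(gbFeatures(sim$truth), gbFeatures(sim$corrupted))
  expect_equal(nrow(sim$diffs), 0L)
})

test_that("generated annotations satisfy the curation rules at many seeds", {
  for (s in 101:110) {
    sim <- makeAnnotatedGenome(seed = s)
    expect_equal(nrow(curateRecord(sim$truth)$diffs), 0L)
    expect_false(any(checkPcgOverlapLegality(sim$truth)$violation))
  }
})

test_that("configured spacers come back from the geometry exactly", {
  lay <- data.frame(
    name = c("p1", "t1", "p2", "t2"), kind = c("PCG", "tRNA", "PCG", "tRNA"),
    strand = "+", len = c(150L, 60L, 90L, 66L),
    gapAfter = c(11L, 5L, 78L, 4L),
    startCodon = c("ATG", NA, "ATG", NA))
  sim <- makeAnnotatedGenome(seed = 2, layout = lay)
  geom <- computeGeneGeometry(sim$truth)
  expect_equal(geom$gap, c(11L, 5L, 78L, 4L))
})

test_that("simulated codon alignments contain no stop codons", {
  tr <- ape::read.tree(text = "((A:0.5,B:0.5):0.2,C:0.7,D:0.7);")
  aln <- simulateCodonAlignment(tr, omega = 2, kappa = 2, nCodons = 300,
                                seed = 31)
  stops <- stopCodons(geneticCode(5L))
  for (x in as.character(aln)) {
    codons <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
    expect_false(any(codons %in% stops))
  }
  expect_error(simulateCodonAlignment(tr, 1, 2, nCodons = 0, seed = 1),
               "positive")
})

test_that("long-branch simulation converges to the stationary frequencies", {
  tr <- ape::read.tree(text = "(A:8,B:8);")
  aln <- simulateCodonAlignment(tr, omega = 1, kappa = 2, nCodons = 10000,
                                seed = 12)
  sense <- senseCodons(geneticCode(5L))
  x <- as.character(aln)[["A"]]
  emp <- table(factor(substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3)),
                      levels = sense)) / 10000
  ## every codon frequency within 2% of its stationary value, and the
  ## overall fit compatible with uniformity
  expect_lt(max(abs(as.numeric(emp) - 1 / 62)), 0.02)
  gof <- suppressWarnings(chisq.test(as.numeric(emp) * 10000,
                                     p = rep(1 / 62, 62)))
  expect_gt(gof$p.value, 1e-3)
})

test_that("all-zero branch lengths copy the root to every tip", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  aln <- as.character(simulateCodonAlignment(tr, 0.5, 2, nCodons = 40,
                                             seed = 2))
  expect_equal(aln[["A"]], aln[["B"]])
  expect_equal(aln[["A"]], aln[["C"]])
})

test_that("scrambling obeys the breakpoint bounds", {
  o <- geneOrder(paste0("+", 1:13), anchor = "1")
  expect_identical(orderSymbols(scrambleGeneOrder(o, 0, 0, seed = 1)$order),
                   orderSymbols(o))
  for (s in 1:25) {
    one <- scrambleGeneOrder(o, nInversions = 1, seed = s)
    expect_equal(breakpointCount(o, one$order), 2L)
    k <- sample(1:4, 1)
    m <- sample(0:2, 1)
    many <- scrambleGeneOrder(o, nInversions = k, nTranspositions = m,
                              seed = 1000 + s)
    expect_lte(breakpointCount(o, many$order), 2L * k + 3L * m)
    expect_equal(nrow(many$events), k + m)
  }
})

test_that("clock trees honour depth and rate multipliers", {
  ct <- makeClockTree(5, depth = 2, seed = 13)
  expect_true(ape::is.ultrametric(ct$tree, tol = 1e-8))
  expect_equal(unname(max(rootToTipDistances(ct$tree))), 2, tolerance = 1e-9)
  ct2 <- makeClockTree(6, depth = 1, rateMultipliers = c(t5 = 3), seed = 13)
  d <- rootToTipDistances(ct2$tree)
  expect_equal(names(which.max(d)), "t5")
  expect_equal(unname(d["t5"]), 3, tolerance = 1e-9)
  ct3 <- makeClockTree(4, depth = 1, rateMultipliers = c(t4 = 2), seed = 2)
  delta <- branchLengthTest(ct3$tree)
  expect_equal(delta$delta[delta$taxon == "t4"], 0.75, tolerance = 1e-9)
})

test_that("two-ratio simulations give the LRT power to detect selection", {
  tr <- ape::read.tree(text = "(A:0.3,B:0.3,C:0.3);")
  sig <- 0L
  for (s in 1:20) {
    aln <- simulateCodonAlignment(tr, omega = c(A = 5, .default = 0.2),
                                  kappa = 2, nCodons = 800, seed = 500 + s)
    f0 <- fitBranchModel(aln, tr, "one_ratio", nStarts = 1)
    f1 <- fitBranchModel(aln, tr, "two_ratios", foreground = "A", nStarts = 1)
    if (likelihoodRatioTest(f0, f1)$statistic > 3.84) sig <- sig + 1L
  }
  expect_gte(sig, 16L)  # >= 80% of 20 replicates
})
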