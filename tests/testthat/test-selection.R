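test_that("protein divergence counts focal sites differing from any taxon", {
  same <- c(a = "MKVL", b = "MKVL", c = "MKVL", d = "MKVL")
  expect_equal(proteinDivergence(same, "a")$proportion, 0)
  mix <- c(a = "MKV", b = "MKV", c = "MRV", d = "MKV")
  pd <- proteinDivergence(mix, "a")
  expect_equal(pd$n_diff, 1L)
  expect_equal(pd$length, 3L)
  expect_equal(pd$proportion, 1 / 3)
  expect_error(proteinDivergence(c(a = "MK", b = "MKV"), "a"), "equal length")
  gap <- c(a = "MKV", b = "M-V")
  expect_equal(proteinDivergence(gap, "a")$n_diff, 0L)
  expect_equal(proteinDivergence(gap, "a", countGaps = TRUE)$n_diff, 1L)
})

test_that("the codon rate matrix is a scaled reversible generator", {
  pi <- f3x4Frequencies(c(x = paste(rep("ATGGCACGATTT", 10), collapse = "")))
  for (om in c(0.2, 1, 5)) {
    Q <- codonRateMatrix(kappa = 2.5, omega = om, freqs = pi)
    expect_lt(max(abs(rowSums(Q))), 1e-10)
    expect_lt(max(abs(as.numeric(pi %*% Q))), 1e-10)     # stationarity
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)  # mean rate 1
  }
  Q <- codonRateMatrix(kappa = 2, omega = 0.25)
  expect_equal(Q["TTT", "CCT"], 0)  # two positions differ
  ## TTT->TTC is a synonymous transition, TTT->TTA a non-synonymous
  ## transversion: the ratio of rates is kappa/omega under uniform freqs
  expect_equal(Q["TTT", "TTC"] / Q["TTT", "TTA"], 2 / 0.25)
  Q1 <- codonRateMatrix(kappa = 1, omega = 1)
  off <- Q1[row(Q1) != col(Q1)]
  expect_setequal(round(unique(off[off > 0]), 12),
                  round(unique(off[off > 0])[1], 12))  # all steps equal
})

test_that("pruning equals brute-force summation on a two-taxon tree", {
  tr <- ape::read.tree(text = "(A:0.2,B:0.3);")
  aln <- simulateCodonAlignment(tr, omega = 0.5, kappa = 2, nCodons = 5,
                                seed = 3)
  ll <- codonLogLik(aln, tr, kappa = 2, omega = 0.5)
  ## brute force: reversibility folds both branches into one of length 0.5
  sense <- senseCodons(geneticCode(5L))
  Q <- codonRateMatrix(2, 0.5)
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * 0.5)) %*% solve(e$vectors))
  pi <- rep(1 / 62, 62)
  s <- as.character(aln)
  toIdx <- function(x) match(substring(x, seq(1, 13, 3), seq(3, 15, 3)), sense)
  ia <- toIdx(s[["A"]]); ib <- toIdx(s[["B"]])
  brute <- sum(log(mapply(function(a, b) pi[a] * P[a, b], ia, ib)))
  expect_equal(ll, brute, tolerance = 1e-8)
})

test_that("zero-length branches reduce the likelihood to the prior", {
  tr <- ape::read.tree(text = "(A:0,B:0);")
  cds <- c(A = "ATGGCACGA", B = "ATGGCACGA")
  ll <- codonLogLik(cds, tr, kappa = 2, omega = 1)
  expect_equal(ll, 3 * log(1 / 62), tolerance = 1e-9)
})

test_that("the likelihood is invariant to re-rooting (pulley principle)", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,(C:0.3,D:0.05):0.1);")
  aln <- simulateCodonAlignment(tr, omega = 0.3, kappa = 2, nCodons = 60,
                                seed = 9)
  l1 <- codonLogLik(aln, tr, 2, 0.3)
  l2 <- codonLogLik(aln, ape::unroot(tr), 2, 0.3)
  l3 <- codonLogLik(aln, ape::root(ape::unroot(tr), "C", resolve.root = TRUE),
                    2, 0.3)
  expect_equal(l1, l2, tolerance = 1e-9)
  expect_equal(l1, l3, tolerance = 1e-9)
})

test_that("branch-model fits nest and count parameters correctly", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.3):0.1,C:0.4,D:0.4);")
  aln <- simulateCodonAlignment(tr, omega = 0.2, kappa = 2, nCodons = 250,
                                seed = 11)
  f1 <- fitBranchModel(aln, tr, "one_ratio", nStarts = 1)
  f2 <- fitBranchModel(aln, tr, "two_ratios", foreground = "A", nStarts = 1)
  ff <- fitBranchModel(aln, tr, "free_ratios", nStarts = 1)
  expect_gte(ff@logLik, f2@logLik - 1e-4)
  expect_gte(f2@logLik, f1@logLik - 1e-4)
  expect_length(unique(round(omegaEstimates(ff), 10)), 5L)  # one per branch
  expect_equal(ff@nParams, 5L + 1L + 5L)
  expect_equal(f2@nParams, 2L + 1L + 5L)
  expect_equal(f1@nParams, 1L + 1L + 5L)
  ## a 500-codon alignment recovers the generating omega within +-0.1
  aln5 <- simulateCodonAlignment(tr, omega = 0.2, kappa = 2, nCodons = 500,
                                 seed = 12)
  f5 <- fitBranchModel(aln5, tr, "one_ratio", nStarts = 1)
  expect_lt(abs(omegaEstimates(f5)[1] - 0.2), 0.1)
  expect_true(f5@converged)
})

test_that("the likelihood-ratio test uses the chi-square upper tail", {
  lrt0 <- likelihoodRatioTest(fitStub(-100, 7), fitStub(-100, 8))
  expect_equal(lrt0$statistic, 0)
  expect_false(lrt0$significant)
  lrt <- likelihoodRatioTest(fitStub(-102, 7), fitStub(-100, 8))
  expect_equal(lrt$statistic, 4)
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(lrt$p, 4), 0.0455)
  expect_true(lrt$significant)  # 4.0 > 3.84
  expect_warning(likelihoodRatioTest(fitStub(-100, 7), fitStub(-101, 8)),
                 "negative LRT")
  expect_error(likelihoodRatioTest(fitStub(-100, 8), fitStub(-99, 8)),
               "more parameters")
})

test_that("counting-method dN/dS behaves on constructed pairs", {
  a <- paste(rep("ATGGCACGATTTCAA", 20), collapse = "")
  expect_equal(ng86(a, a)$dN, 0)
  expect_equal(ng86(a, a)$dS, 0)
  ## one synonymous third-position change: GCA -> GCG
  b <- sub("ATGGCACGA", "ATGGCGCGA", a)
  r <- ng86(a, b)
  expect_equal(r$Nd, 0)
  expect_equal(r$Sd, 1)
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)
  ## one non-synonymous change: ATG -> ATA at a single codon is M -> M
  ## under the mito code (synonymous!), so use CGA -> CCA (R -> P)
  d <- sub("ATGGCACGA", "ATGGCACCA", a)
  r2 <- ng86(a, d)
  expect_equal(r2$Sd, 0)
  expect_equal(r2$Nd, 1)
  expect_error(ng86("ATG", "ATGAAA"), "equal length")
})

test_that("counting omega stays below one under purifying simulation", {
  tr <- ape::read.tree(text = "(A:0.4,B:0.4);")
  below <- 0L; usable <- 0L
  for (s in 1:60) {
    aln <- simulateCodonAlignment(tr, omega = 0.2, kappa = 2, nCodons = 120,
                                  seed = 9000 + s)
    x <- as.character(aln)
    r <- ng86(x[["A"]], x[["B"]])
    if (!is.na(r$omega)) {
      usable <- usable + 1L
      if (r$omega < 1) below <- below + 1L
    }
  }
  expect_gte(usable, 55L)
  expect_gte(below / usable, 0.95)
})
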