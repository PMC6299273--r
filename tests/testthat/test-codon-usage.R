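test_that("codon families partition the 62 sense codons into 22 classes", {
  fam <- codonFamilies()
  expect_length(fam, 62)
  sizes <- table(fam)
  expect_length(sizes, 22)
  expect_setequal(as.integer(sizes), c(2L, 4L))
  expect_equal(sum(sizes == 4), 9)   # four-fold families
  expect_equal(sum(sizes == 2), 13)  # two-fold families
  expect_equal(unname(fam["TCT"]), "Ser2")
  expect_equal(unname(fam["AGA"]), "Ser1")
  expect_equal(unname(fam["TTA"]), "Leu2")
  expect_equal(unname(fam["CTA"]), "Leu1")
  expect_equal(unname(fam["TGA"]), "Trp")  # TGA is tryptophan, not stop
  expect_equal(unname(fam["ATA"]), "Met")  # ATA is methionine
})

test_that("codon counting excludes terminal stops and flags internal ones", {
  ct <- codonCounts(list(toy = "ATGGGATTTTAA"))
  v <- codonCountsVector(ct)
  expect_equal(sum(v), 3)
  expect_equal(unname(v[c("ATG", "GGA", "TTT")]), c(1, 1, 1))
  expect_false("TAA" %in% names(v)[v > 0])
  expect_error(codonCounts(list()), "empty")
  expect_error(codonCounts(list(bad = "ATGTAAGGGTAA")),
               "internal stop codon in CDS 'bad'")
  ## abbreviated terminal stop is completed, then excluded
  ct2 <- codonCounts(list(ab = "ATGGGAT"))
  expect_equal(sum(codonCountsVector(ct2)), 2)
})

test_that("counts are additive over CDS sets", {
  set.seed(3)
  sense <- setdiff(senseCodons(geneticCode(5L)), c("TAA", "TAG"))
  mk <- function(n) paste(c(sample(sense, n, TRUE), "TAA"), collapse = "")
  a <- mk(30); b <- mk(50)
  joint <- codonCountsVector(codonCounts(list(a = a, b = b)))
  parts <- codonCountsVector(codonCounts(list(a = a))) +
    codonCountsVector(codonCounts(list(b = b)))
  expect_equal(joint, parts)
})

test_that("RSCU normalizes to the family degeneracy", {
  fam <- codonFamilies()
  ala <- names(fam)[fam == "Ala"]
  cds <- paste(c(rep(ala, 1), "TAA"), collapse = "")  # one of each: RSCU 1
  r <- rscu(codonCounts(list(x = cds)))
  expect_equal(r$rscu[r$family == "Ala"], rep(1, 4))
  cds2 <- paste(c(rep(ala[1], 4), "TAA"), collapse = "")
  r2 <- rscu(codonCounts(list(x = cds2)))
  expect_equal(max(r2$rscu[r2$family == "Ala"]), 4)
  expect_true(all(is.na(r2$rscu[r2$family == "Gly"])))  # unused family
  ## property: within-family sums equal the degeneracy when used
  set.seed(7)
  sense <- setdiff(senseCodons(geneticCode(5L)), c("TAA", "TAG"))
  big <- paste(c(sample(sense, 600, TRUE), "TAA"), collapse = "")
  rb <- rscu(codonCounts(list(x = big)))
  sums <- tapply(rb$rscu, rb$family, sum)
  ks <- table(fam)[names(sums)]
  used <- !is.na(sums)
  expect_equal(as.numeric(sums[used]), as.numeric(ks[used]))
})

test_that("the family chi-square matches hand-computed expectations", {
  fam <- codonFamilies()
  two <- names(fam)[fam == "Lys"]  # a two-fold family
  mkTable <- function(counts) {
    v <- stats::setNames(numeric(62), names(fam))
    v[names(counts)] <- counts
    methods::new("CodonCountTable", species = "t", counts = v, families = fam)
  }
  focal <- mkTable(stats::setNames(c(10, 0), two))
  other <- mkTable(stats::setNames(c(0, 10), two))
  res <- familyChisq(focal, other, "Lys")
  expect_equal(res$chi2, 10)       # e = (5,5); (10-5)^2/5 + (0-5)^2/5
  expect_equal(res$df, 1L)
  res0 <- familyChisq(focal, focal, "Lys")
  expect_equal(res0$chi2, 0)
  ## pooled proportions equal focal proportions: chi2 = 0
  f2 <- mkTable(stats::setNames(c(5, 5), two))
  o2 <- mkTable(stats::setNames(c(50, 50), two))
  expect_equal(familyChisq(f2, o2, "Lys")$chi2, 0)
  ## unused family in both species is untestable, never dropped silently
  resAll <- familyChisq(focal, other)
  expect_equal(nrow(resAll), 22L)
  expect_false(resAll$testable[resAll$family == "Ala"])
})

test_that("family chi-square follows the pooled-proportion formula", {
  set.seed(21)
  fam <- codonFamilies()
  for (rep in 1:20) {
    cf <- stats::setNames(rpois(62, 20) + 1, names(fam))
    co <- stats::setNames(rpois(62, 15) + 1, names(fam))
    focal <- methods::new("CodonCountTable", species = "a", counts = cf,
                          families = fam)
    other <- methods::new("CodonCountTable", species = "b", counts = co,
                          families = fam)
    res <- familyChisq(focal, other)
    for (fm in res$family) {
      codons <- names(fam)[fam == fm]
      o <- cf[codons]
      e <- sum(o) * (cf[codons] + co[codons]) / sum(cf[codons] + co[codons])
      expect_equal(res$chi2[res$family == fm], sum((o - e)^2 / e),
                   tolerance = 1e-12)
      expect_equal(res$df[res$family == fm], length(codons) - 1L)
    }
  }
})

test_that("sequential Bonferroni follows the Holm step-down", {
  expect_equal(sequentialBonferroni(c(0.001, 0.02, 0.04)), rep(TRUE, 3))
  expect_equal(sequentialBonferroni(c(0.03, 0.04)), rep(FALSE, 2))
  expect_true(sequentialBonferroni(0.04))
  expect_false(sequentialBonferroni(0.06))
  expect_length(sequentialBonferroni(numeric(0)), 0)
  expect_error(sequentialBonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  ## monotone: a smaller p is rejected whenever a larger one is
  set.seed(5)
  for (k in 1:20) {
    p <- runif(8)
    dec <- sequentialBonferroni(p)
    if (any(dec)) expect_true(all(dec[p <= max(p[dec])]))
  }
})

test_that("start/stop usage tallies the annotated codons of the PCGs", {
  u <- startStopUsage(mneritoidesAnnotationRecord())
  expect_equal(u$stops$percent[u$stops$codon == "TAA"], 77L)
  expect_equal(u$stops$percent[u$stops$codon == "TAG"], 23L)
  expect_equal(u$stops$n, c(10L, 3L))
  expect_equal(u$starts$codon[1], "ATG")  # ATG everywhere except atp6
  expect_equal(u$starts$n[u$starts$codon == "ATT"], 1L)
  feats <- data.frame(name = c("a", "b"), kind = "PCG", strand = "+",
                      start = c(1L, 31L), end = c(30L, 60L),
                      start_codon = "ATG", stop_codon = c("TAA", "TAG"))
  rec <- genomeRecord("toy", strrep("A", 70), feats)
  u2 <- startStopUsage(rec)
  expect_equal(sort(u2$stops$percent), c(50L, 50L))
  feats$stop_codon <- "TAA"
  feats$name <- c("c", "d")
  u3 <- startStopUsage(genomeRecord("t2", strrep("A", 70), feats))
  expect_equal(u3$stops$percent, 100L)
})

test_that("the cross-species usage test reports testable families", {
  set.seed(13)
  fam <- codonFamilies()
  sense <- setdiff(senseCodons(geneticCode(5L)), c("TAA", "TAG"))
  mk <- function(seed) {
    set.seed(seed)
    codonCounts(list(x = paste(c(sample(sense, 800, TRUE), "TAA"),
                               collapse = "")))
  }
  res <- codonUsageTest(mk(1), mk(2))
  expect_equal(nrow(res), 22L)
  expect_equal(attr(res, "n_testable"), sum(res$testable))
  expect_true(all(res$holm_reject[res$holm_reject] <= res$reject_raw[res$holm_reject]))
})
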