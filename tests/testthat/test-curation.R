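test_that("gene geometry reproduces the published littorinid layout", {
  rec <- mneritoidesAnnotationRecord()
  geom <- computeGeneGeometry(rec)
  expect_equal(nrow(geom), nrow(gbFeatures(rec)))  # one gap per feature
  expect_equal(geom$gap[geom$upstream == "nad4l"], -7L)
  expect_equal(geom$gap[geom$upstream == "trnE(ttc)"], 78L)
  s <- geometrySummary(geom)
  expect_equal(s$n_spacers, 23L)
  expect_equal(s$total_spacer_bp, 250L)
  expect_equal(s$n_overlaps, 5L)
  expect_equal(s$max_overlap, -36L)  # rrnL/trnL2
})

test_that("gaps plus feature lengths telescope to the genome length", {
  for (s in 1:5) {
    sim <- makeAnnotatedGenome(seed = s, layout = miniLayout(),
                               abbrevStopGenes = "pcgB")
    rec <- sim$truth
    geom <- computeGeneGeometry(rec)
    f <- gbFeatures(rec)
    expect_identical(sum(geom$gap) + sum(f$end - f$start + 1L),
                     genomeLength(rec))
  }
  rec <- mneritoidesAnnotationRecord()
  geom <- computeGeneGeometry(rec)
  f <- gbFeatures(rec)
  expect_identical(sum(geom$gap) + sum(f$end - f$start + 1L),
                   genomeLength(rec))
})

test_that("abutting features have gap zero", {
  feats <- data.frame(name = c("a", "b"), kind = "tRNA", strand = "+",
                      start = c(1L, 11L), end = c(10L, 20L))
  rec <- genomeRecord("toy", strrep("A", 25), feats)
  geom <- computeGeneGeometry(rec)
  expect_equal(geom$gap, c(0L, 5L))  # abutting pair, then the wrap gap
})

test_that("start selection picks the first eligible non-overlapping codon", {
  seqv <- rep("C", 400)
  for (p in c(75, 93, 126)) seqv[p:(p + 2)] <- c("A", "T", "G")
  feats <- data.frame(name = c("trnX", "pcg"), kind = c("tRNA", "PCG"),
                      strand = "+", start = c(1L, 120L), end = c(80L, 299L),
                      start_codon = c(NA, "CCC"), stop_codon = NA)
  rec <- genomeRecord("toy", paste(seqv, collapse = ""), feats)
  sel <- selectStartCodon(rec, "pcg")
  ## the ATG at 75 overlaps the tRNA (ineligible); 93 is the first eligible
  expect_equal(sel$position, 93L)
  expect_equal(sel$codon, "ATG")
  expect_equal(sel$diff$rule, 1L)
  ## protein-length screening passes over candidates outside the range
  sel2 <- selectStartCodon(rec, "pcg", referenceLength = c(50, 60))
  expect_equal(sel2$position, 126L)
  ## an already-first-eligible annotated start is kept unchanged
  feats$start[2] <- 93L
  feats$start_codon[2] <- "ATG"
  rec2 <- genomeRecord("toy", paste(seqv, collapse = ""), feats)
  sel3 <- selectStartCodon(rec2, "pcg")
  expect_false(sel3$changed)
  expect_null(sel3$diff)
})

test_that("stop resolution scans in frame and stops at the first stop", {
  ## gene at 11..100 (annotated); real first in-frame stop TAG at codon 11,
  ## a later TAA must be ignored
  seqv <- rep("C", 200)
  seqv[11:13] <- c("A", "T", "G")
  seqv[(11 + 33):(13 + 33)] <- c("T", "A", "G")
  seqv[(11 + 60):(13 + 60)] <- c("T", "A", "A")
  feats <- data.frame(name = c("pcg", "trnX"), kind = c("PCG", "tRNA"),
                      strand = "+", start = c(11L, 150L), end = c(100L, 190L),
                      start_codon = c("ATG", NA), stop_codon = NA)
  rec <- genomeRecord("toy", paste(seqv, collapse = ""), feats)
  res <- resolveStopCodon(rec, "pcg")
  expect_equal(res$end, 46L)
  expect_equal(res$stopCodon, "TAG")
})

test_that("abbreviated stops are detected flush against the downstream tRNA", {
  sim <- makeAnnotatedGenome(seed = 2, layout = miniLayout(),
                             abbrevStopGenes = "pcgB")
  f <- gbFeatures(sim$truth)
  expect_equal(f$stop_codon[f$name == "pcgB"], "T--")
  res <- resolveStopCodon(sim$truth, "pcgB")
  expect_false(res$changed)
  expect_equal(res$stopCodon, "T--")
  ## gap to the downstream tRNA is zero by construction
  geom <- computeGeneGeometry(sim$truth)
  expect_equal(geom$gap[geom$upstream == "pcgB"], 0L)
})

test_that("same-strand same-frame PCG overlap is flagged, others pass", {
  rec <- mneritoidesAnnotationRecord()
  v <- checkPcgOverlapLegality(rec)
  nad <- v[v$gene1 == "nad4l", ]
  expect_equal(nad$overlap, 7L)      # 7 mod 3 != 0: different frames
  expect_false(nad$same_frame)
  expect_false(any(v$violation))
  ## constructed same-frame overlap of 6 nt on the same strand
  feats <- data.frame(name = c("p1", "p2"), kind = "PCG", strand = "+",
                      start = c(1L, 94L), end = c(99L, 199L),
                      start_codon = "ATG", stop_codon = "TAA")
  bad <- genomeRecord("toy", strrep("A", 210), feats)
  vb <- checkPcgOverlapLegality(bad)
  expect_true(vb$same_frame)
  expect_true(vb$violation)
  ## opposite strands: legal regardless of frame
  feats$strand <- c("+", "-")
  opp <- genomeRecord("toy", strrep("A", 210), feats)
  expect_false(any(checkPcgOverlapLegality(opp)$violation))
})

test_that("duplicate annotations are resolved by quality", {
  f <- data.frame(name = c("trnL2", "trnL2", "g"), kind = "tRNA",
                  strand = "+", start = c(10L, 60L, 120L),
                  end = c(40L, 90L, 150L),
                  quality = c(0.93, 0.41, 0.5))
  dd <- deduplicateCandidates(f)
  expect_equal(nrow(dd$features), 2L)
  expect_equal(dd$features$quality[dd$features$name == "trnL2"], 0.93)
  expect_equal(dd$diffs$rule, 4L)
  ## tie: keep the earliest by start, warn
  f$quality <- c(0.5, 0.5, 0.2)
  expect_warning(dd2 <- deduplicateCandidates(f), "tie")
  expect_equal(dd2$features$start[dd2$features$name == "trnL2"], 10L)
  ## no duplicates: identity
  dd3 <- deduplicateCandidates(f[2:3, ])
  expect_identical(dd3$features, f[2:3, ])
  expect_equal(nrow(dd3$diffs), 0L)
})

test_that("curation recovers generator ground truth and is idempotent", {
  for (s in 1:10) {
    sim <- makeAnnotatedGenome(seed = s, layout = miniLayout(),
                               abbrevStopGenes = "pcgB",
                               pStartShift = 0.7, pStopShift = 0.7,
                               pDuplicate = 0.4)
    cur <- curateRecord(sim$corrupted)
    expect_identical(gbFeatures(cur$record)[, 1:7],
                     gbFeatures(sim$truth)[, 1:7])
    again <- curateRecord(cur$record)
    expect_equal(nrow(again$diffs), 0L)
    ## clean truth is a fixed point
    expect_equal(nrow(curateRecord(sim$truth)$diffs), 0L)
  }
})

test_that("a duplicated rRNA plus a shifted stop yield rule-4 and rule-3 diffs", {
  sim <- makeAnnotatedGenome(seed = 8)
  f <- gbFeatures(sim$truth)
  dup <- f[f$name == "rrnS", ]
  dup$start <- dup$start + 40L; dup$end <- dup$end + 40L
  dup$quality <- 0.2
  f2 <- rbind(f, dup)
  f2$end[f2$name == "cob"] <- f2$end[f2$name == "cob"] + 6L
  broken <- genomeRecord("broken", genomeSequence(sim$truth), f2)
  cur <- curateRecord(broken)
  expect_setequal(cur$diffs$rule, c(4L, 3L))
  expect_identical(gbFeatures(cur$record)[, 1:7], f[, 1:7])
})

test_that("reference records yield length deltas but are never auto-applied", {
  sim <- makeAnnotatedGenome(seed = 4, layout = miniLayout(),
                             abbrevStopGenes = "pcgB")
  ref <- makeAnnotatedGenome(seed = 14, layout = miniLayout(),
                             abbrevStopGenes = "pcgB")$truth
  cur <- curateRecord(sim$truth, referenceRecords = list(ref))
  expect_equal(nrow(cur$diffs), 0L)  # identical layouts: nothing to change
  expect_s3_class(cur$referenceDeltas, "data.frame")
  expect_true(all(cur$referenceDeltas$delta == 0))
})
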