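# a minimal decomposition object for unit-level projection tests
mkStructDecomp <- function(id, consensusLen, copies = 3L) {
  new("TandemDecomposition", readId = id,
      readLen = as.integer(consensusLen * copies),
      period = as.numeric(consensusLen), copyNumber = as.integer(copies),
      monomerIntervals = IRanges(start = (seq_len(copies) - 1L) *
                                   consensusLen + 1L,
                                 width = consensusLen),
      consensus = strrep("A", consensusLen), meanIdentity = 0.95)
}

test_that("projection bins footprints in the feature frame", {
  b <- sharedBundle()
  f <- refFeatures(b)
  te <- f[f$feature_id == "TE3"]
  sl <- refSeqlengths(b)
  chrom <- as.character(seqnames(te))
  # one molecule spanning the whole 5000-bp feature
  dFull <- mkStructDecomp("mFull", 5000L)
  rFull <- mkRecords(chrom, start(te), end(te), "mFull|1", sl)
  # one molecule equal to the left LTR (first 500 bp)
  dLtr <- mkStructDecomp("mLtr", 500L)
  rLtr <- mkRecords(chrom, start(te), start(te) + 499L, "mLtr|1", sl)
  ems <- projectMolecules(list(dFull, dLtr), c(rFull, rLtr), b)
  info <- as.data.frame(moleculeInfo(ems))
  bins <- moleculeBins(ems)
  iF <- which(info$read_id == "mFull"); iL <- which(info$read_id == "mLtr")
  expect_equal(unname(bins[iF, ]), rep(1, 50))
  expect_equal(info$covered_fraction[iF], 1.0)
  expect_equal(info$class[iF], "fl")
  expect_equal(unname(bins[iL, ]), c(rep(1, 5), rep(0, 45)))
  expect_equal(info$ltr_fraction[iL], 1.0)
  expect_equal(info$class[iL], "tr_LTR")
})

test_that("unassignable molecules are reported with a reason, never dropped silently", {
  b <- sharedBundle()
  sl <- refSeqlengths(b)
  f <- refFeatures(b)
  te3 <- f[f$feature_id == "TE3"]; te4 <- f[f$feature_id == "TE4"]
  dUnmapped <- mkStructDecomp("mNone", 1000L)
  dNoFeat <- mkStructDecomp("mBare", 1000L)
  rBare <- mkRecords("chr1", 5, 1004, "mBare|1", sl)   # outside any feature
  # ambiguous across two different features at mapq 0
  dAmb <- mkStructDecomp("mAmb", 1000L, copies = 3L)
  rAmb <- c(mkRecords(as.character(seqnames(te3)), start(te3), start(te3) + 999L,
                      "mAmb|1", sl, mapq = 0L, primary = TRUE),
            mkRecords(as.character(seqnames(te4)), start(te4), start(te4) + 999L,
                      "mAmb|1", sl, mapq = 0L, primary = FALSE))
  ems <- projectMolecules(list(dUnmapped, dNoFeat, dAmb), c(rBare, rAmb), b)
  una <- as.data.frame(unassignedReads(ems))
  expect_equal(nrow(moleculeInfo(ems)), 0L)
  expect_setequal(una$read_id, c("mNone", "mBare", "mAmb"))
  expect_equal(una$reason[una$read_id == "mNone"], "unmapped")
  expect_equal(una$reason[una$read_id == "mBare"], "no_feature")
  expect_equal(una$reason[una$read_id == "mAmb"], "ambiguous")
  # partition invariant: assigned + unassigned = input molecules
  expect_equal(nrow(moleculeInfo(ems)) + nrow(una), 3L)
})

test_that("within-feature ambiguity (identical LTRs) is rescued and flagged", {
  b <- sharedBundle()
  sl <- refSeqlengths(b)
  te <- refFeatures(b)[refFeatures(b)$feature_id == "TE3"]
  chrom <- as.character(seqnames(te))
  d <- mkStructDecomp("mSolo", 500L)
  recs <- c(mkRecords(chrom, start(te), start(te) + 499L, "mSolo|1", sl,
                      mapq = 0L, primary = TRUE),
            mkRecords(chrom, end(te) - 499L, end(te), "mSolo|1", sl,
                      mapq = 0L, primary = FALSE))
  ems <- projectMolecules(list(d), recs, b)
  info <- as.data.frame(moleculeInfo(ems))
  expect_equal(nrow(info), 1L)
  expect_true(info$ambiguous_within_feature)
  expect_equal(info$class, "tr_LTR")
  expect_equal(info$ltr_fraction, 1.0)
})

test_that("classification thresholds behave as documented", {
  expect_equal(classifyMolecule(1.0, 0.1), "fl")
  expect_equal(classifyMolecule(0.95, 0.0), "fl")
  expect_equal(classifyMolecule(0.1, 1.0), "tr_LTR")
  expect_equal(classifyMolecule(0.3, 0.05), "tr_internal")
  expect_equal(classifyMolecule(0.3, 0.5), "tr_other")
  # fl count monotonically non-increasing as the coverage threshold rises
  set.seed(17)
  cov <- runif(200); ltr <- runif(200)
  nFl <- vapply(seq(0.5, 1, by = 0.05), function(thr)
    sum(classifyMolecule(cov, ltr, flMinCov = thr) == "fl"), numeric(1))
  expect_true(all(diff(nFl) <= 0))
})

test_that("grouping partitions molecules by binarized pattern", {
  b <- sharedBundle()
  sl <- refSeqlengths(b)
  te <- refFeatures(b)[refFeatures(b)$feature_id == "TE3"]
  chrom <- as.character(seqnames(te))
  decs <- list(); recs <- GRangesList()
  for (i in 1:5) {                       # 5 identical full-length molecules
    id <- sprintf("fl%d", i)
    decs[[length(decs) + 1L]] <- mkStructDecomp(id, 5000L)
    recs[[length(recs) + 1L]] <- mkRecords(chrom, start(te), end(te),
                                           paste0(id, "|1"), sl)
  }
  for (i in 1:2) {                       # 2 left-LTR molecules
    id <- sprintf("ltr%d", i)
    decs[[length(decs) + 1L]] <- mkStructDecomp(id, 500L)
    recs[[length(recs) + 1L]] <- mkRecords(chrom, start(te),
                                           start(te) + 499L,
                                           paste0(id, "|1"), sl)
  }
  ems <- projectMolecules(decs, unlist(recs), b)
  g <- groupStructures(ems)
  expect_equal(nrow(g$groups), 2L)
  expect_equal(g$groups$count, c(5L, 2L))          # ordered by count desc
  expect_equal(sum(g$groups$count), nrow(moleculeInfo(ems)))
  expect_equal(length(g$membership), nrow(moleculeInfo(ems)))
  # all-identical input -> a single group
  ems1 <- projectMolecules(decs[1:5], unlist(recs[1:5]), b)
  g1 <- groupStructures(ems1)
  expect_equal(nrow(g1$groups), 1L)
  expect_equal(g1$groups$count, 5L)
  # empty input -> empty grouping
  ems0 <- projectMolecules(list(), unlist(recs)[0], b)
  g0 <- groupStructures(ems0)
  expect_equal(nrow(g0$groups), 0L)
})

test_that("length histograms bin circle sizes left-closed", {
  h <- lengthHistogram(c(5000), binWidth = 250)
  expect_equal(h$bin_start, 5000)
  expect_equal(h$bin_end, 5250)
  expect_equal(h$count, 1L)
  h0 <- lengthHistogram(numeric(0))
  expect_equal(nrow(h0), 0L)
  h2 <- lengthHistogram(c(100, 199, 200), binWidth = 100)
  expect_equal(h2$count, c(2L, 1L))
})

test_that("region coverage ratios flag division by an uncovered region", {
  b <- sharedBundle()
  sl <- refSeqlengths(b)
  te <- refFeatures(b)[refFeatures(b)$feature_id == "TE3"]
  chrom <- as.character(seqnames(te))
  # full-length molecules only: all regions covered equally
  decs <- lapply(1:3, function(i) mkStructDecomp(sprintf("f%d", i), 5000L))
  recs <- do.call(c, lapply(1:3, function(i)
    mkRecords(chrom, start(te), end(te), sprintf("f%d|1", i), sl)))
  ems <- projectMolecules(decs, recs, b)
  rc <- regionCoverageRatio(ems, b, "TE3")
  expect_equal(unname(rc$coverage), c(1, 1, 1))
  expect_true(all(rc$ratios$ratio == 1))
  expect_false(any(rc$ratios$infinite))
  # solo-LTR molecules only: internal coverage 0 -> infinite ratio flag
  decsL <- lapply(1:3, function(i) mkStructDecomp(sprintf("l%d", i), 500L))
  recsL <- do.call(c, lapply(1:3, function(i)
    mkRecords(chrom, start(te), start(te) + 499L, sprintf("l%d|1", i), sl)))
  emsL <- projectMolecules(decsL, recsL, b)
  rcL <- regionCoverageRatio(emsL, b, "TE3")
  expect_equal(unname(rcL$coverage["internal"]), 0)
  li <- rcL$ratios[rcL$ratios$numerator == "left" &
                     rcL$ratios$denominator == "internal", ]
  expect_true(is.infinite(li$ratio))
  expect_true(li$infinite)
})
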