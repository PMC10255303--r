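test_that("window tiling covers each chromosome with a short last window", {
  w <- makeWindows(c(chrX = 1250L), 500L)
  expect_equal(start(w), c(1L, 501L, 1001L))
  expect_equal(end(w), c(500L, 1000L, 1250L))
  w1 <- makeWindows(c(chrX = 500L), 500L)
  expect_equal(length(w1), 1L)
  w2 <- makeWindows(c(a = 1000L, b = 1000L), 500L)
  expect_equal(length(w2), 4L)
  expect_error(makeWindows(c(a = 1000L), 10L), ">= 50")
})

test_that("window counting uses >=1 bp intersect semantics", {
  sl <- c(chr1 = 2000L)
  w <- makeWindows(sl, 500L)
  r1 <- mkRecords("chr1", 251, 1250, "q1", sl)     # spans 3 windows
  r2 <- mkRecords("chr1", 501, 1000, "q2", sl)     # exactly window 2
  se <- windowCounts(list(s = c(r1, r2)), w)
  expect_equal(as.integer(assay(se)[, "s"]), c(1L, 2L, 1L, 0L))
  expect_equal(colData(se)$librarySize, 2L)
})

test_that("window counts equal a brute-force interval overlap", {
  b <- sharedBundle()
  sl <- refSeqlengths(b)
  set.seed(14)
  chroms <- sample(names(sl), 100, replace = TRUE)
  starts <- sapply(chroms, function(ch) sample.int(sl[[ch]] - 3000L, 1))
  lens <- sample(200:3000, 100, replace = TRUE)
  recs <- mkRecords(chroms, starts, starts + lens - 1L,
                    sprintf("q%03d", 1:100), sl)
  w <- makeWindows(b, 500L)
  se <- windowCounts(list(x = recs), w)
  expect_equal(as.integer(assay(se)[, "x"]), oracleWindowCounts(recs, w))
  # conservation: every read counts in >= 1 window, <= ceiling(len/w)+1
  expect_gte(sum(assay(se)[, "x"]), 100)
})

test_that("log2 ratio is pseudocounted, normalized and symmetric", {
  sl <- c(chr1 = 1500L)
  w <- makeWindows(sl, 500L)
  mk <- function(counts, lib) {
    SummarizedExperiment(assays = list(counts = cbind(counts)),
                         rowRanges = w,
                         colData = DataFrame(librarySize = lib))
  }
  se <- SummarizedExperiment(
    assays = list(counts = cbind(a = c(80L, 0L, 5L), b = c(10L, 0L, 5L))),
    rowRanges = w, colData = DataFrame(librarySize = c(100L, 100L)))
  r <- log2RatioTrack(se, "a", "b")
  expect_equal(r[1], log2(81 / 11), tolerance = 1e-12)
  expect_equal(r[2], 0)                 # 0/0 with pseudocount
  expect_equal(r[3], 0)                 # equal normalized counts
  # label swap flips every sign
  expect_equal(log2RatioTrack(se, "b", "a"), -r)
})

test_that("locus calling needs threshold, length and replicate concordance", {
  sl <- c(chr1 = 10000L)
  w <- makeWindows(sl, 500L)
  base <- rep(5L, 20)
  up <- base; up[6:9] <- 300L                      # 2 kb enriched run
  oneWin <- base; oneWin[15] <- 300L               # only 500 bp
  se <- SummarizedExperiment(
    assays = list(counts = cbind(r1 = up, r2 = up, only1 = oneWin,
                                 bg = base)),
    rowRanges = w,
    colData = DataFrame(librarySize = rep(1000L, 4)))
  # background vs itself: nothing called
  expect_equal(length(callEccLoci(se, "bg", "bg")), 0L)
  loci <- callEccLoci(se, c("r1", "r2"), "bg", log2Min = 3, minLen = 1000L)
  expect_equal(length(loci), 1L)
  expect_equal(start(loci), 2501L)
  expect_equal(end(loci), 4500L)
  expect_equal(loci$n_windows_merged, 4L)
  # locus above threshold in one replicate only is not called
  expect_equal(length(callEccLoci(se, c("r1", "only1"), "bg")), 0L)
  # single enriched window fails the length rule
  expect_equal(length(callEccLoci(se, "only1", "bg", minLen = 1000L)), 0L)
})

test_that("per-window Fisher testing flags only enriched windows", {
  sl <- c(chr1 = 5000L)
  w <- makeWindows(sl, 500L)
  cs <- c(60L, 2L, 0L, 3L, 1L, 0L, 2L, 1L, 3L, 2L)
  cc <- c(2L, 2L, 0L, 3L, 1L, 0L, 2L, 1L, 3L, 2L)
  se <- SummarizedExperiment(
    assays = list(counts = cbind(stress = cs, control = cc)),
    rowRanges = w, colData = DataFrame(librarySize = c(500L, 500L)))
  ft <- fisherWindowTest(se, "stress", "control", alpha = 0.01)
  expect_true(ft$significant[1])
  expect_false(any(ft$significant[-1]))
  expect_true(all(is.na(ft$p[cs + cc == 0])))
  expect_true(all(ft$p[!is.na(ft$p)] >= 0 & ft$p[!is.na(ft$p)] <= 1))
  # identical columns: nothing significant
  se2 <- SummarizedExperiment(
    assays = list(counts = cbind(stress = cs, control = cs)),
    rowRanges = w, colData = DataFrame(librarySize = c(500L, 500L)))
  expect_false(any(fisherWindowTest(se2, "stress", "control")$significant))
  # window count above library size is rejected
  se3 <- SummarizedExperiment(
    assays = list(counts = cbind(stress = cs, control = cc)),
    rowRanges = w, colData = DataFrame(librarySize = c(10L, 500L)))
  expect_error(fisherWindowTest(se3, "stress", "control"), "exceeds")
})

test_that("significant windows merge book-ended only, with min p/q and summed counts", {
  sl <- c(chr1 = 5000L)
  w <- makeWindows(sl, 500L)
  sig <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  tested <- granges(w)
  mcols(tested) <- DataFrame(count_stress = seq_len(10) * 10L,
                             count_control = rep(1L, 10),
                             p = seq_len(10) / 1000,
                             q = seq_len(10) / 500,
                             significant = sig)
  pk <- mergeSignificant(tested)
  expect_equal(length(pk), 3L)          # runs {1:3}, {5}, {8:9}
  expect_equal(start(pk), c(1L, 2001L, 3501L))
  expect_equal(pk$p[1], 0.001)
  expect_equal(pk$count_stress[1], 60L)
  expect_equal(pk$n_windows_merged, c(3L, 1L, 2L))
  # empty input -> empty output
  tested$significant <- FALSE
  expect_equal(length(mergeSignificant(tested)), 0L)
})

test_that("peak annotation reports overlapping features and read shares", {
  b <- sharedBundle()
  f <- refFeatures(b)
  te <- f[f$feature_id == "TE3"]
  sl <- refSeqlengths(b)
  inside <- GRanges(seqnames(te), IRanges(start(te) + 100L, start(te) + 1599L))
  nowhere <- GRanges("chr1", IRanges(1, 400))
  pk <- c(inside, nowhere)
  ann <- annotatePeaks(pk, b)
  expect_equal(as.list(ann$feature_ids)[[1]], "TE3")
  expect_equal(length(as.list(ann$feature_ids)[[2]]), 0L)
  # read shares 0.6 / 0.4 over two features
  te4 <- f[f$feature_id == "TE4"]
  recs <- c(mkRecords(as.character(seqnames(te)),
                      rep(start(te), 6), rep(start(te) + 999L, 6),
                      sprintf("a%d", 1:6), sl),
            mkRecords(as.character(seqnames(te4)),
                      rep(start(te4), 4), rep(start(te4) + 999L, 4),
                      sprintf("b%d", 1:4), sl))
  pk2 <- c(granges(te), granges(te4))
  ann2 <- annotatePeaks(pk2, b, recs)
  share <- metadata(ann2)$read_share
  expect_equal(share$share[share$feature_id == "TE3"], 0.6)
  expect_equal(share$share[share$feature_id == "TE4"], 0.4)
})

test_that("replicate concordance counts windows within the log2 band", {
  sl <- c(chr1 = 2000L)
  w <- makeWindows(sl, 500L)
  se <- SummarizedExperiment(
    assays = list(counts = cbind(a = c(10L, 10L, 100L, 0L),
                                 b = c(10L, 12L, 2L, 0L))),
    rowRanges = w, colData = DataFrame(librarySize = c(100L, 100L)))
  frac <- replicateConcordance(se, "a", "b", threshold = 2)
  expect_equal(frac, 0.75)    # the 100-vs-2 window exceeds |log2| = 2
})
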