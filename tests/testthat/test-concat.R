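test_that("period estimation recovers exact repeats and rejects random reads", {
  set.seed(10)
  tmpl <- randomDnaStr(1000)
  p0 <- simParams(subRate = 0, insRate = 0, delRate = 0)
  r <- simulateRcaRead(tmpl, 4, 0, "+", p0)
  expect_equal(estimatePeriod(r), 1000)
  # non-repetitive reads: no period, in agreement with autocorrelation
  set.seed(20)
  for (i in 1:5) {
    rnd <- randomDnaStr(2000)
    expect_true(is.na(estimatePeriod(rnd)))
    expect_true(is.na(oracleAutocorrPeriod(rnd)))
  }
  expect_true(is.na(estimatePeriod(randomDnaStr(150))))  # < 2*minPeriod
  expect_error(estimatePeriod(r, k = 5), "k must")
  expect_error(estimatePeriod(r, minPeriod = 10), "minPeriod")
})

test_that("period estimation tolerates nanopore-level noise", {
  set.seed(30)
  tmpl <- randomDnaStr(1000)
  pn <- simParams(seed = 1)
  for (i in 1:10) {
    r <- simulateRcaRead(tmpl, 5, sample.int(1000, 1) - 1,
                         sample(c("+", "-"), 1), pn)
    p <- estimatePeriod(r)
    expect_false(is.na(p))
    expect_lt(abs(p - 1000), 50)
  }
})

test_that("segmentation places complete monomer boundaries only", {
  set.seed(40)
  tmpl <- randomDnaStr(1000)
  p0 <- simParams(subRate = 0, insRate = 0, delRate = 0)
  r4 <- simulateRcaRead(tmpl, 4, 0, "+", p0)
  iv <- segmentMonomers(r4, 1000)
  expect_equal(start(iv), c(1L, 1001L, 2001L, 3001L))
  expect_equal(end(iv), c(1000L, 2000L, 3000L, 4000L))
  # 3.5 copies: terminal partial copy dropped
  iv35 <- segmentMonomers(substr(r4, 1, 3500), 1000)
  expect_equal(length(iv35), 3L)
  expect_equal(end(iv35)[3], 3000L)
  # noisy 5x: five intervals, each within 10% of the period
  pn <- simParams(seed = 2)
  set.seed(41)
  r5 <- simulateRcaRead(tmpl, 5, 0, "+", pn)
  iv5 <- segmentMonomers(r5, estimatePeriod(r5))
  expect_equal(length(iv5), 5L)
  expect_true(all(abs(width(iv5) - 1000) <= 100))
})

test_that("consensus equals the majority sequence and corrects read noise", {
  set.seed(50)
  tmpl <- randomDnaStr(600)
  p0 <- simParams(subRate = 0, insRate = 0, delRate = 0)
  r <- simulateRcaRead(tmpl, 3, 0, "+", p0)
  iv <- segmentMonomers(r, 600)
  cons <- consensusMonomer(r, iv)
  expect_identical(cons$consensus, tmpl)
  expect_equal(cons$identity, 1)
  # one monomer with a single substitution: majority restores the template
  ch <- strsplit(r, "")[[1]]
  ch[650] <- setdiff(c("A", "C", "G", "T"), ch[650])[1]
  rMut <- paste(ch, collapse = "")
  consMut <- consensusMonomer(rMut, iv)
  expect_identical(consMut$consensus, tmpl)
  expect_error(consensusMonomer(r, iv[1]), "at least 2")
  # 10 monomers at ~10% error: consensus within 1% of the true template
  pn <- simParams(seed = 3)
  set.seed(51)
  tmpl2 <- randomDnaStr(1000)
  r10 <- simulateRcaRead(tmpl2, 10, 0, "+", pn)
  d <- decomposeRead(r10, "r")
  al <- Biostrings::pairwiseAlignment(consensusSeq(d), tmpl2)
  expect_gte(Biostrings::pid(al) / 100, 0.99)
})

test_that("decomposition handles self-similar templates via the period-halving check", {
  # a template that is itself a near-perfect doubled unit must decompose to
  # the fundamental unit
  set.seed(60)
  unit <- randomDnaStr(400)
  tmpl <- paste0(unit, unit)
  p0 <- simParams(subRate = 0, insRate = 0, delRate = 0)
  r <- simulateRcaRead(tmpl, 3, 0, "+", p0)
  d <- decomposeRead(r, "r")
  expect_equal(copyNumber(d), 6L)
  expect_equal(period(d), 400)
})

test_that("concatemer retention follows the copy and length thresholds strictly", {
  mkDecomp <- function(id, len, copies, period = 1000) {
    iv <- if (copies > 0)
      IRanges::IRanges(start = (seq_len(copies) - 1L) * period + 1L,
                       width = period)
    else IRanges::IRanges()
    new("TandemDecomposition", readId = id, readLen = as.integer(len),
        period = as.numeric(period), copyNumber = as.integer(copies),
        monomerIntervals = iv, consensus = "", meanIdentity = NA_real_)
  }
  ds <- list(a = mkDecomp("a", 400, 5, 80),     # too short despite 5 copies
             b = mkDecomp("b", 5000, 1, 5000),  # single copy
             c = mkDecomp("c", 500, 2, 250),    # length not strictly > 500
             d = mkDecomp("d", 501, 2, 250),
             e = mkDecomp("e", 9000, 3, 3000))
  f2 <- filterConcatemers(ds, 2, 500)
  expect_setequal(names(f2$retained), c("d", "e"))
  expect_equal(f2$summary$total, 5L)
  expect_equal(f2$summary$fraction, 0.4)
  f3 <- filterConcatemers(ds, 3, 500)
  expect_setequal(names(f3$retained), "e")
  # monotonicity: the 3-copy set is a subset of the 2-copy set
  expect_true(all(names(f3$retained) %in% names(f2$retained)))
})

test_that("retention on simulated reads equals the truth-table brute force", {
  b <- sharedBundle()
  p <- simParams(seed = 33, nEccReads = 25, nWgsReads = 0,
                 templateMix = c(full_TE = 0.3, solo_LTR = 0, two_LTR = 0,
                                 internal_fragment = 0.5, gene_circle = 0.2),
                 featureIds = c("TE3", "TE4", "gene1", "gene2"))
  sim <- simulateSamples(b, p)
  dec <- decomposeReads(sim$reads$ecc_rep1, buildConsensus = FALSE)
  tab <- as.data.frame(decompositionTable(dec))
  truth <- sim$truth[sim$truth$sample == "ecc_rep1", ]
  m <- merge(tab, truth, by = "read_id")
  for (minCopies in 2:3) {
    kept <- names(filterConcatemers(dec, minCopies, 500)$retained)
    bruteExpected <- m$read_id[m$copy_number >= minCopies & m$read_len > 500]
    expect_setequal(kept, bruteExpected)
    # and the decomposition itself agrees with the simulation truth for
    # actual concatemers (single-copy reads legitimately yield no repeat)
    conc <- m$true_copy_number >= 2
    expect_gte(mean((m$copy_number == m$true_copy_number)[conc]), 0.9)
  }
})

test_that("decomposition tables round-trip through TSV", {
  set.seed(70)
  tmpl <- randomDnaStr(500)
  p0 <- simParams(subRate = 0, insRate = 0, delRate = 0)
  r <- simulateRcaRead(tmpl, 3, 0, "+", p0)
  d <- decomposeRead(r, "rt1")
  path <- tempfile(fileext = ".tsv")
  writeDecompositionTable(list(rt1 = d), path)
  back <- readDecompositionTable(path)
  expect_equal(readId(back[[1]]), "rt1")
  expect_equal(copyNumber(back[[1]]), 3L)
  expect_identical(consensusSeq(back[[1]]), consensusSeq(d))
})
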