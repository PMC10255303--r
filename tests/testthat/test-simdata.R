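test_that("makeReference builds the requested features with end-terminal LTRs", {
  b <- sharedBundle()
  f <- refFeatures(b)
  expect_s4_class(b, "ReferenceBundle")
  expect_true(validObject(b))
  expect_equal(sum(f$feature_class == "TE"), 4L)
  expect_equal(sum(width(refSeqs(b))), 200000L)
  for (i in which(f$feature_class == "TE")) {
    rel <- f$ltr_rel[[i]]
    expect_equal(start(rel), c(1L, 4501L))
    expect_equal(end(rel), c(500L, 5000L))
  }
  # multi-copy family: TE1 and TE2 are near-identical (>= 95%)
  s1 <- makeCircleTemplate(b, "full_TE", "TE1")$seq
  s2 <- makeCircleTemplate(b, "full_TE", "TE2")$seq
  al <- Biostrings::pairwiseAlignment(s1, s2)
  expect_gte(Biostrings::pid(al) / 100, 0.95)
  expect_lt(Biostrings::pid(al) / 100, 1)
})

test_that("makeReference is deterministic and rejects impossible packings", {
  d1 <- tempfile(); d2 <- tempfile()
  writeReference(makeReference(9, 1, 30000, 2, 3000, 300), d1)
  writeReference(makeReference(9, 1, 30000, 2, 3000, 300), d2)
  for (f in c("reference.fasta", "features.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_error(makeReference(1, 1, 10000, 4, 5000, 500), "packing")
  expect_error(makeReference(1, 1, 10000, 1, 1000, 600), "ltrLen")
})

test_that("circle templates have the expected content per kind", {
  b <- sharedBundle()
  set.seed(1)
  expect_equal(nchar(makeCircleTemplate(b, "full_TE", "TE1")$seq), 5000L)
  expect_equal(nchar(makeCircleTemplate(b, "solo_LTR", "TE1")$seq), 500L)
  two <- makeCircleTemplate(b, "two_LTR", "TE1")$seq
  expect_equal(nchar(two), 1000L)
  # two_LTR is the concatenation of both (identical) LTR copies
  expect_equal(substr(two, 1, 500), substr(two, 501, 1000))
  g <- makeCircleTemplate(b, "gene_circle", "gene1")
  expect_equal(nchar(g$seq), 2000L)
  expect_error(makeCircleTemplate(b, "gene_circle", "TE1"), "gene feature")
  expect_error(makeCircleTemplate(b, "solo_LTR", "gene1"), "TE feature")
  expect_error(makeCircleTemplate(b, "banana", "TE1"))
})

test_that("error-free RCA reads are exact rotated tandem repeats", {
  p0 <- simParams(subRate = 0, insRate = 0, delRate = 0)
  expect_equal(simulateRcaRead("ACGT", 3, 0, "+", p0), "ACGTACGTACGT")
  expect_equal(simulateRcaRead("ACGT", 2, 2, "+", p0), "GTACGTAC")
  expect_equal(simulateRcaRead("AACG", 1, 0, "-", p0), "CGTT")
  expect_error(simulateRcaRead("ACGT", 0, 0, "+", p0), "copyN")
  expect_error(simulateRcaRead("ACGT", 2, 4, "+", p0), "phase")
})

test_that("the error model hits its expected length and identity", {
  set.seed(1)
  tmpl <- randomDnaStr(1000)
  p <- simParams(seed = 1, subRate = 0.05, insRate = 0, delRate = 0)
  clean <- simulateRcaRead(tmpl, 5, 0, "+",
                           simParams(subRate = 0, insRate = 0, delRate = 0))
  set.seed(2)
  idents <- replicate(100, {
    r <- simulateRcaRead(tmpl, 5, 0, "+", p)
    mean(strsplit(r, "")[[1]] == strsplit(clean, "")[[1]])
  })
  expect_equal(nchar(simulateRcaRead(tmpl, 5, 0, "+", p)), 5000L)
  expect_equal(mean(idents), 0.95, tolerance = 0.01)
  # indels shift the expected length by (ins - del) per base
  set.seed(3)
  pI <- simParams(subRate = 0, insRate = 0.05, delRate = 0)
  lens <- replicate(50, nchar(simulateRcaRead(tmpl, 5, 0, "+", pI)))
  expect_equal(mean(lens) / 5000, 1.05, tolerance = 0.01)
})

test_that("simulateSamples is deterministic, truth-consistent and honors the mix", {
  b <- sharedBundle()
  p <- simParams(seed = 21, nEccReads = 5, nWgsReads = 8)
  s1 <- simulateSamples(b, p)
  s2 <- simulateSamples(b, p)
  expect_identical(as.character(s1$reads$ecc_rep1),
                   as.character(s2$reads$ecc_rep1))
  expect_identical(s1$truth, s2$truth)
  # truth-consistency: one record per read, ids match exactly
  allIds <- unlist(lapply(s1$reads, names), use.names = FALSE)
  expect_setequal(s1$truth$read_id, allIds)
  expect_equal(nrow(s1$truth), length(allIds))
  # FASTQ output is byte-identical across runs
  d1 <- tempfile(); d2 <- tempfile()
  simulateSamples(b, p, d1); simulateSamples(b, p, d2)
  expect_identical(readLines(file.path(d1, "ecc_rep2.fastq")),
                   readLines(file.path(d2, "ecc_rep2.fastq")))
  # zero reads -> empty FASTQ, header-only truth
  s0 <- simulateSamples(b, simParams(seed = 1, nEccReads = 0, nWgsReads = 0))
  expect_equal(nrow(s0$truth), 0L)
  expect_equal(length(s0$reads$ecc_rep1), 0L)
  # single-template mix: every ecc truth record references TE1
  pT <- simParams(seed = 4, nEccReads = 6, nWgsReads = 0,
                  templateMix = c(full_TE = 1, solo_LTR = 0, two_LTR = 0,
                                  internal_fragment = 0, gene_circle = 0),
                  featureIds = "TE1")
  sT <- simulateSamples(b, pT)
  expect_true(all(sT$truth$feature_id == "TE1"))
  expect_true(all(sT$truth$kind == "full_TE"))
})

test_that("simulator parameter validation rejects out-of-range values", {
  expect_error(simParams(subRate = 1.2), "subRate")
  expect_error(simParams(templateMix = c(full_TE = 2, solo_LTR = 0,
                                         two_LTR = 0, internal_fragment = 0,
                                         gene_circle = 0)), "sum to 1")
  expect_error(simParams(nEccReads = -1), "counts")
})
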