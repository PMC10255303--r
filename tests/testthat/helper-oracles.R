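# shared fixtures and independent oracles, built in code at test time

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
  library(SummarizedExperiment)
})

randomDnaStr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# memoized default synthetic reference shared across tests
sharedBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeReference(1, 2, 100000, 4, 5000, 500)
    cache
  }
})

# independent period oracle: exhaustive autocorrelation (match fraction at
# every lag); returns the best lag or NA when nothing repeats convincingly
oracleAutocorrPeriod <- function(read, minPeriod = 100, maxPeriod = NULL) {
  ch <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (is.null(maxPeriod)) maxPeriod <- floor(n / 2)
  if (maxPeriod < minPeriod) return(NA_real_)
  frac <- vapply(minPeriod:maxPeriod, function(lag)
    mean(ch[1:(n - lag)] == ch[(lag + 1):n]), numeric(1))
  best <- which.max(frac)
  if (frac[best] >= 0.8) (minPeriod:maxPeriod)[best] else NA_real_
}

# independent two-sided Fisher oracle: full hypergeometric enumeration via
# stats::dhyper (R's own C implementation, not the package's lchoose route)
oracleFisher <- function(a, b, cc, d) {
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(x, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# brute-force interval-overlap window counter
oracleWindowCounts <- function(records, windows) {
  out <- integer(length(windows))
  for (i in seq_along(windows)) {
    for (j in seq_along(records)) {
      if (as.character(seqnames(windows)[i]) ==
            as.character(seqnames(records)[j]) &&
          start(records)[j] <= end(windows)[i] &&
          end(records)[j] >= start(windows)[i])
        out[i] <- out[i] + 1L
    }
  }
  out
}

# construct alignment records directly (unit-level inputs for peaks/structure)
mkRecords <- function(chrom, start, end, qid, seqlengths,
                      mapq = 60L, primary = TRUE, strand = "+",
                      qstart = 0L) {
  n <- length(start)
  gr <- GRanges(chrom, IRanges(start, end), strand = strand,
                seqlengths = seqlengths)
  mcols(gr) <- DataFrame(query_id = qid,
                         query_start = rep(as.integer(qstart), n),
                         query_end = as.integer(qstart + (end - start + 1L)),
                         query_len = as.integer(end - start + 1L),
                         mapq = rep(as.integer(mapq), length.out = n),
                         is_primary = rep(primary, length.out = n),
                         identity = rep(1, n))
  gr
}

# run the structure branch (decompose -> monomers -> map -> project) on one
# simulated eccDNA sample; returns molecules merged with the truth table
runStructureBranch <- function(bundle, sim, sample = "ecc_rep1",
                               minCopies = 3L) {
  dec <- decomposeReads(sim$reads[[sample]])
  kept <- filterConcatemers(dec, minCopies, 500)$retained
  if (!length(kept)) return(NULL)
  monomers <- do.call(c, unname(lapply(kept, function(d)
    monomerSeqs(d, sim$reads[[sample]][[readId(d)]]))))
  monRecs <- mapReads(monomers, bundle)
  ems <- projectMolecules(kept, monRecs, bundle)
  info <- as.data.frame(moleculeInfo(ems))
  truth <- sim$truth[sim$truth$sample == sample, ]
  list(ems = ems, merged = merge(info, truth, by = "read_id"))
}

expectedClassOfKind <- c(full_TE = "fl", solo_LTR = "tr_LTR",
                         two_LTR = "tr_LTR", internal_fragment = "tr_internal",
                         gene_circle = "fl")
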