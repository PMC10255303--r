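#' Estimate the tandem monomer period of a read
#'
#' Collects the distances between consecutive occurrences of every repeated
#' k-mer along the read and returns the dominant distance mode. Support for
#' a candidate period is the number of k-mer pair distances within +/-10\%
#' of it; ties are broken towards the smaller period (the fundamental period
#' is preferred over its multiples). If both a period p and p/2 are
#' supported and the two halves of a p-length window align at >= 90\%
#' identity, p/2 is returned. Periods below \code{minPeriod} are treated as
#' low-complexity repeats and skipped.
#'
#' @param read read sequence (character, \code{DNAString} or length-1
#'   \code{DNAStringSet}).
#' @param k k-mer size in [8, 21].
#' @param minPeriod,maxPeriod search bounds (bp), \code{minPeriod >= 50}.
#' @param minSupport minimum number of supporting k-mer pair distances.
#' @return the period estimate (bp) or \code{NA} when no tandem structure
#'   is found (including reads shorter than \code{2*minPeriod}).
#' @export
estimatePeriod <- function(read, k = 13L, minPeriod = 100L,
                           maxPeriod = 50000L, minSupport = 5L) {
  if (k < 8L || k > 21L) stop("k must lie in [8, 21]")
  if (minPeriod < 50L) stop("minPeriod must be >= 50")
  read <- .asSeqChar(read)[1]
  n <- nchar(read)
  if (n < 2L * minPeriod) return(NA_real_)

  km <- substring(read, 1:(n - k + 1L), k:n)
  o <- order(km, method = "radix")
  sameKmer <- km[o][-1L] == km[o][-length(o)]
  d <- diff(o)[sameKmer]           # consecutive-occurrence distances
  d <- d[d >= minPeriod & d <= maxPeriod]
  if (length(d) < minSupport) return(NA_real_)

  ds <- sort(d)
  vals <- unique(ds)
  lo <- findInterval(vals * 0.9 - 1e-9, ds)          # < lower bound
  hi <- findInterval(vals * 1.1 + 1e-9, ds)
  supp <- hi - lo
  best <- vals[supp == max(supp)]
  best <- min(best)                                   # ties -> smaller period
  inWin <- ds >= best * 0.9 & ds <= best * 1.1
  est <- median(ds[inWin])

  # fundamental-period check: is est actually 2x the true period?
  halfIdx <- which(vals >= est / 2 * 0.9 & vals <= est / 2 * 1.1)
  if (length(halfIdx) && max(supp[halfIdx]) >= minSupport) {
    p <- round(est)
    if (n >= p) {
      win <- substr(read, 1L, p)
      h1 <- substr(win, 1L, p %/% 2L)
      h2 <- substr(win, p %/% 2L + 1L, p)
      al <- cpp_band_global(h1, h2, max(30L, round(0.1 * nchar(h1))))
      if (al$identity >= 0.9) {
        halfVals <- ds[ds >= est / 2 * 0.9 & ds <= est / 2 * 1.1]
        est <- median(halfVals)
      }
    }
  }
  as.numeric(est)
}

#' Segment a read into complete monomer intervals
#'
#' A representative anchor window of one period length is taken from the
#' read start, candidate monomer starts are located by clustering the
#' diagonals of exact k-mer matches between anchor and read, and each
#' candidate is refined by a banded fit alignment of the anchor, which
#' places the boundary. Only complete monomers are kept: terminal partial
#' copies fail the fit (identity or length) and are discarded. If accepted
#' boundaries drift by more than 20\% of the period the read is rejected
#' with reason \code{"period_drift"}.
#'
#' @param read read sequence.
#' @param period period estimate from \code{\link{estimatePeriod}}.
#' @param minIdent minimum fit identity to accept a monomer occurrence
#'   (0.6 tolerates two ~10\%-error copies aligned to each other).
#' @param kSeg k-mer size for the coarse diagonal vote.
#' @return \code{IRanges} of complete monomer intervals (1-based, closed),
#'   with attributes \code{period} (refined estimate) and, when rejected,
#'   \code{reason}.
#' @export
segmentMonomers <- function(read, period, minIdent = 0.6, kSeg = 11L) {
  read <- .asSeqChar(read)[1]
  n <- nchar(read)
  p <- as.integer(round(period))
  empty <- function(reason = NULL) {
    out <- IRanges()
    attr(out, "period") <- NA_real_
    if (!is.null(reason)) attr(out, "reason") <- reason
    out
  }
  if (is.na(p) || p < 50L || n < p) return(empty("period_invalid"))
  anchor <- substr(read, 1L, p)

  # coarse: diagonals of anchor k-mer matches across the whole read
  akm <- substring(anchor, 1:(p - kSeg + 1L), kSeg:p)
  rkm <- substring(read, 1:(n - kSeg + 1L), kSeg:n)
  hit <- match(rkm, akm)
  ok <- !is.na(hit)
  diag <- which(ok) - hit[ok]                 # read pos - anchor pos (0-based)
  if (!length(diag)) return(empty("no_anchor_match"))
  # candidate starts: density peaks of the diagonal distribution (binned
  # histogram; sparse random k-mer matches cannot bridge clusters)
  bw <- max(50L, as.integer(0.05 * p))
  bin <- floor(diag / bw)
  tab <- table(bin)
  # absolute support threshold: random k-mer matches rarely stack 3 deep in
  # one bin, and the banded fit alignment rejects any spurious candidate
  strong <- as.integer(names(tab))[tab >= 3L]
  strong <- sort(strong)
  grp <- cumsum(c(1L, diff(strong) > 1L))
  cand <- vapply(split(strong, grp), function(bs)
    median(diag[bin %in% bs]), numeric(1))
  cand <- sort(unique(c(0L, round(cand))))
  cand <- cand[cand > -0.2 * p & cand <= n - 0.5 * p]

  band <- max(60L, as.integer(0.04 * p))
  occ <- matrix(numeric(0), ncol = 3L)        # start, end (0-based ho), ident
  for (s in cand) {
    fit <- cpp_fit_align(anchor, read, as.integer(s), band)
    len <- fit$tend - fit$tstart
    if (fit$tstart >= 0 && fit$identity >= minIdent &&
        len >= 0.8 * p && len <= 1.2 * p) {
      occ <- rbind(occ, c(fit$tstart, fit$tend, fit$identity))
    }
  }
  if (!nrow(occ)) return(empty("no_monomer_fit"))
  occ <- occ[order(occ[, 1L]), , drop = FALSE]
  # candidates refined to the same occurrence: keep the best fit
  if (nrow(occ) > 1L) {
    keep <- rep(TRUE, nrow(occ))
    for (i in 2:nrow(occ)) {
      prev <- max(which(keep[1:(i - 1L)]))
      if (occ[i, 1L] - occ[prev, 1L] <= 0.5 * p) {
        if (occ[i, 3L] > occ[prev, 3L]) keep[prev] <- FALSE else keep[i] <- FALSE
      }
    }
    occ <- occ[keep, , drop = FALSE]
  }
  starts <- occ[, 1L]

  spacing <- diff(starts)
  goodSpacing <- spacing[spacing >= 0.8 * p & spacing <= 1.2 * p]
  medSpacing <- if (length(goodSpacing)) median(goodSpacing) else p

  ivStart <- integer(0); ivEnd <- integer(0)
  if (length(starts) > 1L) {
    for (i in seq_len(length(starts) - 1L)) {
      gap <- starts[i + 1L] - starts[i]
      if (gap >= 0.8 * medSpacing && gap <= 1.2 * medSpacing) {
        ivStart <- c(ivStart, starts[i]); ivEnd <- c(ivEnd, starts[i + 1L])
      }
    }
  }
  # terminal complete copy
  last <- starts[length(starts)]
  if (n - last >= 0.9 * medSpacing) {
    ivStart <- c(ivStart, last)
    ivEnd <- c(ivEnd, min(n, last + round(medSpacing)))
  } else if (length(starts) == 1L) {
    # single occurrence, read too short for a second complete copy
    ivStart <- c(ivStart, last)
    ivEnd <- c(ivEnd, min(n, occ[nrow(occ), 2L]))
  }
  if (!length(ivStart)) return(empty("no_complete_monomer"))
  out <- IRanges(start = as.integer(ivStart) + 1L, end = as.integer(ivEnd))
  if (any(width(out) < 0.8 * medSpacing | width(out) > 1.2 * medSpacing))
    return(empty("period_drift"))
  attr(out, "period") <- as.numeric(medSpacing)
  out
}

#' Build the consensus monomer of a decomposed read
#'
#' Star alignment around the medoid monomer: the medoid (maximal mean
#' pairwise identity to the other monomers) is chosen, every monomer is
#' aligned to it with a banded global alignment, and each medoid column is
#' called by majority vote (ties keep the medoid base). Majority-supported
#' insertions between medoid columns are retained, so bases missing from
#' the medoid by sequencing deletion are recovered. The returned identity
#' is the mean identity of the monomers to the finished consensus.
#'
#' @param read read sequence.
#' @param intervals \code{IRanges} of >= 2 monomer intervals
#'   (from \code{\link{segmentMonomers}}).
#' @param maxMedoidCandidates cap on medoid candidates for long reads.
#' @return list with \code{consensus} (character) and \code{identity}.
#' @export
consensusMonomer <- function(read, intervals, maxMedoidCandidates = 8L) {
  read <- .asSeqChar(read)[1]
  m <- length(intervals)
  if (m < 2L) stop("consensus requires at least 2 monomer intervals")
  mono <- substring(read, start(intervals), end(intervals))
  band <- max(40L, as.integer(0.03 * max(nchar(mono))) + 20L)

  # medoid: maximal mean identity against the others
  candIdx <- if (m > maxMedoidCandidates)
    unique(round(seq(1L, m, length.out = maxMedoidCandidates)))
  else seq_len(m)
  meanIdent <- vapply(candIdx, function(i) {
    others <- setdiff(seq_len(m), i)
    if (length(others) > 6L)
      others <- others[unique(round(seq(1L, length(others),
                                        length.out = 6L)))]
    mean(vapply(others, function(j)
      cpp_band_global(mono[i], mono[j], band)$identity, numeric(1)))
  }, numeric(1))
  medoid <- candIdx[which.max(meanIdent)]
  ref <- mono[medoid]
  L <- nchar(ref)
  refCh <- strsplit(ref, "", fixed = TRUE)[[1]]

  # per-medoid-column votes of every monomer (the medoid votes for itself)
  colsMat <- matrix("", nrow = L, ncol = m)
  insMat <- matrix("", nrow = L + 1L, ncol = m)
  colsMat[, medoid] <- refCh
  for (i in setdiff(seq_len(m), medoid)) {
    al <- cpp_align_cols(ref, mono[i], band)
    if (!isTRUE(al$ok)) next
    colsMat[, i] <- al$cols
    insMat[, i] <- al$ins
  }
  alphabet <- c("A", "C", "G", "T", "-")
  cnt <- vapply(alphabet, function(b) rowSums(colsMat == b),
                numeric(L))                  # L x 5
  rowMax <- do.call(pmax, as.data.frame(cnt))
  medCnt <- cnt[cbind(seq_len(L), match(refCh, alphabet))]
  base <- ifelse(medCnt >= rowMax, refCh,
                 alphabet[max.col(cnt, ties.method = "first")])
  # insertion slots: only rows where a majority of monomers insert can win
  insOut <- rep("", L + 1L)
  hot <- which(rowSums(insMat != "") * 2L > m)
  for (s in hot) {
    tab <- sort(table(insMat[s, ]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    insOut[s] <- if (length(top) > 1L && "" %in% top) "" else top[1]
  }
  keepBase <- base != "-"
  consensus <- paste0(paste0(insOut[seq_len(L)],
                             ifelse(keepBase, base, "")), collapse = "")
  consensus <- paste0(consensus, insOut[L + 1L])

  idents <- vapply(mono, function(x)
    cpp_band_global(consensus, x, band)$identity, numeric(1))
  list(consensus = consensus, identity = mean(idents))
}

#' Decompose one read into its tandem monomer structure
#'
#' Runs period estimation, monomer segmentation and consensus construction.
#' After the consensus is built, a fundamental-period check is applied to
#' the error-corrected sequence: if its two halves align at >= 90\%
#' identity the period is halved and the read re-segmented (raw-read noise
#' can mask a period that is actually half the first estimate).
#'
#' @param read read sequence.
#' @param readId read identifier.
#' @param k,minPeriod,maxPeriod,minSupport passed to
#'   \code{\link{estimatePeriod}}.
#' @param buildConsensus build the consensus monomer (default). With
#'   \code{FALSE} only period, copy number and monomer intervals are
#'   computed (cheaper for large screens); the fundamental-period check
#'   then runs on a raw monomer window with a noise-tolerant 0.7 identity
#'   threshold instead of 0.9 on the consensus.
#' @return a \code{\linkS4class{TandemDecomposition}}; reads without tandem
#'   structure yield \code{copyNumber} 0 and an \code{NA} period.
#' @export
decomposeRead <- function(read, readId = "read", k = 13L, minPeriod = 100L,
                          maxPeriod = 50000L, minSupport = 5L,
                          buildConsensus = TRUE) {
  read <- .asSeqChar(read)[1]
  n <- nchar(read)
  emptyDecomp <- function() {
    new("TandemDecomposition", readId = readId, readLen = as.integer(n),
        period = NA_real_, copyNumber = 0L, monomerIntervals = IRanges(),
        consensus = "", meanIdentity = NA_real_)
  }
  p <- estimatePeriod(read, k = k, minPeriod = minPeriod,
                      maxPeriod = maxPeriod, minSupport = minSupport)
  if (is.na(p)) return(emptyDecomp())

  buildAt <- function(p) {
    iv <- segmentMonomers(read, p)
    if (!length(iv)) return(NULL)
    if (buildConsensus && length(iv) >= 2L) {
      cons <- consensusMonomer(read, iv)
    } else {
      cons <- list(consensus = if (buildConsensus)
        substring(read, start(iv), end(iv)) else "",
        identity = NA_real_)
    }
    list(iv = iv, cons = cons, period = attr(iv, "period"))
  }
  res <- buildAt(p)
  if (is.null(res)) return(emptyDecomp())

  # fundamental-period check: on the error-corrected consensus at 0.9, or
  # on a raw monomer window at a noise-tolerant 0.7 when no consensus is
  # built (two ~10%-error copies align at ~0.8, random halves at ~0.5)
  for (iter in 1:2) {
    if (buildConsensus) {
      cs <- res$cons$consensus
      thr <- 0.9
    } else {
      iv1 <- res$iv[1]
      cs <- substring(read, start(iv1), end(iv1))
      thr <- 0.7
    }
    cl <- nchar(cs)
    if (cl < 2L * minPeriod) break
    h1 <- substr(cs, 1L, cl %/% 2L)
    h2 <- substr(cs, cl %/% 2L + 1L, cl)
    al <- cpp_band_global(h1, h2, max(30L, round(0.1 * nchar(h1))))
    if (al$identity < thr) break
    res2 <- buildAt(res$period / 2)
    if (is.null(res2) || length(res2$iv) < 2L * length(res$iv) - 1L) break
    res <- res2
  }

  new("TandemDecomposition", readId = readId, readLen = as.integer(n),
      period = as.numeric(res$period), copyNumber = length(res$iv),
      monomerIntervals = res$iv, consensus = res$cons$consensus,
      meanIdentity = res$cons$identity)
}

#' Decompose a set of reads
#'
#' @param reads named character vector or \code{DNAStringSet}.
#' @param ... passed to \code{\link{decomposeRead}}.
#' @return named list of \code{\linkS4class{TandemDecomposition}}.
#' @export
decomposeReads <- function(reads, ...) {
  sq <- .asSeqChar(reads)
  ids <- names(sq)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(sq))
  out <- lapply(seq_along(sq), function(i)
    decomposeRead(sq[i], readId = ids[i], ...))
  names(out) <- ids
  out
}

#' Summarize decompositions as a table
#'
#' @param decomps list of \code{\linkS4class{TandemDecomposition}}.
#' @return \code{DataFrame} with one row per read.
#' @export
decompositionTable <- function(decomps) {
  DataFrame(
    read_id = vapply(decomps, readId, character(1)),
    read_len = vapply(decomps, function(d) d@readLen, integer(1)),
    period = vapply(decomps, period, numeric(1)),
    copy_number = vapply(decomps, copyNumber, integer(1)),
    mean_identity = vapply(decomps, meanIdentity, numeric(1)),
    consensus_len = vapply(decomps, function(d) nchar(d@consensus),
                           integer(1)))
}

#' Apply the concatemer read-retention filter
#'
#' A read is retained when it holds at least \code{minCopies} complete
#' tandem monomer copies and its length strictly exceeds
#' \code{minReadLen}. Peak calling uses \code{minCopies = 2}; structure
#' analysis, which needs more evidence per molecule, uses
#' \code{minCopies = 3}.
#'
#' @param decomps list of \code{\linkS4class{TandemDecomposition}}.
#' @param minCopies minimum complete monomer copies.
#' @param minReadLen read length threshold (strict >).
#' @return list with \code{retained} (sub-list) and \code{summary}
#'   (total, retained, fraction).
#' @export
filterConcatemers <- function(decomps, minCopies = 2L, minReadLen = 500L) {
  keep <- vapply(decomps, function(d)
    copyNumber(d) >= minCopies && d@readLen > minReadLen, logical(1))
  list(retained = decomps[keep],
       summary = list(total = length(decomps), retained = sum(keep),
                      fraction = if (length(decomps)) mean(keep) else NA_real_))
}

#' Extract the monomer sequences of a decomposition
#'
#' Used by structure mode, where individual monomers (not whole reads) are
#' mapped. Names are \code{<read_id>|<i>}.
#'
#' @param decomp a \code{\linkS4class{TandemDecomposition}}.
#' @param read the read sequence the decomposition refers to.
#' @return \code{DNAStringSet} of monomer sequences.
#' @export
monomerSeqs <- function(decomp, read) {
  read <- .asSeqChar(read)[1]
  iv <- monomerIntervals(decomp)
  if (!length(iv)) return(DNAStringSet())
  s <- substring(read, start(iv), end(iv))
  names(s) <- sprintf("%s|%d", readId(decomp), seq_along(iv))
  DNAStringSet(s)
}

#' Write / read a decomposition summary TSV
#'
#' The TSV (read_id, read_len, period, copy_number, mean_identity,
#' consensus) is also the ingestion point for consensus tables produced by
#' an external concatemer caller.
#'
#' @param decomps list of \code{\linkS4class{TandemDecomposition}}.
#' @param path TSV path.
#' @export
writeDecompositionTable <- function(decomps, path) {
  df <- as.data.frame(decompositionTable(decomps))
  df$consensus <- vapply(decomps, consensusSeq, character(1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDecompositionTable
#' @return \code{readDecompositionTable}: named list of minimal
#'   \code{\linkS4class{TandemDecomposition}} objects (no monomer
#'   intervals; consensus and copy number as given).
#' @export
readDecompositionTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "copy_number", "consensus")
  if (!all(need %in% names(df)))
    stop("decomposition table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    new("TandemDecomposition", readId = df$read_id[i],
        readLen = if ("read_len" %in% names(df)) as.integer(df$read_len[i])
                  else nchar(df$consensus[i]) * as.integer(df$copy_number[i]),
        period = if ("period" %in% names(df)) as.numeric(df$period[i])
                 else as.numeric(nchar(df$consensus[i])),
        copyNumber = 0L, monomerIntervals = IRanges(),
        consensus = df$consensus[i],
        meanIdentity = if ("mean_identity" %in% names(df))
          as.numeric(df$mean_identity[i]) else NA_real_)
  })
  # copy number is carried via a rebuild to satisfy the interval invariant
  for (i in seq_along(out)) {
    d <- out[[i]]
    cn <- as.integer(df$copy_number[i])
    w <- nchar(d@consensus)
    iv <- if (cn > 0L && w > 0L)
      IRanges(start = seq_len(cn) * w - w + 1L, width = w) else IRanges()
    out[[i]] <- new("TandemDecomposition", readId = d@readId,
                    readLen = d@readLen, period = d@period, copyNumber = cn,
                    monomerIntervals = iv, consensus = d@consensus,
                    meanIdentity = d@meanIdentity)
  }
  names(out) <- df$read_id
  out
}
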