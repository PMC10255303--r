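#' Tile a genome into fixed-width windows
#'
#' Windows start at 0, w, 2w, ... on every chromosome; the last window of a
#' chromosome may be short.
#'
#' @param x a \code{\linkS4class{ReferenceBundle}} or named vector of
#'   chromosome lengths.
#' @param w window width (bp), \code{>= 50}.
#' @return \code{GRanges} of windows.
#' @export
makeWindows <- function(x, w = 500L) {
  if (w < 50L) stop("window width must be >= 50")
  sl <- if (is(x, "ReferenceBundle")) refSeqlengths(x) else x
  if (is.null(names(sl))) stop("chromosome lengths must be named")
  tileGenome(sl, tilewidth = as.integer(w), cut.last.tile.in.chrom = TRUE)
}

#' Count filtered alignment records into genome windows
#'
#' A record increments every window it overlaps by at least 1 bp (interval
#' intersection semantics). Records are expected to be primary-only and
#' mapping-quality filtered already (see \code{\link{filterAlignments}}).
#' The library size of a sample is its number of distinct counted queries.
#'
#' @param recordsList named list of alignment \code{GRanges}, one per
#'   sample.
#' @param windows window \code{GRanges} from \code{\link{makeWindows}}.
#' @return \code{RangedSummarizedExperiment} with assay \code{counts}
#'   (windows x samples) and colData column \code{librarySize}.
#' @export
windowCounts <- function(recordsList, windows) {
  if (is.null(names(recordsList)) || anyDuplicated(names(recordsList)))
    stop("recordsList must be uniquely named")
  counts <- vapply(recordsList, function(r)
    countOverlaps(windows, r, ignore.strand = TRUE),
    integer(length(windows)))
  counts <- matrix(counts, nrow = length(windows),
                   dimnames = list(NULL, names(recordsList)))
  libSize <- vapply(recordsList, function(r)
    length(unique(r$query_id)), integer(1))
  SummarizedExperiment(assays = list(counts = counts),
                       rowRanges = windows,
                       colData = DataFrame(librarySize = unname(libSize),
                                           row.names = names(recordsList)))
}

# core log2 ratio of per-100,000-read normalized, pseudocounted counts
.log2ratio <- function(cTest, cBg, nTest, nBg, pseudocount = 1) {
  if (pseudocount < 1) stop("pseudocount must be >= 1")
  normT <- (cTest + pseudocount) * 1e5 / nTest
  normB <- (cBg + pseudocount) * 1e5 / nBg
  log2(normT / normB)
}

#' Per-window log2 ratio of normalized counts
#'
#' Counts are pseudocounted, scaled per 100,000 mapped reads, and compared
#' as \code{log2(test / background)}.
#'
#' @param se \code{RangedSummarizedExperiment} from
#'   \code{\link{windowCounts}}.
#' @param test,background column names of the test and background samples.
#' @param pseudocount added to raw counts before normalization
#'   (\code{>= 1}; keeps zero-count windows finite and symmetric).
#' @return numeric vector of per-window log2 ratios.
#' @export
log2RatioTrack <- function(se, test, background, pseudocount = 1) {
  cts <- assay(se, "counts")
  N <- colData(se)$librarySize
  names(N) <- colnames(se)
  .log2ratio(cts[, test], cts[, background], N[[test]], N[[background]],
             pseudocount)
}

#' Call eccDNA-producing loci by log2 ratio against a background sample
#'
#' Per test replicate, windows with a normalized log2 ratio strictly above
#' \code{log2Min} are marked, marked windows that are adjacent or
#' book-ended are merged, and merged loci of at least \code{minLen} bp are
#' kept. With \code{requireAllReps}, loci are intersected across replicates
#' (any overlap) and the intersection footprint is reported.
#'
#' @param se \code{RangedSummarizedExperiment} from
#'   \code{\link{windowCounts}}.
#' @param testCols column names of the test replicates (>= 1).
#' @param backgroundCol column name of the background (e.g. WGS) sample.
#' @param log2Min log2 ratio threshold (strict >).
#' @param minLen minimum locus length after merging (bp).
#' @param requireAllReps require every replicate to support a locus.
#' @param pseudocount see \code{\link{log2RatioTrack}}.
#' @return \code{GRanges} of loci with summed counts, normalized counts,
#'   per-replicate log2 ratios, window count and replicate support.
#' @export
callEccLoci <- function(se, testCols, backgroundCol, log2Min = 3,
                        minLen = 1000L, requireAllReps = TRUE,
                        pseudocount = 1) {
  windows <- rowRanges(se)
  if (!length(windows)) stop("empty window frame")
  perRep <- lapply(testCols, function(tc) {
    ratio <- log2RatioTrack(se, tc, backgroundCol, pseudocount)
    sel <- which(ratio > log2Min)
    loci <- reduce(windows[sel], ignore.strand = TRUE)
    loci[width(loci) >= minLen]
  })
  loci <- if (requireAllReps) Reduce(GenomicRanges::intersect, perRep)
          else reduce(unlist(GRangesList(perRep)), ignore.strand = TRUE)
  loci <- granges(loci)
  if (!length(loci)) {
    mcols(loci) <- DataFrame(n_windows_merged = integer(),
                             replicate_support = logical())
    return(loci)
  }
  cts <- assay(se, "counts")
  N <- setNames(colData(se)$librarySize, colnames(se))
  ov <- findOverlaps(loci, windows, ignore.strand = TRUE)
  sumCounts <- function(col) {
    v <- rep(0L, length(loci))
    agg <- tapply(cts[subjectHits(ov), col], queryHits(ov), sum)
    v[as.integer(names(agg))] <- as.integer(agg)
    v
  }
  info <- DataFrame(n_windows_merged = countOverlaps(loci, windows,
                                                     ignore.strand = TRUE),
                    replicate_support = TRUE)
  for (col in c(testCols, backgroundCol)) {
    info[[paste0("count_", col)]] <- sumCounts(col)
    info[[paste0("norm_", col)]] <- sumCounts(col) * 1e5 / N[[col]]
  }
  for (tc in testCols) {
    info[[paste0("log2_", tc)]] <-
      .log2ratio(info[[paste0("count_", tc)]],
                 info[[paste0("count_", backgroundCol)]],
                 N[[tc]], N[[backgroundCol]], pseudocount)
  }
  mcols(loci) <- info
  loci
}

#' Fisher's exact test per genome window
#'
#' For each window the 2x2 table
#' \code{[[c_stress, N_stress - c_stress], [c_control, N_control -
#' c_control]]} is tested two-sided; Benjamini-Hochberg adjustment runs
#' over the family of windows with any counts (\code{c_stress + c_control
#' > 0}); zero-count windows get NA p/q and are never significant. A window
#' is significant when \code{q < alpha} and the normalized stress count
#' exceeds the normalized control count (increased eccDNA coverage).
#'
#' @param se \code{RangedSummarizedExperiment} from
#'   \code{\link{windowCounts}}.
#' @param stressCol,controlCol sample column names.
#' @param alpha significance level on the adjusted q-values.
#' @return the window \code{GRanges} with mcols \code{count_stress},
#'   \code{count_control}, \code{p}, \code{q}, \code{significant}.
#' @export
fisherWindowTest <- function(se, stressCol, controlCol, alpha = 0.01) {
  windows <- granges(rowRanges(se))
  cts <- assay(se, "counts")
  N <- setNames(colData(se)$librarySize, colnames(se))
  cs <- cts[, stressCol]; cc <- cts[, controlCol]
  ns <- N[[stressCol]]; nc <- N[[controlCol]]
  if (ns <= 0 || nc <= 0) stop("library sizes must be positive")
  if (any(cs > ns) || any(cc > nc))
    stop("window count exceeds library size")
  fam <- which(cs + cc > 0L)
  p <- rep(NA_real_, length(windows))
  if (length(fam)) {
    key <- paste(cs[fam], cc[fam])
    uk <- !duplicated(key)
    pUnique <- vapply(fam[uk], function(i)
      fisherExactTwoSided(c(cs[i], ns - cs[i], cc[i], nc - cc[i])),
      numeric(1))
    p[fam] <- pUnique[match(key, key[uk])]
  }
  q <- bhAdjust(p)
  sig <- !is.na(q) & q < alpha & (cs / ns > cc / nc)
  mcols(windows) <- DataFrame(count_stress = cs, count_control = cc,
                              p = p, q = q, significant = sig)
  metadata(windows) <- list(stress = stressCol, control = controlCol,
                            alpha = alpha, family_size = length(fam),
                            table = "in-window vs library remainder")
  windows
}

#' Merge adjacent significant windows into peaks
#'
#' Book-ended adjacency only; no gap bridging. Peak p and q are the minima
#' over the merged windows, counts are summed.
#'
#' @param tested output of \code{\link{fisherWindowTest}}.
#' @return \code{GRanges} of peaks with counts, p, q and
#'   \code{n_windows_merged}.
#' @export
mergeSignificant <- function(tested) {
  sel <- tested[tested$significant]
  peaks <- reduce(granges(sel), ignore.strand = TRUE)
  if (!length(peaks)) {
    mcols(peaks) <- DataFrame(count_stress = integer(),
                              count_control = integer(), p = numeric(),
                              q = numeric(), n_windows_merged = integer())
    return(peaks)
  }
  ov <- findOverlaps(peaks, sel, ignore.strand = TRUE)
  agg <- function(v, f) as.numeric(tapply(v[subjectHits(ov)],
                                          queryHits(ov), f))
  mcols(peaks) <- DataFrame(
    count_stress = as.integer(agg(sel$count_stress, sum)),
    count_control = as.integer(agg(sel$count_control, sum)),
    p = agg(sel$p, min), q = agg(sel$q, min),
    n_windows_merged = as.integer(agg(sel$p, length)))
  peaks
}

#' Annotate peaks with overlapping features and per-feature read shares
#'
#' Each peak is annotated with every feature it overlaps by >= 1 bp. When
#' alignment records are supplied, each peak-supporting read is attributed
#' to the feature its record overlaps most, and the fraction of
#' peak-supporting reads per feature is reported in
#' \code{metadata(.)$read_share}.
#'
#' @param peaks peak \code{GRanges}.
#' @param bundle a \code{\linkS4class{ReferenceBundle}}.
#' @param records optional filtered alignment \code{GRanges} supporting the
#'   peaks.
#' @return \code{peaks} with an added \code{feature_ids} CharacterList
#'   column.
#' @export
annotatePeaks <- function(peaks, bundle, records = NULL) {
  feats <- refFeatures(bundle)
  ov <- findOverlaps(peaks, feats, ignore.strand = TRUE)
  ids <- CharacterList(split(feats$feature_id[subjectHits(ov)],
                             factor(queryHits(ov),
                                    levels = seq_along(peaks))))
  names(ids) <- NULL
  peaks$feature_ids <- ids
  if (!is.null(records) && length(records) && length(peaks)) {
    sup <- records[overlapsAny(records, peaks, ignore.strand = TRUE)]
    if (length(sup)) {
      hits <- findOverlaps(sup, feats, ignore.strand = TRUE)
      w <- width(pintersect(sup[queryHits(hits)], feats[subjectHits(hits)],
                            ignore.strand = TRUE))
      bestIdx <- tapply(seq_along(w), queryHits(hits),
                        function(i) i[which.max(w[i])])
      assigned <- feats$feature_id[subjectHits(hits)[unlist(bestIdx)]]
      tab <- table(assigned)
      metadata(peaks)$read_share <- data.frame(
        feature_id = names(tab), n_reads = as.integer(tab),
        share = as.numeric(tab) / length(sup), stringsAsFactors = FALSE)
    }
  }
  peaks
}

#' Replicate concordance of windowed counts
#'
#' Diagnostic used to justify a log2 threshold: the fraction of windows
#' whose between-replicate absolute log2 ratio is at most
#' \code{threshold}.
#'
#' @param se \code{RangedSummarizedExperiment} from
#'   \code{\link{windowCounts}}.
#' @param colA,colB replicate column names.
#' @param threshold absolute log2 ratio bound.
#' @param pseudocount see \code{\link{log2RatioTrack}}.
#' @return the concordant fraction (scalar in [0,1]).
#' @export
replicateConcordance <- function(se, colA, colB, threshold = 2,
                                 pseudocount = 1) {
  r <- log2RatioTrack(se, colA, colB, pseudocount)
  mean(abs(r) <= threshold)
}
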