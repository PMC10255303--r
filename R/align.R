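#' Map query sequences to a reference with a seed-chain-extend mapper
#'
#' Exact k-mer seed matches (both strands) are chained per (chromosome,
#' strand) into runs of near-constant diagonal; chains are clustered into
#' candidate loci by reference-interval overlap, the best chain per locus is
#' extended with a banded alignment to obtain an identity estimate, and the
#' best-scoring locus is marked primary. Mapping quality of the primary
#' record is \code{min(60, round(40 * (1 - s2/s1)))}, where \code{s1} and
#' \code{s2} are the best and second-best locus chain scores (60 when the
#' hit is unique); secondary records get mapq 0. Chains at the same locus
#' (overlapping reference intervals) are not treated as ambiguity --- an RCA
#' concatemer read legitimately produces one chain per tandem copy at its
#' single source locus --- so \code{s2} is taken over alternative loci only.
#' Near-identical TE copies elsewhere in the genome do compete, driving the
#' mapq of multi-copy families below typical filtering thresholds, as
#' happens with real aligners.
#'
#' Alignment records are returned as a \code{GRanges} (1-based) with mcols
#' \code{query_id}, \code{query_start}, \code{query_end} (0-based half-open
#' on the original query), \code{query_len}, \code{mapq}, \code{is_primary}
#' and \code{identity}.
#'
#' @param queries named character vector or \code{DNAStringSet}.
#' @param bundle a \code{\linkS4class{ReferenceBundle}}.
#' @param k seed k-mer size.
#' @param minChainSeeds minimum seeds per chain; queries with no such chain
#'   are unmapped and absent from the output.
#' @param bandWidth diagonal band width (bp) for chaining.
#' @return \code{GRanges} of alignment records.
#' @export
mapReads <- function(queries, bundle, k = 15L, minChainSeeds = 3L,
                     bandWidth = 100L) {
  sq <- .asSeqChar(queries)
  ids <- names(sq)
  if (is.null(ids)) ids <- sprintf("query%d", seq_along(sq))
  refs <- as.character(refSeqs(bundle))
  chromNames <- names(refs)
  sl <- refSeqlengths(bundle)
  emptyGr <- function() {
    gr <- GRanges(seqnames = factor(character(), levels = chromNames),
                  IRanges(), strand = character(), seqlengths = sl)
    mcols(gr) <- DataFrame(query_id = character(), query_start = integer(),
                           query_end = integer(), query_len = integer(),
                           mapq = integer(), is_primary = logical(),
                           identity = numeric())
    gr
  }
  if (!length(sq)) return(emptyGr())
  if (any(nchar(sq) < k)) stop("all queries must be at least k bases long")

  ch <- cpp_map_chains(refs, unname(sq), as.integer(k), as.integer(bandWidth))
  ch <- ch[ch$score >= minChainSeeds, , drop = FALSE]
  if (!nrow(ch)) return(emptyGr())

  out <- list()
  for (qi in unique(ch$qidx)) {
    cq <- ch[ch$qidx == qi, , drop = FALSE]
    # cluster chains into loci by reference-interval overlap (strand-blind)
    ivs <- GRanges(chromNames[cq$chrom],
                   IRanges(cq$rstart + 1L, cq$rend))
    red <- reduce(ivs, ignore.strand = TRUE)
    locus <- findOverlaps(ivs, red, select = "first")
    best <- vapply(split(seq_len(nrow(cq)), locus), function(idx)
      idx[order(-cq$score[idx], cq$strand[idx] * -1L, cq$rstart[idx])][1],
      integer(1))
    bc <- cq[best, , drop = FALSE]
    ord <- order(-bc$score, bc$chrom, bc$rstart)
    bc <- bc[ord, , drop = FALSE]
    s1 <- bc$score[1]
    s2 <- if (nrow(bc) > 1L) bc$score[2] else 0L
    mq1 <- if (s2 == 0L) 60L else
      max(0L, min(60L, as.integer(round(40 * (1 - s2 / s1)))))

    qseq <- unname(sq[qi]); qlen <- nchar(qseq)
    recs <- lapply(seq_len(nrow(bc)), function(i) {
      r <- bc[i, ]
      seg <- substr(qseq, r$qstart + 1L, r$qend)
      if (r$strand < 0L) seg <- .revcomp(seg)
      refSeg <- substr(refs[r$chrom], r$rstart + 1L, r$rend)
      band <- max(50L, min(200L, as.integer(0.1 * nchar(seg))))
      al <- cpp_band_global(seg, refSeg, band)
      gr <- GRanges(chromNames[r$chrom], IRanges(r$rstart + 1L, r$rend),
                    strand = if (r$strand > 0L) "+" else "-",
                    seqlengths = sl)
      mcols(gr) <- DataFrame(query_id = ids[qi], query_start = r$qstart,
                             query_end = r$qend, query_len = qlen,
                             mapq = if (i == 1L) mq1 else 0L,
                             is_primary = i == 1L, identity = al$identity)
      gr
    })
    out[[length(out) + 1L]] <- do.call(c, recs)
  }
  res <- do.call(c, out)
  sort(res, ignore.strand = TRUE)
}

#' @rdname mapReads
#' @param query a single query sequence.
#' @param ... passed to \code{mapReads}.
#' @export
mapQuery <- function(query, bundle, ...) {
  q <- .asSeqChar(query)[1]
  if (is.null(names(q))) names(q) <- "query"
  mapReads(q, bundle, ...)
}

#' Filter alignment records: primary-only and minimum mapping quality
#'
#' Reproduces the semantics of dropping secondary/supplementary alignments
#' and records below a mapping-quality threshold
#' (\code{samtools view -F 3840 -q 30}). The operation is idempotent.
#'
#' @param records alignment \code{GRanges} from \code{\link{mapReads}} or
#'   \code{\link{readSam}}.
#' @param minMapq minimum mapping quality retained (\code{>=}).
#' @param primaryOnly drop non-primary records.
#' @return filtered \code{GRanges}.
#' @export
filterAlignments <- function(records, minMapq = 30L, primaryOnly = TRUE) {
  keep <- records$mapq >= minMapq
  if (primaryOnly) keep <- keep & records$is_primary
  records[keep]
}

# CIGAR for a record whose per-base alignment is not retained: soft clips
# around a single M run, with the query/reference span difference expressed
# as one I or D run. Round-trips all AlignmentRecord fields.
.recordCigar <- function(refSpan, qStart, qEnd, qLen, minus) {
  qSpan <- qEnd - qStart
  mlen <- min(refSpan, qSpan)
  mid <- if (refSpan > qSpan) sprintf("%dM%dD", mlen, refSpan - qSpan)
         else if (qSpan > refSpan) sprintf("%dM%dI", mlen, qSpan - refSpan)
         else sprintf("%dM", mlen)
  lead <- if (minus) qLen - qEnd else qStart
  trail <- if (minus) qStart else qLen - qEnd
  paste0(if (lead > 0) sprintf("%dS", lead) else "", mid,
         if (trail > 0) sprintf("%dS", trail) else "")
}

#' Write alignment records as SAM
#'
#' Minimal dialect: \code{@HD}/\code{@SQ} header, FLAG (0x10 strand, 0x100
#' secondary), RNAME, POS, MAPQ, CIGAR (S/M/I/D), and the identity in an
#' \code{XI:f} tag. Sequence and quality columns are written as \code{*}.
#'
#' @param records alignment \code{GRanges} (as from \code{\link{mapReads}}).
#' @param path output path.
#' @param seqlengths named chromosome lengths; defaults to
#'   \code{seqlengths(records)}.
#' @export
writeSam <- function(records, path, seqlengths = NULL) {
  if (is.null(seqlengths)) seqlengths <- GenomeInfoDb::seqlengths(records)
  if (any(is.na(seqlengths)))
    stop("seqlengths must be known to write SAM")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)), con)
  if (length(records)) {
    minus <- as.character(strand(records)) == "-"
    flag <- ifelse(minus, 16L, 0L) + ifelse(records$is_primary, 0L, 256L)
    cig <- vapply(seq_along(records), function(i)
      .recordCigar(width(records)[i], records$query_start[i],
                   records$query_end[i], records$query_len[i], minus[i]),
      character(1))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tXI:f:%.6f",
                       records$query_id, flag,
                       as.character(seqnames(records)), start(records),
                       records$mapq, cig, records$identity), con)
  }
  invisible(path)
}

#' Read a SAM file into alignment records
#'
#' Parses the minimal dialect written by \code{\link{writeSam}} and, more
#' generally, any SAM whose CIGARs use M/=/X/I/D/S/H. FLAG bits 0x100 and
#' 0x800 map to \code{is_primary = FALSE}; unmapped records (FLAG 0x4 or
#' RNAME \code{*}) are skipped. Malformed lines and unknown chromosomes
#' raise an error naming the offending line.
#'
#' @param path SAM path.
#' @return alignment \code{GRanges} as from \code{\link{mapReads}}.
#' @export
readSam <- function(path) {
  lines <- readLines(path)
  isHdr <- startsWith(lines, "@")
  sqLines <- lines[startsWith(lines, "@SQ")]
  sl <- integer(0)
  for (h in sqLines) {
    fields <- strsplit(h, "\t", fixed = TRUE)[[1]]
    sn <- sub("^SN:", "", grep("^SN:", fields, value = TRUE)[1])
    ln <- as.integer(sub("^LN:", "", grep("^LN:", fields, value = TRUE)[1]))
    sl[sn] <- ln
  }
  body <- which(!isHdr & nzchar(lines))
  recs <- vector("list", length(body))
  for (j in seq_along(body)) {
    lineNo <- body[j]
    f <- strsplit(lines[lineNo], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop("malformed SAM line ", lineNo, ": expected >= 11 fields")
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    mapq <- suppressWarnings(as.integer(f[5]))
    if (is.na(flag) || is.na(pos) || is.na(mapq))
      stop("malformed SAM line ", lineNo, ": non-numeric FLAG/POS/MAPQ")
    if (bitwAnd(flag, 4L) > 0L || f[3] == "*") next
    if (!(f[3] %in% names(sl)))
      stop("unknown chromosome '", f[3], "' at SAM line ", lineNo)
    ops <- gregexpr("\\d+[MIDNSHP=X]", f[6])[[1]]
    if (f[6] == "*" || ops[1] == -1L)
      stop("missing CIGAR at SAM line ", lineNo)
    opStr <- regmatches(f[6], gregexpr("\\d+[MIDNSHP=X]", f[6]))[[1]]
    opLen <- as.integer(sub("[MIDNSHP=X]$", "", opStr))
    opChr <- sub("^\\d+", "", opStr)
    refSpan <- sum(opLen[opChr %in% c("M", "D", "N", "=", "X")])
    qSpan <- sum(opLen[opChr %in% c("M", "I", "=", "X")])
    lead <- if (opChr[1] %in% c("S", "H")) opLen[1] else 0L
    last <- length(opChr)
    trail <- if (opChr[last] %in% c("S", "H")) opLen[last] else 0L
    qLen <- lead + qSpan + trail
    minus <- bitwAnd(flag, 16L) > 0L
    qStart <- if (minus) trail else lead
    ident <- NA_real_
    xi <- grep("^XI:f:", f[-(1:11)], value = TRUE)
    if (length(xi)) ident <- as.numeric(sub("^XI:f:", "", xi[1]))
    recs[[j]] <- data.frame(
      query_id = f[1], chrom = f[3], start = pos, end = pos + refSpan - 1L,
      strand = if (minus) "-" else "+",
      query_start = qStart, query_end = qStart + qSpan, query_len = qLen,
      mapq = mapq,
      is_primary = bitwAnd(flag, 256L) == 0L && bitwAnd(flag, 2048L) == 0L,
      identity = ident, stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    gr <- GRanges(seqnames = factor(character(), levels = names(sl)),
                  IRanges(), seqlengths = sl)
    mcols(gr) <- DataFrame(query_id = character(), query_start = integer(),
                           query_end = integer(), query_len = integer(),
                           mapq = integer(), is_primary = logical(),
                           identity = numeric())
    return(gr)
  }
  df <- do.call(rbind, recs)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                seqlengths = sl)
  mcols(gr) <- DataFrame(query_id = df$query_id,
                         query_start = df$query_start,
                         query_end = df$query_end, query_len = df$query_len,
                         mapq = df$mapq, is_primary = df$is_primary,
                         identity = df$identity)
  gr
}
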