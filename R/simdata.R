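#' Construct simulator parameters
#'
#' Defaults emulate an R9.4.1-era nanopore error profile (~10\% total error:
#' 5\% substitutions, 2.5\% insertions, 2.5\% deletions), a truncated
#' geometric RCA copy-number distribution over 1..20 with mean ~4 (so both
#' the >=2-copy peak filter and the >=3-copy structure filter are
#' exercised), and a template mix dominated by full-length TE circles with
#' LTR-derived and internal truncated forms.
#'
#' @param seed integer seed controlling all simulator randomness.
#' @param subRate,insRate,delRate per-base error probabilities.
#' @param copyNumberDist function(n) -> integer copies >= 1 (default:
#'   geometric with success probability 1/4 truncated to 1..20).
#' @param templateMix named weights over \code{full_TE}, \code{solo_LTR},
#'   \code{two_LTR}, \code{internal_fragment}, \code{gene_circle}.
#' @param nEccReads reads per eccDNA replicate; \code{nWgsReads} control reads.
#' @param wgsReadLenDist function(n) -> WGS fragment lengths (default:
#'   uniform 1-10 kb, a typical nanopore genomic length scale).
#' @param wgsConcatFraction fraction of WGS reads drawn as concatemers
#'   (default 0: a clean linear background).
#' @param featureIds restrict template source features to these ids
#'   (default: all compatible features).
#' @return a validated \code{\linkS4class{SimParams}} object.
#' @export
simParams <- function(seed = 1L, subRate = 0.05, insRate = 0.025,
                      delRate = 0.025, copyNumberDist = NULL,
                      templateMix = c(full_TE = 0.40, solo_LTR = 0.25,
                                      two_LTR = 0.15,
                                      internal_fragment = 0.15,
                                      gene_circle = 0.05),
                      nEccReads = 100L, nWgsReads = 500L,
                      wgsReadLenDist = NULL, wgsConcatFraction = 0,
                      featureIds = character()) {
  if (is.null(copyNumberDist)) {
    copyNumberDist <- function(n) {
      k <- 1:20
      sample(k, n, replace = TRUE, prob = (3 / 4)^(k - 1))
    }
  }
  if (is.null(wgsReadLenDist)) {
    wgsReadLenDist <- function(n) round(runif(n, 1000, 10000))
  }
  new("SimParams", seed = as.integer(seed), subRate = subRate,
      insRate = insRate, delRate = delRate, copyNumberDist = copyNumberDist,
      templateMix = templateMix[TEMPLATE_KINDS],
      nEccReads = as.integer(nEccReads), nWgsReads = as.integer(nWgsReads),
      wgsReadLenDist = wgsReadLenDist,
      wgsConcatFraction = wgsConcatFraction,
      featureIds = as.character(featureIds))
}

#' Generate a synthetic reference genome with TE and gene features
#'
#' Builds \code{nChroms} random chromosomes and places non-overlapping TE
#' and gene features. Every TE carries two identical LTR copies at its ends.
#' The first two TEs form a multi-copy family: the second is a ~1\%-diverged
#' copy of the first (>=95\% identity), so near-identical insertions --- the
#' classic source of cross-mapping ambiguity among TE copies --- are present
#' in every simulated genome.
#'
#' @param seed integer seed.
#' @param nChroms,chromLen number and length (bp) of chromosomes.
#' @param nTes,teLen,ltrLen TE count, TE length, LTR length
#'   (\code{teLen > 2*ltrLen}).
#' @param nGenes,geneLen gene feature count and length.
#' @return a \code{\linkS4class{ReferenceBundle}}.
#' @examples
#' bundle <- makeReference(1, nChroms = 2, chromLen = 50000,
#'                         nTes = 2, teLen = 3000, ltrLen = 300)
#' refFeatures(bundle)
#' @export
makeReference <- function(seed = 1L, nChroms = 2L, chromLen = 100000L,
                          nTes = 4L, teLen = 5000L, ltrLen = 500L,
                          nGenes = 2L, geneLen = 2000L) {
  if (teLen <= 2 * ltrLen) stop("teLen must exceed 2*ltrLen")
  set.seed(as.integer(seed))
  nChroms <- as.integer(nChroms); chromLen <- as.integer(chromLen)
  nTes <- as.integer(nTes); nGenes <- as.integer(nGenes)

  featLens <- c(rep(teLen, nTes), rep(geneLen, nGenes))
  featClass <- c(rep("TE", nTes), rep("gene", nGenes))
  featIds <- c(sprintf("TE%d", seq_len(nTes)),
               sprintf("gene%d", seq_len(nGenes)))

  # feature sequences; TE1/TE2 are one family (TE2 ~1% diverged from TE1)
  mkTe <- function() {
    ltr <- .randomDna(ltrLen)
    internal <- .randomDna(teLen - 2L * ltrLen)
    paste0(ltr, internal, ltr)
  }
  seqsOf <- character(length(featLens))
  for (i in seq_len(nTes)) {
    if (i == 2L && nTes >= 2L) {
      base <- seqsOf[1]
      ltr <- .mutateDna(substr(base, 1L, ltrLen), 0.01)
      internal <- .mutateDna(substr(base, ltrLen + 1L, teLen - ltrLen), 0.01)
      seqsOf[i] <- paste0(ltr, internal, ltr)
    } else {
      seqsOf[i] <- mkTe()
    }
  }
  for (i in seq_len(nGenes)) seqsOf[nTes + i] <- .randomDna(geneLen)

  # assign features to chromosomes round-robin, then pack with random gaps
  chromOf <- rep(seq_len(nChroms), length.out = length(featLens))
  starts <- integer(length(featLens))
  genome <- vapply(seq_len(nChroms), function(i) .randomDna(chromLen),
                   character(1))
  names(genome) <- sprintf("chr%d", seq_len(nChroms))
  for (ch in seq_len(nChroms)) {
    idx <- which(chromOf == ch)
    if (!length(idx)) next
    used <- sum(featLens[idx])
    free <- chromLen - used - 20L * (length(idx) + 1L)  # min 20 bp gaps
    if (free < 0)
      stop("impossible packing: features do not fit on chromosome ", ch)
    cuts <- sort(sample.int(free + 1L, length(idx) + 1L, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts)) + 20L
    pos <- 0L
    for (j in seq_along(idx)) {
      pos <- pos + gaps[j]
      starts[idx[j]] <- pos + 1L
      substr(genome[ch], pos + 1L, pos + featLens[idx[j]]) <- seqsOf[idx[j]]
      pos <- pos + featLens[idx[j]]
    }
  }

  ltrRel <- IRangesList(lapply(seq_along(featLens), function(i) {
    if (featClass[i] == "TE")
      IRanges(c(1L, featLens[i] - ltrLen + 1L), c(ltrLen, featLens[i]))
    else IRanges()
  }))
  feats <- GRanges(names(genome)[chromOf],
                   IRanges(starts, width = featLens), strand = "+",
                   feature_id = featIds, feature_class = featClass,
                   ltr_rel = ltrRel)
  seqs <- DNAStringSet(genome)
  new("ReferenceBundle", seqs = seqs, features = feats)
}

#' Extract one circular eccDNA template from an annotated feature
#'
#' Template kinds mirror the circle forms seen for LTR retrotransposons:
#' the full element (\code{full_TE}), one LTR (\code{solo_LTR}), the two
#' LTRs joined (\code{two_LTR}), a random internal sub-interval
#' (\code{internal_fragment}), or a gene-derived circle
#' (\code{gene_circle}).
#'
#' @param bundle a \code{\linkS4class{ReferenceBundle}}.
#' @param kind one of \code{full_TE}, \code{solo_LTR}, \code{two_LTR},
#'   \code{internal_fragment}, \code{gene_circle}.
#' @param featureId feature to draw from (class-compatible with
#'   \code{kind}).
#' @param internalLenRange length range of internal fragments (bp); drawn
#'   uniformly, clipped to the internal region. The default is the ~1-kb
#'   scale typical of truncated eccDNAs.
#' @return list with \code{seq} (character template) and \code{truth}
#'   (one-row data.frame: feature, kind, genome intervals, template length).
#' @export
makeCircleTemplate <- function(bundle, kind, featureId,
                               internalLenRange = c(900L, 1100L)) {
  kind <- match.arg(kind, TEMPLATE_KINDS)
  f <- refFeatures(bundle)
  i <- match(featureId, f$feature_id)
  if (is.na(i)) stop("unknown feature: ", featureId)
  cls <- f$feature_class[i]
  chrom <- as.character(seqnames(f))[i]
  fstart <- start(f)[i]; fend <- end(f)[i]
  chromSeq <- as.character(refSeqs(bundle)[[chrom]])
  rel <- f$ltr_rel[[i]]
  getAbs <- function(s, e) substr(chromSeq, fstart + s - 1L, fstart + e - 1L)

  if (kind == "gene_circle") {
    if (cls != "gene") stop("gene_circle requires a gene feature")
    seq <- getAbs(1L, width(f)[i])
    iv <- sprintf("%s:%d-%d", chrom, fstart, fend)
  } else {
    if (cls != "TE") stop(kind, " requires a TE feature")
    if (kind != "internal_fragment" && length(rel) != 2L)
      stop(kind, " requires a TE with annotated LTRs")
    if (kind == "full_TE") {
      seq <- getAbs(1L, width(f)[i])
      iv <- sprintf("%s:%d-%d", chrom, fstart, fend)
    } else if (kind == "solo_LTR") {
      j <- sample(1:2, 1L)
      seq <- getAbs(start(rel)[j], end(rel)[j])
      iv <- sprintf("%s:%d-%d", chrom, fstart + start(rel)[j] - 1L,
                    fstart + end(rel)[j] - 1L)
    } else if (kind == "two_LTR") {
      seq <- paste0(getAbs(start(rel)[1], end(rel)[1]),
                    getAbs(start(rel)[2], end(rel)[2]))
      iv <- paste(sprintf("%s:%d-%d", chrom, fstart + start(rel) - 1L,
                          fstart + end(rel) - 1L), collapse = ";")
    } else { # internal_fragment
      intLo <- if (length(rel) == 2L) end(rel)[1] + 1L else 1L
      intHi <- if (length(rel) == 2L) start(rel)[2] - 1L else width(f)[i]
      maxLen <- intHi - intLo + 1L
      len <- min(maxLen,
                 round(runif(1, internalLenRange[1], internalLenRange[2])))
      s <- intLo + sample.int(maxLen - len + 1L, 1L) - 1L
      seq <- getAbs(s, s + len - 1L)
      iv <- sprintf("%s:%d-%d", chrom, fstart + s - 1L, fstart + s + len - 2L)
    }
  }
  list(seq = seq,
       truth = data.frame(feature_id = featureId, kind = kind,
                          chrom = chrom, intervals = iv,
                          template_len = nchar(seq),
                          stringsAsFactors = FALSE))
}

#' Simulate one RCA concatemer read from a circular template
#'
#' Rolling-circle amplification turns a circle into a linear tandem repeat:
#' the template is rotated to a random start phase, repeated \code{copyN}
#' times, optionally reverse-complemented, and per-base
#' substitution/insertion/deletion errors are applied. With zero error
#' rates the read is an exact tandem repeat of the rotated template.
#'
#' @param template circular template sequence (character).
#' @param copyN number of tandem copies (>= 1).
#' @param phase 0-based rotation offset, \code{0 <= phase < nchar(template)}.
#' @param strand \code{"+"} or \code{"-"}.
#' @param params a \code{\linkS4class{SimParams}} (error rates used).
#' @return the simulated read (character).
#' @export
simulateRcaRead <- function(template, copyN, phase = 0L, strand = "+",
                            params = simParams()) {
  n <- nchar(template)
  if (copyN < 1L) stop("copyN must be >= 1")
  if (phase < 0L || phase >= n) stop("phase must be in [0, template length)")
  rot <- if (phase > 0L)
    paste0(substr(template, phase + 1L, n), substr(template, 1L, phase))
  else template
  read <- paste(rep(rot, copyN), collapse = "")
  if (strand == "-") read <- .revcomp(read)
  .applyReadErrors(read, params@subRate, params@insRate, params@delRate)
}

# vectorized per-base substitution/insertion/deletion error process
.applyReadErrors <- function(read, subRate, insRate, delRate) {
  if (subRate == 0 && insRate == 0 && delRate == 0) return(read)
  ch <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(ch)
  sub <- which(runif(n) < subRate)
  if (length(sub))
    ch[sub] <- vapply(ch[sub], function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
  del <- runif(n) < delRate
  ins <- runif(n) < insRate
  insBase <- character(n)
  ki <- which(ins)
  if (length(ki)) insBase[ki] <- sample(DNA_BASES, length(ki), replace = TRUE)
  ch[del] <- ""
  paste(paste0(ch, insBase), collapse = "")
}

#' Simulate an eccDNA sequencing experiment with a WGS control
#'
#' Draws two eccDNA replicates of RCA concatemer reads from the template mix
#' and a whole-genome control of uniform linear fragments (optionally
#' containing a small concatemer fraction, as real WGS nanopore runs do),
#' all deterministically from \code{params@seed}. A truth table records one
#' row per emitted read.
#'
#' @param bundle a \code{\linkS4class{ReferenceBundle}}.
#' @param params a \code{\linkS4class{SimParams}}.
#' @param outDir optional directory; when given, FASTQ files
#'   (\code{ecc_rep1.fastq}, \code{ecc_rep2.fastq}, \code{wgs.fastq}), a
#'   truth TSV and a metadata file are written there.
#' @return list with \code{reads} (named list of \code{DNAStringSet}:
#'   \code{ecc_rep1}, \code{ecc_rep2}, \code{wgs}) and \code{truth}
#'   (data.frame).
#' @export
simulateSamples <- function(bundle, params = simParams(), outDir = NULL) {
  set.seed(params@seed)
  f <- refFeatures(bundle)
  teIds <- f$feature_id[f$feature_class == "TE"]
  teWithLtr <- f$feature_id[f$feature_class == "TE" & lengths(f$ltr_rel) == 2L]
  geneIds <- f$feature_id[f$feature_class == "gene"]
  if (length(params@featureIds)) {
    teIds <- intersect(teIds, params@featureIds)
    teWithLtr <- intersect(teWithLtr, params@featureIds)
    geneIds <- intersect(geneIds, params@featureIds)
  }
  sl <- refSeqlengths(bundle)

  drawEccRead <- function(readId, sampleLabel) {
    w <- params@templateMix
    ok <- c(full_TE = length(teIds) > 0, solo_LTR = length(teWithLtr) > 0,
            two_LTR = length(teWithLtr) > 0,
            internal_fragment = length(teIds) > 0,
            gene_circle = length(geneIds) > 0)
    w[!ok[names(w)]] <- 0
    if (sum(w) == 0) stop("no features compatible with the template mix")
    kind <- sample(names(w), 1L, prob = w)
    fid <- switch(kind,
      full_TE = , internal_fragment = sample(teIds, 1L),
      solo_LTR = , two_LTR = sample(teWithLtr, 1L),
      gene_circle = sample(geneIds, 1L))
    tmpl <- makeCircleTemplate(bundle, kind, fid)
    copyN <- params@copyNumberDist(1L)
    phase <- sample.int(nchar(tmpl$seq), 1L) - 1L
    strand <- sample(c("+", "-"), 1L)
    read <- simulateRcaRead(tmpl$seq, copyN, phase, strand, params)
    truth <- cbind(data.frame(read_id = readId, sample = sampleLabel,
                              stringsAsFactors = FALSE),
                   tmpl$truth,
                   data.frame(true_copy_number = copyN, true_strand = strand,
                              phase = phase, stringsAsFactors = FALSE))
    list(read = read, truth = truth)
  }

  drawWgsRead <- function(readId, sampleLabel) {
    if (params@wgsConcatFraction > 0 &&
        runif(1) < params@wgsConcatFraction) {
      return(drawEccRead(readId, sampleLabel))
    }
    len <- max(100L, round(params@wgsReadLenDist(1L)))
    chrom <- sample(names(sl), 1L, prob = as.numeric(sl))
    len <- min(len, sl[[chrom]])
    s <- sample.int(sl[[chrom]] - len + 1L, 1L)
    seq <- substr(as.character(refSeqs(bundle)[[chrom]]), s, s + len - 1L)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") seq <- .revcomp(seq)
    read <- .applyReadErrors(seq, params@subRate, params@insRate,
                             params@delRate)
    truth <- data.frame(read_id = readId, sample = sampleLabel,
                        feature_id = NA_character_, kind = "linear",
                        chrom = chrom,
                        intervals = sprintf("%s:%d-%d", chrom, s, s + len - 1L),
                        template_len = len, true_copy_number = 1L,
                        true_strand = strand, phase = 0L,
                        stringsAsFactors = FALSE)
    list(read = read, truth = truth)
  }

  samples <- list()
  truthRows <- list()
  for (rep in 1:2) {
    label <- sprintf("ecc_rep%d", rep)
    reads <- character(params@nEccReads)
    for (i in seq_len(params@nEccReads)) {
      id <- sprintf("%s_read%05d", label, i)
      d <- drawEccRead(id, label)
      reads[i] <- d$read
      truthRows[[length(truthRows) + 1L]] <- d$truth
    }
    names(reads) <- sprintf("%s_read%05d", label, seq_len(params@nEccReads))
    samples[[label]] <- DNAStringSet(reads)
  }
  reads <- character(params@nWgsReads)
  for (i in seq_len(params@nWgsReads)) {
    id <- sprintf("wgs_read%05d", i)
    d <- drawWgsRead(id, "wgs")
    reads[i] <- d$read
    truthRows[[length(truthRows) + 1L]] <- d$truth
  }
  names(reads) <- sprintf("wgs_read%05d", seq_len(params@nWgsReads))
  samples[["wgs"]] <- DNAStringSet(reads)

  truthCols <- c("read_id", "sample", "feature_id", "kind", "chrom",
                 "intervals", "template_len", "true_copy_number",
                 "true_strand", "phase")
  truth <- if (length(truthRows)) {
    do.call(rbind, lapply(truthRows, function(r) r[truthCols]))
  } else {
    as.data.frame(setNames(rep(list(character(0)), length(truthCols)),
                           truthCols))
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(samples))
      writeSimFastq(samples[[nm]], file.path(outDir, paste0(nm, ".fastq")))
    write.table(truth, file.path(outDir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(sprintf("seed\t%d", params@seed),
               file.path(outDir, "metadata.tsv"))
  }
  list(reads = samples, truth = truth)
}

#' Write reads as FASTQ with constant placeholder qualities
#'
#' Base qualities are never consumed downstream, so a constant Q12 string
#' is emitted.
#' @param reads a \code{DNAStringSet} (named).
#' @param path output FASTQ path.
#' @export
writeSimFastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!length(reads)) return(invisible(path))
  ids <- names(reads)
  sq <- as.character(reads)
  qual <- vapply(nchar(sq), function(n) strrep("-", n), character(1)) # Q12
  writeLines(paste0("@", ids, "\n", sq, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#' @param path FASTQ path.
#' @export
readFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write a ReferenceBundle to FASTA + BED6 + GFF3
#'
#' BED intervals are converted to 0-based half-open at this boundary; GFF3 is
#' written 1-based inclusive with LTRs as child features.
#'
#' @param bundle a \code{\linkS4class{ReferenceBundle}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReference <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "reference.fasta")
  writeXStringSet(refSeqs(bundle), fa)
  f <- refFeatures(bundle)
  bed <- file.path(dir, "features.bed")
  bedGr <- f
  mcols(bedGr) <- NULL
  bedGr$name <- f$feature_id
  bedGr$score <- 0L
  rtracklayer::export(bedGr, bed, format = "BED")
  gff <- file.path(dir, "features.gff3")
  parts <- list()
  for (i in seq_along(f)) {
    top <- f[i]
    mcols(top) <- NULL
    top$type <- ifelse(f$feature_class[i] == "TE", "transposable_element",
                       "gene")
    top$ID <- f$feature_id[i]
    parts[[length(parts) + 1L]] <- top
    rel <- f$ltr_rel[[i]]
    if (length(rel) == 2L) {
      ltr <- GRanges(seqnames(f)[i],
                     IRanges(start(f)[i] + start(rel) - 1L,
                             start(f)[i] + end(rel) - 1L),
                     strand = strand(f)[i])
      ltr$type <- "long_terminal_repeat"
      ltr$ID <- sprintf("%s_LTR%d", f$feature_id[i], 1:2)
      ltr$Parent <- f$feature_id[i]
      parts[[length(parts) + 1L]] <- ltr
    }
  }
  all <- suppressWarnings(do.call(c, parts))
  rtracklayer::export(all, gff, format = "GFF3")
  invisible(c(fasta = fa, bed = bed, gff3 = gff))
}

#' Import feature annotation from BED or GFF3
#'
#' BED features become LTR-less TEs; in GFF3,
#' \code{long_terminal_repeat} children are folded into their parent
#' feature's \code{ltr_rel}.
#'
#' @param path annotation file (.bed, .gff3/.gff).
#' @param seqs \code{DNAStringSet} of the genome the annotation refers to.
#' @return a \code{\linkS4class{ReferenceBundle}}.
#' @export
readReference <- function(path, seqs) {
  gr <- rtracklayer::import(path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    feats <- gr
    ids <- if (!is.null(gr$name)) gr$name else sprintf("feat%d", seq_along(gr))
    mcols(feats) <- NULL
    feats$feature_id <- ids
    feats$feature_class <- "TE"
    feats$ltr_rel <- IRangesList(rep(list(IRanges()), length(gr)))
  } else {
    isLtr <- gr$type == "long_terminal_repeat"
    top <- gr[!isLtr]
    feats <- top
    mcols(feats) <- NULL
    feats$feature_id <- top$ID
    feats$feature_class <- ifelse(top$type == "gene", "gene", "TE")
    feats$ltr_rel <- IRangesList(lapply(seq_along(top), function(i) {
      kids <- gr[isLtr & vapply(gr$Parent, function(p)
        length(p) > 0 && p[[1]] == top$ID[i], logical(1))]
      if (!length(kids)) return(IRanges())
      sort(IRanges(start(kids) - start(top)[i] + 1L,
                   end(kids) - start(top)[i] + 1L))
    }))
  }
  new("ReferenceBundle", seqs = seqs, features = feats)
}
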