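#' Project decomposed reads onto their source feature frame
#'
#' For every read that passed the structure filter (>= 3 tandem copies),
#' the footprints of its monomer alignments are united, assigned to the
#' feature with the largest overlap, intersected with that feature, and
#' binned into \code{nBins} equal bins of the feature frame (bin value =
#' covered fraction of the bin). Molecule length is the consensus monomer
#' length (the inferred circle size), not the read length.
#'
#' Assignment uses primary alignments with \code{mapq >= minMapq}. A
#' molecule whose monomers only map ambiguously is rescued when all its
#' candidate placements fall inside one single feature (the typical case:
#' a solo-LTR circle matching both identical LTRs of its source element) —
#' the union of those placements is projected and the molecule flagged
#' \code{ambiguous_within_feature}. Ambiguity across features (e.g. between
#' near-identical TE family copies) sends the read to the unassigned bucket
#' with reason \code{"ambiguous"}; reads with no alignment at all get
#' \code{"unmapped"}, and reads overlapping no feature \code{"no_feature"}.
#'
#' @param decomps list of \code{\linkS4class{TandemDecomposition}}
#'   (typically \code{filterConcatemers(..., minCopies = 3)$retained}).
#' @param records monomer alignment \code{GRanges} from
#'   \code{\link{mapReads}} (unfiltered: secondary records are used for the
#'   ambiguity rescue). Query names must be \code{<read_id>|<i>}.
#' @param bundle a \code{\linkS4class{ReferenceBundle}}.
#' @param nBins number of feature-frame bins.
#' @param minMapq mapping-quality threshold for confident placement.
#' @param flMinCov,ltrMin classification thresholds, see
#'   \code{\link{classifyMolecule}}.
#' @return an \code{\linkS4class{EccMoleculeSet}}.
#' @export
projectMolecules <- function(decomps, records, bundle, nBins = 50L,
                             minMapq = 30L, flMinCov = 0.9, ltrMin = 0.8) {
  feats <- refFeatures(bundle)
  recRead <- sub("\\|\\d+$", "", records$query_id)
  binsRows <- list(); infoRows <- list(); fpList <- list()
  unassigned <- list()

  featBins <- lapply(seq_along(feats), function(i)
    tile(feats[i], n = nBins)[[1]])
  names(featBins) <- feats$feature_id

  for (d in decomps) {
    rid <- readId(d)
    rec <- records[recRead == rid]
    if (!length(rec)) {
      unassigned[[length(unassigned) + 1L]] <- c(rid, "unmapped"); next
    }
    conf <- rec[rec$is_primary & rec$mapq >= minMapq]
    ambiguous <- FALSE
    if (!length(conf)) {
      # ambiguity rescue: every candidate placement inside one same feature?
      ovAll <- findOverlaps(rec, feats, ignore.strand = TRUE)
      if (!length(ovAll)) {
        unassigned[[length(unassigned) + 1L]] <- c(rid, "no_feature"); next
      }
      hitFeats <- unique(subjectHits(ovAll))
      covered <- unique(queryHits(ovAll))
      if (length(hitFeats) != 1L || length(covered) != length(rec)) {
        unassigned[[length(unassigned) + 1L]] <- c(rid, "ambiguous"); next
      }
      conf <- rec
      ambiguous <- TRUE
    }
    # assign the feature from the confident placements ...
    fpConf <- reduce(granges(conf), ignore.strand = TRUE)
    ovF <- findOverlaps(fpConf, feats, ignore.strand = TRUE)
    if (!length(ovF)) {
      unassigned[[length(unassigned) + 1L]] <- c(rid, "no_feature"); next
    }
    w <- width(pintersect(fpConf[queryHits(ovF)], feats[subjectHits(ovF)],
                          ignore.strand = TRUE))
    byFeat <- tapply(w, subjectHits(ovF), sum)
    # largest footprint overlap; ties broken by genome order
    fi <- as.integer(names(byFeat))[order(-byFeat, as.integer(names(byFeat)))][1]
    feat <- feats[fi]
    # ... then take the union of all the molecule's placements at that
    # feature: a rotated circular monomer maps as several collinear
    # segments, of which only one can be primary
    use <- rec[overlapsAny(rec, feat, ignore.strand = TRUE)]
    fp <- reduce(granges(use), ignore.strand = TRUE)
    fpIn <- GenomicRanges::intersect(fp, granges(feat), ignore.strand = TRUE)
    fpWidth <- sum(width(fp)); inWidth <- sum(width(fpIn))
    coveredFraction <- inWidth / width(feat)
    ltr <- ltrRanges(bundle, feat$feature_id)
    ltrFraction <- if (inWidth > 0 && length(ltr)) {
      ovL <- GenomicRanges::intersect(fpIn, granges(ltr),
                                      ignore.strand = TRUE)
      sum(width(ovL)) / inWidth
    } else 0
    bins <- featBins[[feat$feature_id]]
    binCov <- numeric(nBins)
    ovB <- findOverlaps(bins, fpIn, ignore.strand = TRUE)
    if (length(ovB)) {
      wB <- width(pintersect(bins[queryHits(ovB)], fpIn[subjectHits(ovB)],
                             ignore.strand = TRUE))
      agg <- tapply(wB, queryHits(ovB), sum)
      binCov[as.integer(names(agg))] <-
        as.numeric(agg) / width(bins)[as.integer(names(agg))]
    }
    binsRows[[length(binsRows) + 1L]] <- pmin(1, binCov)
    fpList[[length(fpList) + 1L]] <- fp
    infoRows[[length(infoRows) + 1L]] <- DataFrame(
      read_id = rid, feature_id = feat$feature_id,
      monomer_len = nchar(consensusSeq(d)),
      covered_fraction = coveredFraction, ltr_fraction = ltrFraction,
      ambiguous_within_feature = ambiguous,
      flank = fpWidth > inWidth)
  }

  info <- if (length(infoRows)) do.call(rbind, infoRows) else
    DataFrame(read_id = character(), feature_id = character(),
              monomer_len = integer(), covered_fraction = numeric(),
              ltr_fraction = numeric(),
              ambiguous_within_feature = logical(), flank = logical())
  info$class <- classifyMolecule(info$covered_fraction, info$ltr_fraction,
                                 flMinCov, ltrMin)
  bins <- if (length(binsRows)) do.call(rbind, binsRows) else
    matrix(numeric(0), ncol = nBins, nrow = 0)
  una <- if (length(unassigned)) {
    m <- do.call(rbind, unassigned)
    DataFrame(read_id = m[, 1], reason = m[, 2])
  } else DataFrame(read_id = character(), reason = character())
  fps <- if (length(fpList)) GRangesList(fpList) else GRangesList()
  new("EccMoleculeSet", bins = bins, footprints = fps, info = info,
      nbins = as.integer(nBins), unassigned = una)
}

#' Classify eccDNA molecules into full-length and truncated forms
#'
#' \code{fl} when the molecule covers at least \code{flMinCov} of its
#' feature; otherwise \code{tr_LTR} when at least \code{ltrMin} of its
#' footprint lies in LTRs, \code{tr_internal} when at most
#' \code{1 - ltrMin} does, and \code{tr_other} in between.
#'
#' @param coveredFraction,ltrFraction numeric vectors (same length).
#' @param flMinCov full-length coverage threshold.
#' @param ltrMin LTR-dominance threshold.
#' @return character vector of classes.
#' @export
classifyMolecule <- function(coveredFraction, ltrFraction, flMinCov = 0.9,
                             ltrMin = 0.8) {
  ifelse(coveredFraction >= flMinCov, "fl",
    ifelse(ltrFraction >= ltrMin, "tr_LTR",
      ifelse(ltrFraction <= 1 - ltrMin, "tr_internal", "tr_other")))
}

#' Group molecules by their binarized feature-frame pattern
#'
#' Bin coverages are binarized at \code{binarizeAt}; molecules sharing a
#' pattern (and feature) form a group. Groups are ordered by descending
#' count.
#'
#' @param ems an \code{\linkS4class{EccMoleculeSet}}.
#' @param binarizeAt binarization threshold on bin coverage.
#' @return list with \code{groups} (DataFrame: group_id, feature_id, count,
#'   pattern), \code{matrix} (groups x bins binary heatmap matrix),
#'   \code{moleculeMatrix} (molecules x bins), and \code{membership}
#'   (group id per molecule).
#' @export
groupStructures <- function(ems, binarizeAt = 0.5) {
  info <- moleculeInfo(ems)
  binsM <- moleculeBins(ems)
  if (!nrow(info)) {
    return(list(groups = DataFrame(group_id = character(),
                                   feature_id = character(),
                                   count = integer(), pattern = character()),
                matrix = matrix(0L, 0, ems@nbins),
                moleculeMatrix = matrix(0L, 0, ems@nbins),
                membership = character(0)))
  }
  bin <- (binsM >= binarizeAt) * 1L
  key <- paste(info$feature_id, apply(bin, 1L, paste, collapse = ""))
  tab <- sort(table(key), decreasing = TRUE)
  gid <- sprintf("group%d", seq_along(tab))
  names(gid) <- names(tab)
  first <- match(names(tab), key)
  groups <- DataFrame(group_id = gid,
                      feature_id = info$feature_id[first],
                      count = as.integer(tab),
                      pattern = vapply(first, function(i)
                        paste(bin[i, ], collapse = ""), character(1)))
  mat <- bin[first, , drop = FALSE]
  rownames(mat) <- gid
  list(groups = groups, matrix = mat, moleculeMatrix = bin,
       membership = unname(gid[key]))
}

#' Histogram of inferred circle lengths
#'
#' Circle size is the consensus monomer length. A mixture of full-length
#' (~5 kb) and truncated (~1 kb) circles yields a bimodal histogram.
#'
#' @param ems an \code{\linkS4class{EccMoleculeSet}}, or a numeric vector
#'   of lengths.
#' @param binWidth histogram bin width (bp); bins are
#'   \code{[i*binWidth, (i+1)*binWidth)}.
#' @return data.frame with \code{bin_start}, \code{bin_end}, \code{count}
#'   (empty bins omitted).
#' @export
lengthHistogram <- function(ems, binWidth = 100L) {
  lens <- if (is(ems, "EccMoleculeSet")) moleculeInfo(ems)$monomer_len
          else as.numeric(ems)
  if (!length(lens)) {
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0)))
  }
  b <- floor(lens / binWidth)
  tab <- table(b)
  data.frame(bin_start = as.numeric(names(tab)) * binWidth,
             bin_end = (as.numeric(names(tab)) + 1) * binWidth,
             count = as.integer(tab))
}

#' Mean molecule coverage of named feature sub-regions, with ratios
#'
#' In-silico analogue of region-specific quantification (e.g. left LTR vs
#' internal vs right LTR abundance): the mean fraction of each region
#' covered by the molecules of a feature, and all pairwise ratios of those
#' means. A zero denominator is reported as \code{Inf} with the
#' \code{infinite} flag set.
#'
#' @param ems an \code{\linkS4class{EccMoleculeSet}}.
#' @param bundle a \code{\linkS4class{ReferenceBundle}}.
#' @param featureId feature to analyse.
#' @param regions optional named \code{GRanges} of sub-regions; the default
#'   is left LTR, central third (\code{internal}) and right LTR.
#' @return list with \code{coverage} (named means) and \code{ratios}
#'   (data.frame: numerator, denominator, ratio, infinite).
#' @export
regionCoverageRatio <- function(ems, bundle, featureId, regions = NULL) {
  feats <- refFeatures(bundle)
  i <- match(featureId, feats$feature_id)
  if (is.na(i)) stop("unknown feature: ", featureId)
  feat <- feats[i]
  if (is.null(regions)) {
    ltr <- ltrRanges(bundle, featureId)
    w <- width(feat)
    third <- IRanges(start(feat) + floor(w / 3),
                     start(feat) + floor(2 * w / 3) - 1L)
    internal <- GRanges(seqnames(feat), third)
    regions <- if (length(ltr) == 2L)
      setNames(c(granges(ltr)[1], internal, granges(ltr)[2]),
               c("left", "internal", "right"))
    else setNames(c(GRanges(seqnames(feat),
                            IRanges(start(feat), start(feat) + floor(w / 3) - 1L)),
                    internal,
                    GRanges(seqnames(feat),
                            IRanges(start(feat) + floor(2 * w / 3), end(feat)))),
                  c("left", "internal", "right"))
  }
  info <- moleculeInfo(ems)
  sel <- which(info$feature_id == featureId)
  if (!length(sel)) stop("no molecules assigned to ", featureId)
  fps <- moleculeFootprints(ems)[sel]
  cov <- vapply(seq_along(regions), function(r) {
    reg <- granges(regions[r])
    mean(vapply(seq_along(fps), function(m) {
      ov <- GenomicRanges::intersect(fps[[m]], reg, ignore.strand = TRUE)
      sum(width(ov)) / sum(width(reg))
    }, numeric(1)))
  }, numeric(1))
  names(cov) <- names(regions)
  pairs <- expand.grid(numerator = names(cov), denominator = names(cov),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$numerator != pairs$denominator, ]
  pairs$ratio <- cov[pairs$numerator] / cov[pairs$denominator]
  pairs$infinite <- cov[pairs$denominator] == 0
  rownames(pairs) <- NULL
  list(coverage = cov, ratios = pairs)
}
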