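#' ReferenceBundle: genome sequences plus TE/gene annotation
#'
#' Container for a (synthetic or real) reference genome together with its
#' feature annotation. Features are TEs or genes; TE features may carry two
#' long terminal repeat (LTR) sub-intervals, stored feature-relative in
#' \code{ltr_rel} (an \code{IRangesList}, 1-based, one element per feature).
#' All coordinates follow the Bioconductor convention (1-based, closed);
#' conversion to BED (0-based half-open) happens only when files are written.
#'
#' @slot seqs \code{DNAStringSet} of chromosome sequences.
#' @slot features \code{GRanges} with mcols \code{feature_id},
#'   \code{feature_class} (\code{"TE"} or \code{"gene"}) and \code{ltr_rel}.
#'
#' @export
setClass("ReferenceBundle",
  representation(seqs = "DNAStringSet", features = "GRanges"))

setValidity("ReferenceBundle", function(object) {
  msg <- character()
  feats <- object@features
  need <- c("feature_id", "feature_class", "ltr_rel")
  if (!all(need %in% names(mcols(feats))))
    return(paste("features must carry mcols:", paste(need, collapse = ", ")))
  sl <- setNames(width(object@seqs), names(object@seqs))
  if (length(feats)) {
    if (!all(as.character(seqnames(feats)) %in% names(sl)))
      msg <- c(msg, "feature seqnames missing from genome")
    else {
      lens <- sl[as.character(seqnames(feats))]
      if (any(start(feats) < 1L) || any(end(feats) > lens))
        msg <- c(msg, "feature intervals outside their chromosome")
    }
    if (anyDuplicated(feats$feature_id))
      msg <- c(msg, "feature_id values must be unique")
    if (!all(feats$feature_class %in% c("TE", "gene")))
      msg <- c(msg, "feature_class must be 'TE' or 'gene'")
    nltr <- lengths(feats$ltr_rel)
    if (!all(nltr %in% c(0L, 2L)))
      msg <- c(msg, "every feature must have 0 or 2 LTR intervals")
    two <- which(nltr == 2L)
    for (i in two) {
      ir <- sort(feats$ltr_rel[[i]])
      w <- width(feats)[i]
      if (start(ir)[1] != 1L || end(ir)[2] != w)
        msg <- c(msg, sprintf("LTRs of %s are not at the feature ends",
                              feats$feature_id[i]))
      if (end(ir)[1] >= start(ir)[2])
        msg <- c(msg, sprintf("LTRs of %s overlap", feats$feature_id[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ReferenceBundle chromosome sequences
#' @param x,object a \code{ReferenceBundle}
#' @export
refSeqs <- function(x) x@seqs

#' @describeIn ReferenceBundle feature annotation as \code{GRanges}
#' @export
refFeatures <- function(x) x@features

#' @describeIn ReferenceBundle named chromosome lengths
#' @export
refSeqlengths <- function(x) setNames(width(x@seqs), names(x@seqs))

#' Absolute (genome-coordinate) LTR intervals of a feature
#'
#' @param x a \code{ReferenceBundle}
#' @param featureId a feature identifier present in the bundle
#' @return \code{GRanges} with 0 or 2 ranges.
#' @export
ltrRanges <- function(x, featureId) {
  f <- refFeatures(x)
  i <- match(featureId, f$feature_id)
  if (is.na(i)) stop("unknown feature: ", featureId)
  rel <- f$ltr_rel[[i]]
  if (!length(rel)) return(GRanges(seqnames = character()))
  GRanges(seqnames(f)[i], IRanges(start(f)[i] + start(rel) - 1L,
                                  start(f)[i] + end(rel) - 1L),
          strand = strand(f)[i])
}

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle:", length(object@seqs), "chromosome(s),",
      sum(width(object@seqs)), "bp;",
      sum(object@features$feature_class == "TE"), "TE and",
      sum(object@features$feature_class == "gene"), "gene feature(s)\n")
})

#' SimParams: parameters of the synthetic mobilome simulator
#'
#' The error model is a per-base substitution/insertion/deletion process
#' emulating nanopore reads (defaults approximate a ~10\% total error rate).
#' \code{copyNumberDist} and \code{wgsReadLenDist} are sampling functions
#' taking a count and returning that many draws.
#'
#' @slot seed integer seed; all simulator randomness derives from it.
#' @slot subRate,insRate,delRate per-base error probabilities in [0,1).
#' @slot copyNumberDist function(n) returning integer RCA copy numbers >= 1.
#' @slot templateMix named numeric weights over template kinds
#'   (\code{full_TE}, \code{solo_LTR}, \code{two_LTR},
#'   \code{internal_fragment}, \code{gene_circle}); they must sum to 1.
#' @slot nEccReads,nWgsReads read counts per eccDNA replicate / WGS control.
#' @slot wgsReadLenDist function(n) returning WGS fragment lengths.
#' @slot wgsConcatFraction fraction of WGS reads that are concatemers
#'   (background circles seen in whole-genome controls).
#' @slot featureIds optional subset of feature ids templates are drawn from
#'   (character(0) = all compatible features).
#' @export
setClass("SimParams",
  representation(seed = "integer", subRate = "numeric", insRate = "numeric",
                 delRate = "numeric", copyNumberDist = "function",
                 templateMix = "numeric", nEccReads = "integer",
                 nWgsReads = "integer", wgsReadLenDist = "function",
                 wgsConcatFraction = "numeric", featureIds = "character"))

TEMPLATE_KINDS <- c("full_TE", "solo_LTR", "two_LTR", "internal_fragment",
                    "gene_circle")

setValidity("SimParams", function(object) {
  msg <- character()
  for (s in c("subRate", "insRate", "delRate")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v >= 1)
      msg <- c(msg, paste(s, "must be in [0,1)"))
  }
  if (!setequal(names(object@templateMix), TEMPLATE_KINDS))
    msg <- c(msg, paste("templateMix must be named over:",
                        paste(TEMPLATE_KINDS, collapse = ", ")))
  else if (any(object@templateMix < 0) ||
           abs(sum(object@templateMix) - 1) > 1e-8)
    msg <- c(msg, "templateMix weights must be >= 0 and sum to 1")
  if (object@nEccReads < 0L || object@nWgsReads < 0L)
    msg <- c(msg, "read counts must be >= 0")
  if (object@wgsConcatFraction < 0 || object@wgsConcatFraction > 1)
    msg <- c(msg, "wgsConcatFraction must be in [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: seed=%d  sub/ins/del=%.3g/%.3g/%.3g  ecc=%d  wgs=%d\n",
    object@seed, object@subRate, object@insRate, object@delRate,
    object@nEccReads, object@nWgsReads))
  cat("  mix:", paste(sprintf("%s=%.2f", names(object@templateMix),
                              object@templateMix), collapse = " "), "\n")
})

#' TandemDecomposition: one read's inferred tandem-repeat structure
#'
#' An RCA read is a tandem concatemer of monomers, each one pass around the
#' source circle. This class records the estimated monomer period, the number
#' of complete monomer copies, the monomer intervals on the read (1-based,
#' closed), the error-corrected consensus monomer, and the mean identity of
#' the monomers to the consensus. Reads in which no tandem structure is found
#' have \code{copyNumber} 0 and an \code{NA} period.
#'
#' @slot readId character read identifier.
#' @slot readLen read length (bp).
#' @slot period estimated monomer length (bp), NA when no repeat was found.
#' @slot copyNumber number of complete monomer copies.
#' @slot monomerIntervals \code{IRanges} of complete monomers on the read.
#' @slot consensus consensus monomer sequence (character; "" when none).
#' @slot meanIdentity mean per-monomer identity to the consensus, in [0,1].
#' @export
setClass("TandemDecomposition",
  representation(readId = "character", readLen = "integer",
                 period = "numeric", copyNumber = "integer",
                 monomerIntervals = "IRanges", consensus = "character",
                 meanIdentity = "numeric"))

setValidity("TandemDecomposition", function(object) {
  msg <- character()
  iv <- object@monomerIntervals
  if (object@copyNumber != length(iv))
    msg <- c(msg, "copyNumber must equal the number of monomer intervals")
  if (length(iv) > 1L) {
    if (is.unsorted(start(iv)))
      msg <- c(msg, "monomer intervals must be sorted")
    if (any(start(iv)[-1] <= end(iv)[-length(iv)]))
      msg <- c(msg, "monomer intervals must not overlap")
  }
  if (length(iv) && !is.na(object@period)) {
    if (any(width(iv) < 0.8 * object@period | width(iv) > 1.2 * object@period))
      msg <- c(msg, "monomer interval lengths must be within 20% of the period")
  }
  mi <- object@meanIdentity
  if (!is.na(mi) && (mi < 0 || mi > 1))
    msg <- c(msg, "meanIdentity must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn TandemDecomposition read identifier
#' @param x a \code{TandemDecomposition}
#' @export
readId <- function(x) x@readId
#' @describeIn TandemDecomposition estimated monomer period (bp)
#' @export
period <- function(x) x@period
#' @describeIn TandemDecomposition number of complete monomer copies
#' @export
copyNumber <- function(x) x@copyNumber
#' @describeIn TandemDecomposition monomer intervals on the read
#' @export
monomerIntervals <- function(x) x@monomerIntervals
#' @describeIn TandemDecomposition consensus monomer sequence
#' @export
consensusSeq <- function(x) x@consensus
#' @describeIn TandemDecomposition mean monomer identity to the consensus
#' @export
meanIdentity <- function(x) x@meanIdentity

setMethod("show", "TandemDecomposition", function(object) {
  cat(sprintf(
    "TandemDecomposition %s: len=%d  period=%s  copies=%d  identity=%s\n",
    object@readId, object@readLen,
    ifelse(is.na(object@period), "NA", sprintf("%.0f", object@period)),
    object@copyNumber,
    ifelse(is.na(object@meanIdentity), "NA",
           sprintf("%.3f", object@meanIdentity))))
})

#' EccMoleculeSet: reconstructed eccDNA molecules in their TE frame
#'
#' One row per assigned molecule. \code{bins} holds the fractional coverage
#' of the source feature divided into \code{nbins} equal bins (values in
#' [0,1]); \code{footprints} keeps the un-binned genome-coordinate coverage
#' of each molecule; \code{info} carries per-molecule statistics and the
#' structural class; \code{unassigned} records reads that could not be
#' placed (with a reason: \code{unmapped}, \code{ambiguous} across features,
#' or \code{no_feature}).
#'
#' @slot bins numeric matrix, molecules x bins.
#' @slot footprints \code{GRangesList}, one element per molecule.
#' @slot info \code{DFrame} with columns \code{read_id}, \code{feature_id},
#'   \code{monomer_len}, \code{covered_fraction}, \code{ltr_fraction},
#'   \code{ambiguous_within_feature}, \code{flank}, \code{class}.
#' @slot nbins number of bins.
#' @slot unassigned \code{DFrame} with \code{read_id}, \code{reason}.
#' @export
setClass("EccMoleculeSet",
  representation(bins = "matrix", footprints = "GRangesList",
                 info = "DFrame", nbins = "integer", unassigned = "DFrame"))

setValidity("EccMoleculeSet", function(object) {
  msg <- character()
  if (nrow(object@bins) != nrow(object@info))
    msg <- c(msg, "bins and info must have one row per molecule")
  if (nrow(object@bins) && ncol(object@bins) != object@nbins)
    msg <- c(msg, "bins must have nbins columns")
  if (nrow(object@bins) &&
      (min(object@bins) < 0 || max(object@bins) > 1 + 1e-9))
    msg <- c(msg, "bin values must lie in [0,1]")
  cf <- object@info$covered_fraction
  if (length(cf) && (any(cf < 0) || any(cf > 1 + 1e-9)))
    msg <- c(msg, "covered_fraction must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn EccMoleculeSet per-molecule statistics table
#' @param x an \code{EccMoleculeSet}
#' @export
moleculeInfo <- function(x) x@info
#' @describeIn EccMoleculeSet molecules-by-bins coverage matrix
#' @export
moleculeBins <- function(x) x@bins
#' @describeIn EccMoleculeSet unassigned reads and reasons
#' @export
unassignedReads <- function(x) x@unassigned
#' @describeIn EccMoleculeSet genome-coordinate footprints
#' @export
moleculeFootprints <- function(x) x@footprints

setMethod("show", "EccMoleculeSet", function(object) {
  cat(sprintf("EccMoleculeSet: %d molecule(s) over %d bins; %d unassigned\n",
              nrow(object@info), object@nbins, nrow(object@unassigned)))
  if (nrow(object@info)) {
    tab <- table(object@info$class)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = " "), "\n")
  }
})
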