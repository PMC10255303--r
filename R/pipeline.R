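#' Build and validate a pipeline configuration
#'
#' Flat key-value configuration covering every stage, with the standard
#' thresholds as defaults: 500-bp windows, log2 ratio > 3, minimum locus
#' length 1000 bp, alpha 0.01, >= 2 copies (peaks) / >= 3 copies
#' (structure), read length > 500 bp, mapq >= 30, per-100,000-read
#' normalization. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return validated named list with class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L, w = 500L, log2_min = 3, min_len = 1000L, alpha = 0.01,
    min_copies_peaks = 2L, min_copies_structure = 3L, min_read_len = 500L,
    min_mapq = 30L, fl_min_cov = 0.9, ltr_min = 0.8, n_bins = 50L,
    pseudocount = 1, map_k = 15L, min_chain_seeds = 3L,
    n_chroms = 2L, chrom_len = 100000L, n_tes = 4L, te_len = 5000L,
    ltr_len = 500L, n_ecc_reads = 100L, n_wgs_reads = 500L,
    sub_rate = 0.05, ins_rate = 0.025, del_rate = 0.025)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  ok <- function(cond, what) if (!cond) stop("invalid config: ", what)
  ok(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0,1)")
  ok(cfg$w >= 50, "w must be >= 50")
  ok(cfg$log2_min >= 0, "log2_min must be >= 0")
  ok(cfg$min_len >= cfg$w, "min_len must be >= w")
  ok(cfg$min_copies_peaks >= 1 && cfg$min_copies_structure >= 1,
     "copy thresholds must be >= 1")
  ok(cfg$min_mapq >= 0 && cfg$min_mapq <= 60, "min_mapq must be in [0,60]")
  ok(cfg$fl_min_cov > 0 && cfg$fl_min_cov <= 1,
     "fl_min_cov must lie in (0,1]")
  ok(cfg$ltr_min > 0.5 && cfg$ltr_min <= 1, "ltr_min must lie in (0.5,1]")
  ok(cfg$pseudocount >= 1, "pseudocount must be >= 1")
  for (r in c("sub_rate", "ins_rate", "del_rate"))
    ok(cfg[[r]] >= 0 && cfg[[r]] < 1, paste(r, "must lie in [0,1)"))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full eccDNA pipeline on simulated data
#'
#' Executes: simulation -> concatemer decomposition (>= 2 copies) ->
#' mapping -> window counting -> locus calling and Fisher testing; and in
#' parallel the structure branch: decomposition filter at >= 3 copies ->
#' per-monomer mapping -> molecule projection, grouping and length
#' histogram. Every output is written under \code{outDir} together with a
#' manifest carrying the effective configuration and its hash; identical
#' configurations yield identical manifests and outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory.
#' @return invisibly, the manifest list.
#' @export
runAll <- function(config = pipelineConfig(), outDir = tempfile("eccrun")) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  manifest <- list(config = unclass(config),
                   config_hash = .configHash(config), stages = list())
  addStage <- function(name, outputs) {
    manifest$stages[[name]] <<- list(outputs = outputs)
  }

  bundle <- stage("sim-reference", makeReference(
    seed = config$seed, nChroms = config$n_chroms,
    chromLen = config$chrom_len, nTes = config$n_tes,
    teLen = config$te_len, ltrLen = config$ltr_len))
  refPaths <- writeReference(bundle, file.path(outDir, "reference"))
  addStage("sim-reference", as.list(refPaths))

  params <- simParams(seed = config$seed, subRate = config$sub_rate,
                      insRate = config$ins_rate, delRate = config$del_rate,
                      nEccReads = config$n_ecc_reads,
                      nWgsReads = config$n_wgs_reads)
  sim <- stage("sim-reads", simulateSamples(bundle, params,
                                            file.path(outDir, "reads")))
  addStage("sim-reads", list(dir = file.path(outDir, "reads")))

  decomps <- stage("concat", lapply(sim$reads, decomposeReads))
  for (nm in names(decomps))
    writeDecompositionTable(decomps[[nm]],
                            file.path(outDir, paste0("decomp_", nm, ".tsv")))
  addStage("concat", list(tables = file.path(
    outDir, paste0("decomp_", names(decomps), ".tsv"))))

  keptPeaks <- lapply(decomps, filterConcatemers,
                      minCopies = config$min_copies_peaks,
                      minReadLen = config$min_read_len)
  # eccDNA samples: concatemer-retained reads only; the WGS control is the
  # whole-genome coverage baseline and is mapped unfiltered
  recs <- stage("map", lapply(names(sim$reads), function(nm) {
    reads <- if (nm == "wgs") sim$reads[[nm]] else
      sim$reads[[nm]][vapply(keptPeaks[[nm]]$retained, readId, character(1))]
    filterAlignments(mapReads(reads, bundle, k = config$map_k,
                              minChainSeeds = config$min_chain_seeds),
                     minMapq = config$min_mapq)
  }))
  names(recs) <- names(sim$reads)
  for (nm in names(recs))
    writeSam(recs[[nm]], file.path(outDir, paste0(nm, ".sam")))
  addStage("map", list(sam = file.path(outDir,
                                       paste0(names(recs), ".sam"))))

  windows <- makeWindows(bundle, config$w)
  se <- windowCounts(recs, windows)
  loci <- stage("peaks", callEccLoci(
    se, testCols = c("ecc_rep1", "ecc_rep2"), backgroundCol = "wgs",
    log2Min = config$log2_min, minLen = config$min_len,
    pseudocount = config$pseudocount))
  lociDf <- as.data.frame(loci)
  write.table(lociDf, file.path(outDir, "ecc_loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tested <- fisherWindowTest(
    windowCounts(list(
      stress = c(recs$ecc_rep1, recs$ecc_rep2), control = recs$wgs),
      windows),
    "stress", "control", alpha = config$alpha)
  fpeaks <- annotatePeaks(mergeSignificant(tested), bundle,
                          c(recs$ecc_rep1, recs$ecc_rep2))
  write.table(as.data.frame(fpeaks), file.path(outDir, "fisher_peaks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  addStage("peaks", list(loci = file.path(outDir, "ecc_loci.tsv"),
                         fisher = file.path(outDir, "fisher_peaks.tsv")))

  structDecomp <- stage("concat-structure", {
    eccDecomps <- c(decomps$ecc_rep1, decomps$ecc_rep2)
    filterConcatemers(eccDecomps, minCopies = config$min_copies_structure,
                      minReadLen = config$min_read_len)$retained
  })
  eccReads <- c(sim$reads$ecc_rep1, sim$reads$ecc_rep2)
  monomers <- do.call(c, unname(lapply(structDecomp, function(d)
    monomerSeqs(d, eccReads[[readId(d)]]))))
  if (is.null(monomers)) monomers <- DNAStringSet()
  monRecs <- stage("map-monomers",
                   mapReads(monomers, bundle, k = config$map_k,
                            minChainSeeds = config$min_chain_seeds))
  writeSam(monRecs, file.path(outDir, "monomers.sam"),
           seqlengths = refSeqlengths(bundle))
  ems <- stage("structure", projectMolecules(
    structDecomp, monRecs, bundle, nBins = config$n_bins,
    minMapq = config$min_mapq, flMinCov = config$fl_min_cov,
    ltrMin = config$ltr_min))
  write.table(as.data.frame(moleculeInfo(ems)),
              file.path(outDir, "molecules.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  grp <- groupStructures(ems)
  write.table(as.data.frame(grp$groups), file.path(outDir, "groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(grp$matrix, file.path(outDir, "heatmap_matrix.tsv"),
              sep = "\t", quote = FALSE, col.names = FALSE)
  write.table(lengthHistogram(ems), file.path(outDir, "length_histogram.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  addStage("structure", list(
    molecules = file.path(outDir, "molecules.tsv"),
    groups = file.path(outDir, "groups.tsv"),
    heatmap = file.path(outDir, "heatmap_matrix.tsv"),
    histogram = file.path(outDir, "length_histogram.tsv")))

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  addStage("manifest", list(path = manifestPath))
  invisible(manifest)
}

# order-independent hash of the effective configuration
.configHash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  s <- paste(names(x), vapply(x, function(v) paste(format(v, digits = 15),
                                                   collapse = ","),
                              character(1)),
             sep = "=", collapse = ";")
  # FNV-1a over the serialized key=value string (32-bit arithmetic kept
  # exact in doubles by splitting the multiply)
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    lo16 <- h %% 65536; hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
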