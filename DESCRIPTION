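Package: eccMobilome
Title: Extrachromosomal Circular DNA Detection and Structure Analysis from
    Rolling-Circle Amplified Nanopore Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects eccDNA-producing loci and reconstructs individual
    extrachromosomal circular DNA (eccDNA) molecules from long nanopore reads of
    rolling-circle amplification (RCA) products. RCA converts each circle into a
    linear concatemer of tandem monomer copies; the package decomposes such
    concatemer reads into monomers, builds error-corrected consensus circles, maps
    reads and monomers to a reference genome, counts filtered alignments into
    fixed genome windows, calls eccDNA-producing loci by normalized log2 ratio
    against a whole-genome control with replicate concordance, calls
    stress-responsive differential peaks with a two-sided Fisher exact test and
    Benjamini-Hochberg correction, and classifies molecules from LTR
    retrotransposons into full-length versus truncated (solo-LTR, two-LTR,
    internal) circle forms. A built-in synthetic mobilome simulator generates
    reference genomes, TE annotations, RCA concatemer reads and background
    whole-genome reads deterministically from a seed, so the whole pipeline is
    testable end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
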