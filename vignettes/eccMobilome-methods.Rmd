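---
title: "Detecting and reconstructing eccDNA from rolling-circle amplified nanopore reads"
author: "eccMobilome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and reconstructing eccDNA from rolling-circle amplified nanopore reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Background

Extrachromosomal circular DNAs (eccDNAs) arise in plant and animal genomes,
prominently from the activity of LTR retrotransposons. Mobilome-seq enriches
them by exonuclease digestion of linear DNA followed by rolling-circle
amplification (RCA) with Phi29 polymerase: each circle becomes a long linear
concatemer in which one *monomer* — one pass around the circle — is repeated
in tandem. Long nanopore reads capture several monomers per read, which has
two consequences this package exploits:

* a read containing two or more tandem monomer copies is near-certain
  evidence of a circular template, so the concatemer structure itself is the
  enrichment filter;
* the monomers are independent error-corrupted observations of the same
  circle, so a consensus over them reconstructs the full circle sequence,
  including its length — something short reads cannot do.

`eccMobilome` implements the full desk-scale pipeline: concatemer
decomposition, consensus building, read/monomer mapping, windowed locus
calling against a whole-genome (WGS) control, differential peak calling
between conditions, and per-molecule structural classification of TE-derived
circles into full-length (`fl`) and truncated (`tr_LTR`, `tr_internal`,
`tr_other`) forms. A seeded simulator generates every input the pipeline
consumes, so all claims are testable without external data.

## Concatemer decomposition

**Period estimation** (`estimatePeriod`). For every k-mer (default `k = 13`)
occurring more than once on a read, the distances between consecutive
occurrences are collected. On a tandem repeat these distances pile up at the
monomer length (and its multiples); the estimate is the mode of the distance
distribution, where the support of a candidate is the number of distances
within ±10% of it. Ties go to the smaller period, preferring the fundamental
period over its multiples. Periods under `minPeriod = 100` bp are treated as
low-complexity repeats and skipped; the search is capped at 50 kb. A
candidate needs at least `minSupport = 5` distances. With 13-mers, a pair of
adjacent monomers at ~10% error per copy retains roughly
$0.9^{13 \cdot 2} \approx 6\%$ of positions as intact shared k-mers — ample
support for templates of a few hundred bases and up.

**Segmentation** (`segmentMonomers`). An anchor window of one period length
is taken from the read start. Candidate monomer starts are found by binning
the diagonals (read position minus anchor position) of exact 11-mer matches
between anchor and read; bins holding at least 3 matches seed a candidate.
An absolute support threshold is deliberate: sparse random matches almost
never stack three deep in one bin, while relative thresholds are distorted by
the anchor's perfect self-match. Each candidate is then refined by a banded
fit alignment of the whole anchor against the read around that offset (band
4% of the period, at least 60 bp; scores 2/−4/−4). A fit is accepted when its
identity reaches 0.6 — two independent 10%-error copies align at ~0.80, while
unrelated sequence aligns near 0.50, so the threshold separates cleanly —
and its length is within 20% of the period. Boundaries are the accepted fit
starts; only complete monomers are kept (a terminal partial copy fails the
fit), and a read whose accepted spacings drift more than 20% from their
median is rejected with a reason code.

**Consensus** (`consensusMonomer`). Star alignment around the medoid
monomer: the monomer with the highest mean pairwise banded identity is the
reference; every monomer is aligned to it; each medoid column is called by
majority vote with ties kept as the medoid base. Insertion slots between
medoid columns are voted the same way, so true bases that the medoid lost to
a sequencing deletion are recovered from the other monomers; this keeps the
consensus length essentially unbiased. No polishing beyond the majority vote
is attempted. At 10 monomers and 10% read error the consensus is typically
≥99% identical to the true circle.

**Fundamental-period check.** A circle whose sequence is itself a doubled
unit (the classic case: a circle of two identical LTRs) yields a first
period estimate of twice the fundamental unit. After the consensus is built
its two halves are aligned; at ≥90% identity the period is halved and the
read re-segmented. When the consensus is skipped (`buildConsensus = FALSE`,
used for large period/copy screens), the same check runs on a raw monomer
window with a noise-tolerant 0.7 threshold, since two raw 10%-error copies
cannot reach 90%.

**Retention filter** (`filterConcatemers`). A read is kept when it has at
least `minCopies` complete monomers *and* its length strictly exceeds
500 bp. Peak calling uses `minCopies = 2`; structure analysis, which needs
more evidence per molecule, uses `minCopies = 3`. Note that the copy filter
applies to the *fundamental* period: a two-LTR circle of identical LTRs
legitimately decomposes to twice as many single-LTR monomers.

## Mapping

`mapReads` is a deliberate desk-scale seed–chain–extend mapper for genomes
up to ~10 Mb; for real genomes, SAM ingestion (`readSam`) is the supported
route and all downstream stages are agnostic to which mapper produced the
alignments. Exact 15-mer seeds on both strands are chained per (chromosome,
strand) into runs of near-constant diagonal (gap ≤ 100 bp), chains are
clustered into candidate loci by reference overlap, and the best chain per
locus is extended with a banded alignment (band 10% of span, capped at
200 bp) for an identity estimate.

Mapping quality is a surrogate built to reproduce *filtering behaviour*, not
any specific aligner's formula: `mapq = min(60, round(40·(1 − s2/s1)))` with
`s1`, `s2` the best and second-best *locus* scores, 60 when unique, and 0
for secondary records. Two details matter:

* chains at the *same* locus are not ambiguity — an RCA concatemer read
  produces one chain per tandem copy at its single source locus, and a
  rotated circular monomer maps as two collinear segments. `s2` is therefore
  taken over alternative loci only;
* near-identical TE family copies elsewhere in the genome *do* compete, so
  multi-copy families fall below the `mapq ≥ 30` filter, reproducing the
  cross-mapping behaviour real aligners show on recently expanded families.

`filterAlignments` applies the standard primary-only, `mapq ≥ 30` filter
(the `samtools view -F 3840 -q 30` semantics) and is idempotent.

## Windowed locus calling

The genome is tiled into non-overlapping 500-bp windows (`makeWindows`); a
filtered alignment increments every window it overlaps by ≥1 bp
(`windowCounts`, intersect semantics), and the library size of a sample is
its number of distinct counted reads. Counts are compared after adding a
pseudocount of 1 and scaling per 100,000 mapped reads; the pseudocount keeps
zero-count windows finite and makes the log2 ratio of two empty windows
exactly 0.

**Ratio mode** (`callEccLoci`): per replicate, windows with
`log2(test/background) > 3` are marked, adjacent marked windows merged
(book-ended only, no gap bridging), merged loci shorter than 1000 bp
dropped, and — with two replicates — loci intersected so that only
replicate-concordant signal survives. The threshold and minimum length are
the field-standard values for this assay; both are configuration keys.
`replicateConcordance` reports the fraction of windows whose
between-replicate |log2| ratio is within 2, the diagnostic that motivates a
threshold of 3.

**Fisher mode** (`fisherWindowTest`): per window, the 2×2 table
`[[c_stress, N_stress − c_stress], [c_control, N_control − c_control]]`
(in-window reads versus library remainder) is tested with the package's
two-sided Fisher kernel; Benjamini–Hochberg adjustment runs over the family
of windows with any counts (zero/zero windows are excluded from the family —
they carry no information and would only dilute `m`; the choice is recorded
in the result metadata). A window is significant at `q < 0.01` *and*
normalized stress coverage above control (increased eccDNA production).
Control replicates are pooled; stress replicates can be tested separately
and intersected. `mergeSignificant` merges book-ended significant windows
into peaks (peak p/q = minima, counts summed) and `annotatePeaks` attributes
peak-supporting reads to overlapping features, yielding per-feature read
shares.

## Structure analysis

For every read passing the ≥3-copy filter, its monomers are mapped
individually and the union of their footprints is projected onto the source
feature (`projectMolecules`): the feature with the largest footprint overlap
wins, ties break by genome order, and flank bases outside the feature are
ignored but flagged. The footprint within the feature is binned into 50
equal bins of the feature frame (bin value = covered fraction; binarized at
0.5 for grouping), giving the heatmap matrix; `covered_fraction` and
`ltr_fraction` are computed from the un-binned footprint.

Classification (`classifyMolecule`): `fl` at `covered_fraction ≥ 0.9`;
otherwise `tr_LTR` at `ltr_fraction ≥ 0.8`, `tr_internal` at
`ltr_fraction ≤ 0.2`, `tr_other` between. The fl/tr distinction is defined
visually in the literature, never numerically; 0.9 and 0.8 are this
package's explicit operationalization, exposed in the configuration and
recorded in outputs. Molecule length is the consensus monomer length — the
inferred circle size — never the read length, because the RCA copy number is
amplification artifact, not biology.

Two ambiguity rules deserve note. A molecule whose monomers only map below
`mapq 30` is *rescued* when every candidate placement falls inside one
single feature — the typical case being a solo-LTR circle matching both
identical LTRs of its source element; the union of the placements is
projected and the molecule flagged `ambiguous_within_feature`. Its class is
unaffected (`ltr_fraction` is 1 either way), though its heatmap pattern
shows both LTR ends, which is also the honest statement of what the data
can resolve: with identical LTRs, solo-LTR and two-LTR circles are
indistinguishable. Ambiguity *across* features (near-identical TE family
copies) sends the read to a family-level unassigned bucket rather than
dropping it silently; SNP-based disambiguation of family copies is out of
scope.

`groupStructures` partitions molecules by binarized bin pattern (groups
ordered by count), `lengthHistogram` bins circle sizes (default 100-bp
bins, left-closed), and `regionCoverageRatio` reports mean molecule coverage
of named sub-regions (default: left LTR, central third, right LTR) with all
pairwise ratios — the in-silico analogue of region-specific qPCR
quantification; a zero denominator is flagged infinite rather than silently
dropped.

## Statistical kernels

The three kernels are self-contained and oracle-tested: a two-sided Fisher
exact test (summation over all tables with the observed margins whose
hypergeometric probability is at most the observed one, with a 1e-7
relative tolerance on the comparison; log-gamma arithmetic so library-scale
margins cannot overflow), the Yates continuity-corrected chi-square for 2×2
tables (correction clipped at zero; p from the χ²(1) upper tail), and
Benjamini–Hochberg step-up adjustment. The suite checks them against
independent routes: exhaustive hypergeometric enumeration via `dhyper`,
`fisher.test`, `chisq.test(correct = TRUE)` and `p.adjust(method = "BH")`.
One property often claimed of BH — idempotence — is *not* asserted: it is
false (re-adjusting multiplies sorted values by m/rank again), which is easy
to verify numerically.

## The simulator and what passing tests mean

`makeReference` builds random chromosomes with non-overlapping TE and gene
features; every TE carries two identical LTRs at its ends, and TE1/TE2 form
a ~99%-identical family so that cross-mapping ambiguity is present in every
simulated genome. `simulateRcaRead` rotates a circular template to a random
phase, repeats it, optionally reverse-complements, and applies a per-base
substitution/insertion/deletion process; `simulateSamples` draws two eccDNA
replicates from a template mix plus a uniform linear WGS control, with a
truth record per read.

Defaults are the study conditions: error rates 5%/2.5%/2.5% (≈10% total, an
R9.4.1-era nanopore profile; the assay never consumes base qualities, so
FASTQ qualities are a constant Q12 placeholder); RCA copy numbers from a
geometric distribution truncated to 1..20 with mean ≈4, so both the ≥2 and
≥3 copy filters bite (the empirical copy-number distribution of real RCA
libraries is not published; this is an exposed configuration choice);
full-length templates ≈5 kb and truncated ones ≈1 kb (internal fragments
drawn uniformly from 900–1100 bp), matching the two length scales of
TE-derived circles; solo-LTR 500 bp and two-LTR 1000 bp by construction.
The WGS control can optionally contain a concatemer fraction, as real
whole-genome nanopore runs do (~10%); the default is a clean linear
background.

What the simulator does *not* emulate: signal-level artifacts, basecalling
error structure (homopolymer bias, quality correlation), chimeric and
adapter reads, within-element LTR divergence, nested or fragmented TE
annotations, and genome-scale repeat landscapes (centromeres, rDNA).
Passing tests therefore demonstrate algorithmic correctness under a clean
generative model of the assay, not performance on real libraries — for real
data the external-aligner SAM path and external concatemer-caller TSV path
exist precisely so that production tooling can replace the desk-scale
stand-ins while the downstream statistics stay identical.

Internally all coordinates are 1-based closed (the Bioconductor convention,
since sequence, range and count containers are `DNAStringSet`, `GRanges`
and `RangedSummarizedExperiment`); BED output converts to 0-based half-open
at the boundary, GFF3 stays 1-based, and SAM/alignment query offsets are
0-based half-open as in the formats themselves.

## Problem sizes and runtime

The test-suite simulations use 2×100-kb genomes with four 5-kb TEs, eccDNA
cohorts of 50–70 reads per replicate, WGS controls of 300 reads, a 500-read
decomposition screen, a 100-run global-null calibration of 2000 windows
each, and structure cohorts of 50–60 reads — sizes chosen so each property
is measured with enough events to be stable at the asserted thresholds
while the whole suite stays in the minutes range on a single core. The
mix-ratio recovery check compares against the *realized* template mix of
each cohort (from the truth table) rather than the nominal weights, so it
measures classification error rather than multinomial sampling noise.

## Known limitations

* The built-in mapper has no affine gaps and no split/supplementary
  alignment model; queries spanning structural breakpoints map as separate
  chains. At desk scale this is inconsequential; at genome scale use an
  external aligner and `readSam`.
* Breakpoint-resolution junction calling is not attempted; circle identity
  is established at monomer/consensus level.
* Base qualities are ignored throughout, mirroring the assay's analysis
  conventions.
* Near-identical TE family members cannot be told apart without SNP-level
  curation; such molecules are reported in the family-level bucket.
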