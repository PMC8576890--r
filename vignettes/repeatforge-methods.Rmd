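---
title: "Methods: curating, classifying and dating transposable elements with repeatforge"
author: "repeatforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating, classifying and dating transposable elements with repeatforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`repeatforge` implements a desk-scale repeatome analysis for
transposable elements (TEs): curation of a consensus library against a
genome, subclass/superfamily classification, Kimura 2-parameter (K2P)
divergence landscapes, TE density across gene anatomy, and family-level
differential expression. Genome-scale inputs are replaced by a
synthetic-genome simulator that plants TE families with known
divergence, copy number and truncation, so that every stage can be
validated against recorded truth. This vignette explains the models and
the numerical choices; it states no empirical result beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

# The synthetic-data model

`makeBackbone()` draws i.i.d. nucleotides at a configurable GC content
(default 0.43, matching the background composition at which the
curation substitution matrix is parameterized). `makeTEFamily()` builds
a consensus per `teFamilySpec()`: exact reverse-complement terminal
inverted repeat (TIR) arms when `tirLength > 0`, and, for coding
families, an embedded open reading frame of at least 100 aa (ATG, 109+
non-stop codons, stop). Non-coding consensi are rejection-sampled until
no six-frame ORF of 100 aa remains — random DNA of a few kb carries
such ORFs surprisingly often (roughly one expected stop-free 100-codon
stretch per kb across six frames), so this step is not cosmetic.

`mutateCopy()` applies a K2P substitution process: the per-site
transition probability $p$ and transversion probability $q = p/\kappa$
(default $\kappa = 2$, a typical insect transition bias) are obtained
by numerically inverting

$$K = -\tfrac12 \ln\!\big((1-2p-q)\sqrt{1-2q}\big)$$

so the expected distance of a copy equals the family's target.
Insertions and deletions of 1–5 bp (uniform) occur at a configurable
per-site rate; the paper-style hit tables report `%del`/`%ins` but no
indel model, so the 1–5 uniform choice is ours. The default indel rate
used when planting copies is 0.002/bp — small relative to
substitutions, as in young insect TE families. `plantCopies()` inserts
copies at uniformly random positions of the growing genome, never
inside gene space (or an explicit `avoid` set) and never inside a
previous copy unless nesting is drawn; LINE-like copies are 5'-truncated
with exponentially distributed truncated length (canonical
target-primed reverse transcription biology; the choice to truncate
only LINE-like families is ours). Gene models passed through
`plantCopies()` are returned with coordinates shifted through every
insertion, so the annotation and the genome stay consistent.

What the simulator does **not** emulate: satellite arrays beyond simple
tandem repeats, CpG hypermutability (consensus CpG enrichment is off by
default), nested deletion structures, segmental duplications, and
sequencing/assembly error. Tests passing on these simulations therefore
validate the *rules and estimators*, not robustness to assembly
artifacts.

`simulateTECounts()` draws family-by-sample counts from a negative
binomial with log-normal base means (median ≈ 150), log-normal size
factors (sd 0.15 on the log scale), dispersion `Var = mu + a mu^2`, and
a chosen fraction of truly differential families at a symmetric log2
fold change.

# Homology search

`naiveHomologySearch()` is a k-mer seeded local aligner sized for
megabase genomes: exact 11-mers sampled every 4 bp of each consensus
(both strands) are located with a sorted k-mer index of the scaffold,
chained by diagonal (band half-width 32, genomic chaining gap 50 bp),
and each candidate with at least two chained seeds is refined by a
banded affine local alignment (+1/−1, gap open 4, extend 1; C++). The
default reporting cutoff is score 200. With these defaults recall on
planted copies ≥ 500 bp is essentially complete up to 20% divergence
(two chained exact 11-mers are practically guaranteed there, while
isolated random 11-mer matches are suppressed). Hits of one family that
are ≥ 90% contained in a better hit are collapsed; TIR elements match
their own reverse complement through their arms, so this dedup works
across strands. `%div`, `%del` and `%ins` are computed per aligned
column, and each hit records its K2P divergence from the actual
alignment.

# Library curation

The curation pipeline follows the classical consensus-quality steps:

* **Trim/split** (`trimSplitConsensus`): the per-position genomic
  support is computed from the hit table; the cutoff is 5% of the mean
  depth; maximal runs at or above the cutoff become segments, terminal
  low-support runs are trimmed and internal ones split. Segments below
  `minSegment` (default 50 bp, below seed detectability) are dropped.
  An all-zero profile yields a flagged empty result rather than an
  error.
* **80/80 deduplication** (`clusterLibrary`): greedy length-descending
  clustering; a sequence joins a longer representative at ≥ 80%
  identity over ≥ 80% of the *shorter* sequence's length, in either
  orientation. Identity comes from a banded local alignment restricted
  to the diagonals a near-duplicate can occupy (drift 400 bp), after a
  shared 11-mer prescreen that skips clearly unrelated pairs. The
  operation is idempotent, which the tests assert.
* **Support filter** (`filterLibrary`): the copy-equivalent of a
  consensus is total aligned genomic bp divided by consensus length.
  The published removal rule ("under 200 bp and represented by less
  than two full-length copies") is ambiguous between AND and OR; the
  default (strict) reading keeps a consensus only if *both* length ≥
  200 bp and copy-equivalent ≥ 2 hold, and `mode = "lenient"` provides
  the other reading.
* **Tandem filter** (`tandemFilter`): a k-mer periodicity detector
  (period ≤ 12, ≥ 3 units) masks tandem arrays; sequences > 80% masked
  or < 100 bp are dropped.
* **Extension** (`extendConsensus`): instances aligned in consensus
  coordinates, with recorded genomic flanks, are extended column by
  column. The consensus base of a new column maximizes the summed
  log-odds score of the contributing instance bases under a K2P model
  at 20% divergence and 43% GC, scaled so a match averages +10; a side
  stops when the best net column score is ≤ 27, i.e. roughly three
  sequences in agreement. Extension is column-synchronous (no gaps are
  opened during extension); the full per-row dynamic programming of the
  reference implementation is deliberately not reproduced, which is why
  the stated −28/−6 affine penalties do not appear as tunables here.
  Because match scores are composition-dependent (A/T matches ≈ +8.9,
  G/C ≈ +11.4), "three sequences" is an average, not an exact count.

# Classification

Each consensus receives up to three votes: nucleotide homology against
a labeled reference library (per superfamily, scores of non-overlapping
hits are summed so fragments of related families can support one call;
call emitted at combined length ratio ≥ 0.08), translated-protein
homology (six-frame translation, local BLOSUM62 alignment against
labeled TE proteins; ratio ≥ 0.03 with hit length in aa × 3), and
structure (an einverted-style inverted-repeat search, match +3,
mismatch −4, affine gaps, minimum score 50, arms within 100 bp of the
termini). The subclass is assigned when two of the three sources agree;
otherwise TIR if a terminal inverted repeat was found, else Unknown.
The structural source votes only the subclass "TIR", never a
superfamily; a tie between two single-vote superfamilies assigns none.
MITEs are called when TIRs are present but no ORF ≥ 100 aa, no protein
homology, and length ≤ 1 kb (a configurable cap — the literature gives
a tendency, not a rule).

# Divergence landscapes

`pairwiseK2P()` computes the K2P distance over ungapped alignment
columns. With CpG adjustment, transitions at consensus CpG dinucleotide
positions are down-weighted to 1/10, and the two positions of one CpG
contribute at most one transition before weighting — the convention of
the widely used repeat-landscape utilities, stated here explicitly
because the source tools give no formula. Saturated alignments
(non-positive logarithm arguments) report `NA` and are excluded from
landscapes, counted in an `excludedBp` attribute. `resolveOverlaps()`
assigns every genomic bp to the highest-scoring overlapping hit (ties:
earlier start, then input order), so total attributed bp equals the
interval-union length — an invariant the tests assert.
`buildLandscape()` bins attributed bp per 1% of K2P up to 50%
(beyond that, alignments to the consensus are no longer reliable) and
reports percent of genome per subclass or superfamily; bp weighting is
the default, copy-count weighting is available. On simulator output the
landscapes are computed with CpG adjustment off, because the mutation
process is CpG-agnostic and the unadjusted estimator is the unbiased
one there.

# Genomic distribution

`partitionRegions()` builds an exclusive cover of the genome from the
annotation with precedence UTR > exon > intron > intergenic (UTR bp are
excluded from exons so the six published region classes stay disjoint),
plus a strand-aware TSS ± 3 kb overlay track, which necessarily
overlaps the other labels and is therefore not part of the cover — the
cover summing exactly to genome size is a tested invariant.
`windowedTECoverage()` computes the TE bp fraction per 100-bp window
(last partial window normalized by its true width), and
`metaprofile()` rescales every region instance to a fixed number of
bins, 5'→3' by gene strand. `intronTETable()` intersects
overlap-resolved TE fragments with each intron.

# Differential family expression

`aggregateFamilyCounts()` assumes the upstream aligner assigned each
read to exactly one copy (the random-best-hit multimapper contract);
family counts are sums over copies and a read occurring twice in one
sample is an error. `medianOfRatiosNormalize()` is the median-of-ratios
estimator (families with any zero count are excluded from the
geometric-mean reference; with no such family it falls back to
total-count scaling with a warning).

`nbWaldTest()` is a deliberately simple NB Wald test — the full
DESeq2 machinery (dispersion trend fitting, LFC shrinkage, outlier
handling, independent filtering) is not reimplemented. Per family the
dispersion is a pooled within-condition method-of-moments estimate on
normalized counts. With three replicates per group such an estimate is
extremely noisy, and plugging it into a Wald statistic with a normal
reference is anticonservative (measured type-I error about 0.12 at
nominal 0.05 in our calibration simulations), while a
$t_{n_A+n_B-2}$ reference over-corrects and destroys power. We
therefore floor each per-family estimate at the across-family median
dispersion (`moderate = TRUE`) — a crude empirical-Bayes moderation in
the spirit of DESeq2's rule of taking the maximum of the individual
estimate and the fitted trend — and use the normal reference. Under the
package's own calibration simulation (2000 families, 3 vs 3,
dispersion 0.1) this is calibrated (type-I ≈ 0.05) with high power at
|log2FC| = 2; the acceptance tests recompute both. `moderate = FALSE`
recovers the unmoderated estimator. The log2 fold change uses a
pseudocount of ½ on condition means; significance follows the
published thresholds (BH-adjusted p < 0.05 and |log2FC| > 1), with a
separate report for |log2FC| above a highlight level (default 2).
`transcriptionalLoad()` is the percentage of total reads assigned to
TE consensus sequences.

# The benchmark scenario and problem sizes

`benchmarkScenario()` fixes the end-to-end study conditions: a 2-Mb
backbone at GC 0.43 carrying 20 families — six autonomous TIR families
(2.0–2.8 kb, arms 25–50 bp, coding, 12 copies each), five MITEs
(350–600 bp, arms 120–180 bp, non-coding, 35 copies), five LINE-like
families (2.6–3.4 kb, coding, 12 copies, exponential 5' truncation with
mean 800 bp) and four LTR-like families (3.6–4.4 kb, coding, 8
copies) — at divergences spanning 2–20%, about half a megabase of
planted TE sequence. From the same seed it derives the inputs an
analysis would start from: a raw library (true consensi wrapped in
junk flanks, redundant fragments, tandem/random/undersized decoys) and
classification references (12%-diverged nucleotide relatives and the
coding-region proteins of the autonomous families; MITEs get no
homology reference, as in real repeat databases, and must be rescued by
the structural vote). Copy numbers and truncation scale are
illustrative choices — the source study reports no fitted copy-number
or truncation distributions. Smaller problem sizes are used where the
quantity under test does not need the full scenario: landscape-mode
recovery uses 150-kb genomes with 25 copies per family over 20 seeds,
and the region-rank check uses 120-kb genomes with 7 genes over 5
seeds; these sizes keep per-copy sampling error of the K2P estimator
(≈ 1% at 2 kb) well inside the ±1-bin acceptance band.

# Known limitations

* The homology search is exact-seed based; families beyond ~25%
  divergence from their consensus are increasingly invisible, which
  mirrors (but does not numerically match) the sensitivity limits of
  production repeat annotators.
* Consensus extension is ungapped per column, so instances with indels
  in their flanks desynchronize and stop extension early — conservative
  rather than wrong.
* The NB test is two-condition only, with no covariates.
* `plantCopies()` records nested copies as their full stretched span;
  fragment-level truth for nested insertions is not reconstructed.
* Coordinates are single-scaffold in the simulator (multi-scaffold
  genomes are supported everywhere downstream).
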