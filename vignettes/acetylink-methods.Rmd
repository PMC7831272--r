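---
title: "Methods: differential H3K27ac analysis and enhancer-gene linking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential H3K27ac analysis and enhancer-gene linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`acetylink` integrates H3K27ac ChIP-seq with RNA-seq in a two-group,
three-replicate design — as in a study of fatty liver hemorrhagic syndrome
(FLHS) in laying hens — and nominates candidate enhancer target genes by
correlating peak activity with gene expression. This vignette documents the
models, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Coordinate conventions and peak classification

All intervals are 0-based half-open in memory and on disk (BED
convention); GTF is read and written 1-based inclusive. Each gene's
transcription start site (TSS) is taken from its *canonical* transcript,
defined as the transcript with the greatest summed exon length, ties broken
by lexicographically smallest transcript id. On the + strand the TSS is the
transcript's first base; on the − strand its last base.

A merged peak is **proximal** when a TSS lies inside the peak or within
1 kb of a peak boundary — a distance of exactly 1000 bp is proximal,
because "within 1 kb" is inclusive while "distal" requires *over* 1 kb.
The distance from a TSS to a peak is zero inside the peak and otherwise
the distance to the nearest covered base. Feature labels
(promoter-TSS > exon > intron > intergenic) are resolved at the *summit*,
the single base of maximal coverage, so that a peak spanning several
features gets exactly one label; intron ordinals are 1-based and counted
from the TSS side, i.e. strand-aware. Tools differ on whether TSS distance
is measured from the boundary, center or summit, and the choice shifts
category percentages; ours is fixed as stated and tested at the boundary
cases.

## Peak merging

Per-sample peak calls are merged by **single-linkage clustering on summit
distance**: two peaks on the same chromosome join one merged region when
their summits are less than 1 kb apart, and linkage chains. A consequence,
documented rather than hidden, is that a chain of peaks can span more than
1 kb. The merged interval is the union of constituent intervals; the
consensus summit is the summit of the highest-scoring constituent
(leftmost on ties). In one dimension single-linkage clusters are exactly
the maximal runs of summit gaps below the threshold, which is how the
implementation computes them; the test suite checks it against a literal
O(n²) union-find oracle on random instances.

## Signal quantification

Raw signal is the number of read intervals overlapping a merged peak by at
least 1 bp under half-open semantics (an abutting read does not count).
Each count is normalized by sequencing depth (per million mapped reads)
and peak length (per kb), the same for the matched input library, and the
normalized input is subtracted from the normalized ChIP signal to limit
fragmentation bias:

    signal = max(0, chip/(total_chip/1e6 · len/1e3) − input/(total_input/1e6 · len/1e3))

Negative differences are floored at zero (the model is an occupancy
signal, and the subtraction is a bias correction, not a quantity that can
meaningfully go negative). Size factors for the downstream test are fixed
at 1 because depth normalization has already been applied; estimating
size factors *before* input subtraction is a defensible alternative we did
not take, since the subtracted signal is the quantity being modelled.

## The negative-binomial Wald test

Both differential expression and differential acetylation use one
self-contained test. Counts (or rounded normalized signal) are modelled as
negative binomial with variance μ + αμ²; for sample groups A and B with
normalized group means m_A, m_B:

* log2FC = log2((m_B + c)/(m_A + c)) with pseudocount c = 0.5, so zero
  means are defined and the statistic is antisymmetric under swapping
  group membership;
* per-feature dispersion α̂ is the pooled within-group method-of-moments
  estimate (v − μ)/μ², floored at 1e-8, then **moderated halfway toward
  the across-feature median** — with 3 replicates per group the raw
  estimate is unusable, and borrowing strength across features is what
  every serious count-based differential tool does, here in its simplest
  form;
* the Wald statistic is log2FC over a delta-method standard error with
  Var(m̂_g) ≈ (m_g + α m_g²)/n_g, referred to a two-sided normal
  distribution;
* p-values are Benjamini–Hochberg adjusted across features.

There is no dispersion trend fitting, no Cox–Reid adjustment, no
independent filtering and no fold-change shrinkage; these are deliberate
simplifications, and the calibration test (10,000 null features, α = 0.1,
mean 100, 3 vs 3) bounds the realized level: the p < 0.05 fraction must
fall in [0.02, 0.09]. Features with zero counts in both groups get p = 1
and log2FC = 0.

Significance rules differ by stage, mirroring common practice: expression
calls use the *adjusted* p ≤ 0.05 with |log2FC| ≥ 1; acetylation calls use
the *raw* p < 0.05 with |log2FC| ≥ 1, labelled hyper-/hypo-acetylated
(case over control). The raw-p rule is anticonservative by construction —
in the planted-truth recovery study its empirical false discovery rate is
reported but not bounded, and it is large precisely because input
subtraction roughly doubles the variance of the signal while the
threshold ignores multiplicity. Users who need a controlled error rate on
peaks should use the adjusted column, which the output always carries.

## Peak–gene linking

Candidate pairs are all (differential peak, gene) with the gene TSS within
1 Mb of the peak summit on the same chromosome. The link statistic is the
Pearson correlation r between the peak's normalized subtracted signal and
the gene's FPKM across the matched samples, with the exact t-transform
p-value, t = r·√((n−2)/(1−r²)) on n−2 degrees of freedom, two-sided. A
link is kept when |r| > 0.8 **and** p < 0.01. At n = 6 the p-threshold is
the binding constraint: p < 0.01 two-sided implies |r| ≳ 0.917, so the
r-clause only matters for larger designs. Constant vectors make r
undefined; such pairs are dropped with a reason rather than scored.

Top gene lists per direction are built by sorting links by p ascending,
then |r| descending, then gene id; each gene keeps only its best link, and
the list is truncated to k = 100. The distance-decay summary histograms
link counts in 100-kb bins of summit–TSS distance, split by correlation
sign and peak direction; bin totals always sum to the number of links in
range.

## Motif and gene-set enrichment

The PWM scanner scores every window of length L on both strands with the
log2-odds score Σ log2(p_base/bg) against a uniform background,
probabilities clamped at 1e-4 on load so scores stay finite. A window is a
hit at ≥ 0.8 of the maximum achievable score — a HOMER-like relative
threshold — and windows containing N are skipped. A zero-information PWM
(maximum score ≤ 0) is flagged unscannable instead of silently matching
everywhere. Motif enrichment counts sequences with at least one hit and
tests the target count with a one-sided hypergeometric upper tail,
drawing the target-set size from the pooled target+background collection.
A hypergeometric test is simpler and exactly testable against enumeration,
which we prefer over a ZOOPS-binomial for a validation-oriented pipeline.
Gene-set over-representation is the same hypergeometric tail on gene
overlaps within an explicit universe, BH-corrected across sets.

## qPCR arithmetic

Percent input adjusts the input Ct for its dilution — a fraction f of
chromatin corresponds to log2(1/f) extra cycles — then converts
ΔCt = Ct_ChIP − Ct_input,adjusted to 100·2^(−ΔCt), reported on a 0–100
scale. Fold enrichment of a positive locus over a negative locus is
2^(ΔCt_negative − ΔCt_positive), oriented so that genuine enrichment gives
fold > 1 (sign conventions in the literature are inconsistent; ours is
fixed by that orientation). Relative expression is the standard 2^(−ΔΔCt)
against a housekeeping reference and a calibrator condition; it is
invariant to adding a constant to all four Ct values. One cycle = one
factor of 2 throughout; amplification-efficiency correction is out of
scope. The input dilution fraction is a required user parameter.

## The synthetic-data generator

The generator emulates the study design — two groups of three sequenced
libraries, NB counts with a single dispersion α (variance μ + αμ²),
lognormal per-sample size factors (sd 0.1 on the log scale) to exercise
the normalization code — and plants recoverable structure: differential
peak loci at |log2FC| = 2 with alternating sign, differential genes
likewise, enhancer–gene pairs whose gene FPKM is an affine function of the
peak's normalized subtracted signal plus Gaussian noise scaled so the
expected Pearson correlation equals the target (0.99 by default), and a
sharp 10-bp motif embedded in differential-peak sequences. Every output is
a pure function of the configuration: one global seed feeds a derived
sub-seed per stage, so enlarging the peak set does not perturb the RNA
draws and reruns are byte-identical.

Choices worth knowing about:

* **Isolated regulatory neighborhoods.** Differential loci are spaced at
  least 2.2 Mb apart, so each planted gene (within the 1 Mb window of its
  peak) can be near at most one differential peak. Real genomes violate
  this: co-regulated peaks share the group effect, their signals correlate
  strongly across six samples, and any gene driven by one of them
  correlates with all of them. Planted-link recovery here therefore
  measures the linking *machinery* — recall and precision of the selection
  rule against known truth — not linking performance on real chromatin.
* **Few DE genes in large designs** (`planted_de_fraction`). FPKM divides
  by the realized library size; if a large fraction of the transcriptome
  carries fold changes, library sizes shift systematically between groups
  and every untouched gene inherits a spurious group effect through the
  denominator. This is a genuine pathology of per-library normalization,
  not a generator bug; the generator keeps the DE fraction small (a few
  percent, as in real transcriptomes) so the null genes are actually null.
* **Planted genes are kept ≥ 1.1 Mb from differential loci** unless they
  are the planted link target, so expression group effects cannot
  masquerade as links.
* **Motif instances are resampled until they pass the scan threshold** (50
  attempts, then the consensus), so a planting rate of 1 guarantees at
  least one hit per differential sequence — the property the round-trip
  test asserts. The default motif is sharp (consensus probability 0.94),
  putting the background hit rate near 0.2% per kb.
* Per-sample peak calls jitter the consensus summit by at most ±200 bp,
  strictly below half the merge threshold, so merging recovers exactly the
  planted loci; per-locus counts from the generator stand in for BAM
  coverage extraction, while the read-interval counter is exercised
  separately on constructed reads.

The generator does **not** simulate reads (FASTQ/BAM), GC or mappability
bias, replicate-specific dispersion, correlated peaks, or any real
effect-size distribution; its defaults are chosen for testability. Problem
sizes used by the validation studies — 10,000 features for calibration and
expression recovery, a 1-Gb toy genome with 600 loci and 2,000 genes for
link recovery, 150 loci for the demo — are the package's own choice of a
scale at which the stochastic bounds are tight.

## Numerical details and degenerate inputs

Benjamini–Hochberg adjustment is `stats::p.adjust(method = "BH")` behind a
validated wrapper; the test suite compares it against a literal O(n²)
step-up implementation, and the hypergeometric tail against exhaustive
enumeration over all universes up to N = 25. Pearson r matches a
direct-summation oracle to 1e-12 relative error. Empty peak sets, empty
annotations, all-zero count rows, single-exon transcripts, chromosomes
without genes, and constant vectors all have defined, tested behavior
(empty results, p = 1, `NA` ordinals, "distal", and rejected links,
respectively). Ties are broken deterministically everywhere (leftmost
summit, lexicographic ids), so all outputs are reproducible sort-stable
tables.

## Known limitations

The Wald test's normal reference is approximate at n = 3 per group; its
realized level is bounded by the calibration study, not exact. The raw-p
rule for peaks is liberal (see above). FPKM-based linking inherits
composition sensitivity from per-library normalization. The proximal/
distal and feature classifications depend on the stated anchor
conventions, and percentages are not comparable across tools with
different anchors. None of the enrichment machinery models GC-matched
backgrounds or the gene-ontology DAG.
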