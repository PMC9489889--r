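---
title: "Calling factor-rich chromatin domains and testing their regulatory associations"
author: "richdom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling factor-rich chromatin domains and testing their regulatory associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richdom)
```

## The problem

Polycomb-group factors such as EZH2 silence genes through broad repressive
chromatin domains rather than through sharp, isolated binding events.
Identifying such *factor-rich domains* from ChIP-seq data is the same
problem that super-enhancer calling solves for activating marks, and this
package applies the same algorithm (the ROSE procedure) to any factor:
cluster the peak calls, score each cluster against the matched input, and
separate the heavy upper tail of the rank-ordered score curve. Around that
core, the package implements the downstream analyses that give such domains
their biological interpretation: where they sit relative to genes, whether
they prefer the repressive B compartment of the Hi-C A/B decomposition,
whether their target genes are transcriptionally repressed, and the
cohort-level statistics (ROC, over-representation, cohort splits, signature
scores, methylation-expression correlation) used to connect the factor to
disease expression data.

## The domain caller

The caller is a composition of three steps, each exposed on its own.

**Stitching.** Peaks on the same chromosome are merged transitively
whenever the gap between them (next start minus previous end) is at most
the stitch window. The default window is 4 kb, the value used for
EZH2/Polycomb domain definition; super-enhancer work on H3K27ac
conventionally uses 12.5 kb, and the window is a plain argument. Stitching
is implemented on `GenomicRanges::reduce()` and is idempotent; enlarging
the window can only reduce the number of regions.

**Scoring.** Each stitched region receives a background-subtracted signal:
the mean per-bp ChIP density minus the mean input density over the full
stitched span, multiplied by the span length. Scoring over the whole span
(rather than over the constituent peaks only) is the default because ROSE
maps density over the complete stitched region; `scoreMode =
"constituents"` restricts the sum to the member peaks for users who prefer
to ignore the stitched gaps. Negative scores are clamped to zero by
default: the cutoff geometry below assumes a non-negative ascending curve,
and a region whose ChIP signal is below input carries no evidence of
enrichment.

**Tangent-line cutoff.** Scores are sorted ascending into a curve
$y_1 \le \dots \le y_N$ and scanned with a line of slope
$m = (\max y - \min y)/N$ — the slope of the diagonal of the rank-ordered
plot. For each candidate index $i$ the number of points *strictly below*
the line through $(i, y_i)$ is counted; the index minimising that count is
the elbow, and regions scoring strictly above $y_i$ are called rich. Two
tie-break decisions are fixed and tested: ties on the minimum go to the
smallest index (the more conservative cutoff, fewer rich calls), and
points exactly on the line do not count as below it, so a flat curve
yields zero rich regions rather than arbitrary calls. The implementation
is vectorised but the test suite holds it to exact agreement with a
literal $O(N^2)$ two-loop search.

Degenerate inputs are defined rather than rejected: zero peaks return an
empty result; a single stitched region cannot support a rank-ordered
cutoff and is returned flagged not-rich with a warning.

## Coordinates, tracks and units

All in-memory intervals are `GRanges` (1-based, closed), the Bioconductor
convention; the 0-based half-open coordinates of BED, narrowPeak, bedGraph
and the gene table are converted at the reader/writer boundary and nowhere
else. Chromosome names are taken verbatim — a `chr1` vs `1` mismatch
between files raises an error naming both sides, because silent renaming
hides real data errors.

Signal lives in `SignalTrack` objects: fixed-width bins per chromosome
with a free-text units label. bedGraph records of any granularity are
resampled onto the fixed grid by coverage-weighted mean with uncovered
base pairs contributing zero, so resampling conserves mass and is
invariant to record order. The default 50 bp bin keeps a human genome
track in desk-scale memory at sub-peak resolution; the synthetic data in
this package use 200 bp for ChIP/input and 25 kb for the eigenvector. No
unit conversion is ever attempted between fold-change and raw coverage
tracks — the units label travels with the track and the caller only
requires that ChIP and input share a scale.

## Annotation

Promoters are defined as the TSS ± 2 kb by default, matching the promoter
definition used for the methylation analyses this package accompanies
(ChIPseeker's default is ± 3 kb; the window is an argument). Each interval
receives the highest-priority category among promoter > exon > intron >
distal, and the nearest gene by absolute TSS distance with lexicographic
gene-id tie-breaks; the signed distance is negative upstream of the TSS in
the direction of transcription. Finer categories (UTRs, downstream) are
deliberately collapsed: the analyses downstream only distinguish
promoter-resident from distal domains.

## Compartment enrichment

The Hi-C eigenvector's sign is arbitrary per chromosome, so it is first
oriented against a gene-density track (A, positive, is the gene-rich
compartment); a zero-variance eigenvector is left unflipped with a
warning. Bins with value exactly zero stay unassigned rather than being
forced into a class.

Enrichment of a domain set in B is measured as the bp-weighted fraction of
domain territory in B bins — bp-weighted because domains vary more than
ten-fold in length. The null model places each domain uniformly at random
on its own chromosome, length preserved, with no overlap constraint: this
is simple, seedable and adequate at the scale the package targets, while a
circular-shift null for strong spatial autocorrelation is noted as future
work. Significance is the one-sided add-one empirical p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$, which is
never zero and is uniform under the null — the test suite checks that
uniformity with a Kolmogorov-Smirnov test over 200 replicate seeds.

## The statistical layer

The conventions, all tested against closed forms or enumeration:

* **Rank-sum test** (`rankSumTest`): Mann-Whitney U with midrank ties;
  exact p when $n_1 n_2 \le 10{,}000$ and the data are tie-free, otherwise
  the tie-corrected normal approximation with continuity correction. The
  repression comparison (domain-target genes vs all others, per-gene mean
  of log2-scale expression) defaults to the one-sided "less" alternative,
  matching the directional claim it exists to test.
* **Correlation** (`correlationTest`): Pearson and Spearman with p-values
  plus the least-squares line, the triple reported for
  methylation-vs-expression scatter plots.
* **ROC** (`rocAnalysis`): AUC by Mann-Whitney pair counting (ties count
  one half); the operating cutoff maximises the Youden index
  $J = \text{sens} + \text{spec} - 1$ (the default criterion of the
  easyROC tool), ties broken toward higher specificity, and samples
  predicted positive at score ≥ cutoff. AUC and the operating point are
  invariant under strictly monotone transforms of the scores.
* **Over-representation** (`overRepresentation`): one-sided upper-tail
  hypergeometric p per gene set after intersecting sets with the universe,
  Benjamini-Hochberg adjustment across sets.
* **Cohort split** (`splitByDriver`): top-$n$ and bottom-$n$ samples by a
  driver gene's expression (default 20 per group); ties break by sample id
  so the split is deterministic. The differential-expression step usually
  run between such cohorts (negative-binomial modelling, FC 1.5 /
  adjusted-p 0.05 thresholds) is out of scope here — only the split is
  modelled.
* **Signature score** (`signatureScore`): unweighted per-sample mean of
  gene-wise z-scores (sample sd, $n-1$). This is a deliberately generic
  stand-in for proprietary weighted signatures; zero-variance genes are an
  error because their z-score is undefined.

## CpG island scanning

The scanner uses the classical criteria: windows of 200 bp, shifted 1 bp,
must have GC% strictly above 50 and observed/expected CpG strictly above
0.6, where Obs is the CG dinucleotide count and Exp is
$(\#C \cdot \#G)/\text{length}$. "Window > 200" is read as a 200 bp window
with a 200 bp minimum merged-island length, the MethPrimer reading of
those settings; both thresholds are strict as printed. Overlapping passing
windows are merged by union — boundaries are the union of passing windows,
not trimmed to passing cores, matching MethPrimer's visual convention;
this is a declared choice, not a claim of bit-compatibility with
MethPrimer's undocumented merge rule. N bases are excluded from both GC
numerator and denominator, and windows more than 10% N fail outright
rather than being silently skipped.

## The synthetic genome and what passing means

Every planted-truth check runs on data from `simulateDataset()`, whose
defaults are the package's fixed study conditions: three 5 Mb chromosomes,
400 genes, 200 background peaks, and 5 planted domains of 20-60 kb tiled
by constituent peaks of 0.5-1.5 kb separated by sub-4 kb gaps — so
recovering a domain genuinely requires the stitch step to merge at least
three peaks. ChIP signal is clipped Gaussian background (mean 1, sd 0.25)
multiplied by 10 over planted domains and by 2 over background peaks;
input carries background only. With those settings the caller recovers the
planted domains at precision and recall ≥ 0.9 under Jaccard ≥ 0.5
matching.

Compartments are alternating A/B runs of geometrically distributed length
(mean two 25 kb bins, i.e. ~50 kb runs) balanced so each chromosome is
close to 50% B. The granularity is a design choice with a statistical
purpose: runs must be long enough that a domain assigned to B (probability
0.9) can be embedded entirely within one B run, and short enough that
random placements average over several runs — that is what gives the
permutation test its contrast between an observed B fraction near 0.9 and
a null near 0.5. Domains drawn "not B" are constrained only at their
midpoint bin. The written eigenvector gets an independent random sign flip
per chromosome so the orientation step is genuinely exercised. Note that
with five domains the enrichment p-value is intrinsically coarse; draws in
which the Bernoulli(0.9) assignment sends two or more domains to A are
genuinely weakly enriched, and no attempt is made to make those pass.

Expression is log2-scale Gaussian (per-gene baselines N(6, 1), per-sample
noise sd 1) over 40 tumor and 20 normal samples; the 40 domain-target
genes (8 per domain, TSSs planted inside domains) are shifted by −2 log2
units in tumor samples. The driver gene's promoter methylation and
expression are coupled across tumor samples through a Gaussian copula with
normal correlation $r = 2\sin(\pi\rho/6)$, which makes the population
Spearman correlation exactly the target $\rho = -0.25$; monotone margin
transforms (beta values in 0.2-0.8, a log2 expression scale) leave Spearman
untouched. ROC cohorts are binormal with
$\Delta = \sigma\sqrt{2}\,\Phi^{-1}(\text{AUC})$ so the theoretical AUC
equals the request exactly.

What passing does **not** show: the generator has no read-level noise, no
fragment-size effects, no mappability or copy-number artifacts, no
correlated background between ChIP and input, and its expression model is
Gaussian rather than count-based. Recovery on these data demonstrates that
the algorithms are implemented correctly against their own contracts and
planted parameters — not that the pipeline is robust to every artifact of
real ENCODE or TCGA data.

## Problem sizes and determinism

The shipped test suite uses 100-vector oracle sweeps (N ≤ 500) for the
cutoff and stitching equivalences, the default synthetic dataset for
end-to-end recovery, 999 permutations for the pinned enrichment run, 200
replicate seeds for the calibration (uniformity) checks at 199
permutations each, and 100 seeds at n = 300 for copula recovery — sizes
chosen so the whole suite completes in a couple of minutes on one core.
All randomness flows from explicit seeds; generator outputs are
byte-identical for identical configurations, and enrichment results are
bit-identical for a fixed seed.

## Known limitations

* Only bedGraph is consumed for signal; bigWig input requires an external
  conversion (e.g. `bigWigToBedGraph`).
* The caller assumes ChIP and input tracks on a shared scale; no
  between-sample normalisation beyond the subtraction is applied.
* The uniform-placement null ignores spatial autocorrelation of domains.
* TSS-proximal peaks are not excluded before stitching (ROSE offers this);
  promoter-resident domains are a finding of interest here, so exclusion
  would be counterproductive.
* The exact domain counts of any particular study are not reproduction
  targets: they depend on upstream alignment, peak calling and replicate
  pooling outside this package's scope.
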