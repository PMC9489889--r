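# richdom

Factor-rich chromatin domain calling (ROSE-style) and the downstream
analyses that interpret such domains, with a planted-truth synthetic-data
generator so the whole pipeline is testable end to end.

## The problem

Repressive chromatin factors — EZH2 and the Polycomb machinery being the
motivating case — act through broad domains rather than isolated binding
sites. The standard way to find the "rich" tail of such binding is the
super-enhancer algorithm (ROSE) applied to the factor of interest:

1. **Stitch**: merge peaks whose gap is at most a window *w* (default
   4 kb) into clustered regions.
2. **Score**: for each stitched region, the background-subtracted signal
   `(mean ChIP density − mean input density) × span length`.
3. **Cutoff**: sort the scores ascending into a curve `y₁ ≤ … ≤ y_N`;
   slide a line of slope `m = (max y − min y)/N` along the curve and pick
   the point leaving the fewest points strictly below it. Regions scoring
   above that elbow are the rich domains.

Around this core the package provides the analyses such domains feed:
promoter/exon/intron/distal annotation against gene models (promoter =
TSS ± 2 kb), A/B-compartment assignment from a gene-density-oriented Hi-C
eigenvector with a permutation test for B-compartment enrichment
(one-sided add-one empirical p), a one-sided rank-sum test for repression
of domain-target genes, Pearson/Spearman methylation–expression
correlation, ROC diagnostics with Youden-optimal cutoffs, hypergeometric
over-representation with BH adjustment, expression-based cohort splitting,
mean z-score signature scoring, and sliding-window CpG-island prediction
(window 200, shift 1, GC% > 50, Obs/Exp > 0.6, strict).

All of it runs on a seed-reproducible synthetic genome
(`simulateDataset()`) that plants domains, compartments, repressed target
genes and a methylation-coupled driver gene, and writes the truth alongside
the data — so every claim the package makes about itself is checked
against known ground truth.

## Worked example

```r
library(richdom)

## 1. a synthetic epigenome with planted ground truth
sim <- simulateDataset(simConfig(seed = 1), "demo")

## 2. call rich domains: stitch -> score vs input -> tangent-line cutoff
peaks <- readNarrowPeak("demo/peaks.narrowPeak")
chip  <- readBedGraph("demo/chip.bedGraph",  binSize = 200)
input <- readBedGraph("demo/input.bedGraph", binSize = 200)
rd <- callRichDomains(peaks, chip, input, stitchWindow = 4000)
rd
#> RichDomainSet: 194 stitched region(s), 5 rich
#>   tangent-line cutoff: 2294 (index 189, 0 points below)
#>   #1 chr2:3425497-3481299 score 4.916e+05 (22 peaks) [rich]
#>   #2 chr2:1868416-1913606 score 4.113e+05 (16 peaks) [rich]
#>   #3 chr1:3962158-3991496 score 2.573e+05 (11 peaks) [rich]
```

The 267 input peaks stitch into 194 regions; the rank-ordered score curve
elbows at 2294, and exactly the five planted domains sit above it:

```r
truth <- GenomicRanges::GRanges(sim$truth$planted_domains$chrom,
  IRanges::IRanges(sim$truth$planted_domains$start + 1,
                   sim$truth$planted_domains$end))
unlist(domainRecovery(richDomains(rd), truth)[c("precision", "recall")])
#> precision    recall
#>         1         1
```

Compartment preference: orient the eigenvector by gene density, label
bins, and compare the domains' bp-weighted B fraction to random
length-preserving placements:

```r
genes <- readGeneTable("demo/genes.tsv")
eig   <- readBedGraph("demo/eigen.bedGraph", binSize = 25000)
comp  <- assignCompartments(orientEigenvector(
           eig, geneDensityTrack(genes, 25000)))
enr <- domainCompartmentEnrichment(richDomains(rd), comp,
                                   nPermutations = 999, seed = 1)
unlist(enr[c("observed_fraction", "fold_enrichment", "empirical_p")])
#> observed_fraction   fold_enrichment       empirical_p
#>         0.8191992         1.5700695         0.0280000
```

82% of domain territory lies in B bins versus ~52% for random placement
(fold 1.57, p = 0.028 with 999 permutations). And the planted repression
of domain-target genes is recovered by the one-sided rank-sum test:

```r
expr <- readExpressionMatrix("demo/expr.tsv")
repr <- compareDomainGeneExpression(expr, sim$truth$target_genes,
          samples = grep("^Tumor", colnames(expr), value = TRUE))
unlist(repr[c("p_value", "median_domain", "median_background")])
#>       p_value     median_domain median_background
#>  1.799606e-20      3.850261e+00      5.941088e+00
```

Domain-target genes sit ~2 log2 units below background — the planted
effect size.

A thin command-line wrapper over the same functions ships in
`inst/scripts/richdom` (subcommands `simulate`, `call-domains`,
`annotate`, `compartments`, `cpg-scan`).

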