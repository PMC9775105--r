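---
title: "Methods: allele-informed MZT analysis and X/Y sperm omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-informed MZT analysis and X/Y sperm omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mztrace)
```

This vignette records the models, parameter choices and numerical
conventions behind `mztrace`, in the spirit of a methods section: what
each component assumes, which knobs matter, and what the synthetic tests
do and do not demonstrate about real data.

## 1. The classification model

The pipeline rests on a simple genetic observation. If a gene harbors a
SNP at which the mother is homozygous for one allele and the father
homozygous for a different one, every read from an embryo of that cross
can be assigned a parental origin. Before zygotic genome activation the
embryo transcribes nothing of its own, so expressed genes show only
maternal alleles; once the zygotic genome switches on, biparental
(heterozygous) expression appears; genes showing only the paternal allele
indicate transcripts that cannot be maternal carry-over.

`call_marker_genotype()` turns allele counts into site calls with two
explicit thresholds:

* `min_allele_reads = 2` — reads required before an allele counts as
  observed. One read is compatible with a sequencing error; two
  independent reads are the weakest defensible evidence.
* `min_total_reads = 5` — total coverage required for a *single-allele*
  call. Claiming "only the maternal allele is present" from three reads
  is much weaker evidence than claiming "both alleles are present" from
  two reads of each, which is why the biparental call carries no total
  gate.

`classify_gene()` applies the priority **zygotic > maternal > paternal**:
a single biparental site is decisive because no maternal-only mechanism
produces paternal reads (up to the error rate), whereas maternal-only
sites at other markers of the same gene are expected even in zygotically
active genes (allele sampling at finite depth).

Replicates are merged by **evidence union** by default: allele counts are
pooled across replicates per site before calling. Pooling maximizes
sensitivity at low per-replicate depth; the cost is that a sporadic error
read in any replicate contributes to the pooled count. A
`replicate_rule = "majority"` mode (call each replicate, majority vote
per site, ties resolved toward the stronger evidence class) is provided
for users who prefer robustness to sensitivity; the default follows the
pooled-counting style of SNP-composition summaries.

The **transition point** is the consecutive stage pair with the largest
*absolute* increase in zygotic gene count (ties to the earlier pair),
matching the notion of a burst of newly active genes; a ratio criterion
would favor tiny early fluctuations when baseline counts are near zero.
When no strictly positive increase exists the detector reports none.

## 2. Differential expression

`de_test()` is a compact negative-binomial Wald test: median-of-ratios
size factors (computed over genes positive in every sample), group means
on normalized counts, and a Wald statistic on the log2 fold change. Two
departures from the textbook construction deserve explanation.

*Moderated dispersions.* Method-of-moments gene-wise dispersion estimates
from three replicates per group have ~4 degrees of freedom and are far too
noisy to plug into a Wald variance: the resulting test is badly
anticonservative under a normal reference and badly underpowered under a
heavy-tailed one. We therefore shrink each gene-wise estimate toward the
median dispersion across genes with a prior weight of `prior_df = 10`
pseudo-degrees of freedom — the same empirical-Bayes idea that edgeR and
limma rely on — and refer the Wald statistic to a t-distribution with
(residual + prior) degrees of freedom. The package's calibration tests
simulate the null (3 vs 3, negative binomial) and verify that the raw
p-value rejection rate at 5 % stays within Monte-Carlo error of 5 %,
while planted four-fold genes are recalled with high probability at the
padj < 0.05, fold-change > 2 thresholds.

*Zero-mean groups.* Genes absent in one group (the interesting case at
zygotic activation) get a floor of half a normalized count in that group,
which keeps the fold change finite and strongly significant rather than
undefined. Genes at zero in *all* samples report log2FC = 0, p = 1.

*Normalization caveat.* Median-of-ratios assumes most expressed genes are
stable between the conditions. Between embryonic stages this is true of
real transcriptomes (the constitutive majority) but has to be modeled
explicitly in simulation: the generator's `frac_constitutive` program
(flat expression; maternal alleles before activation, biparental after —
the classic maternal–zygotic class) exists for exactly this reason and is
enabled in the stage-comparison analyses. With no stable class, a
uniformly decaying maternal transcriptome is indistinguishable from a
sequencing-depth change, and fold changes against it are relative, not
absolute — a genuine property of count-based RNA-seq, not an artifact of
this implementation.

## 3. The PGC screen and exact Spearman p-values

Stage profiles are replicate-mean FPKM vectors over the declared stage
series. A gene is PGC-related when its profile tracks at least one of the
five marker genes (sox2, nanog, ddx4, dnd1, nanos3) with Spearman
r > 0.9 and p < 0.05. Design choices:

* **Per-marker maximum, not a composite.** The markers split into
  self-renewal and formation/migration archetypes with different shapes;
  correlation against their mean would favor neither. A
  `composite = TRUE` mode averages the marker profiles instead.
* **One-sided positive tail.** The screen looks for genes *tracking* the
  markers; anti-correlated genes are not PGC-like, and the r > 0.9
  threshold is itself one-sided.
* **Exact p-values.** With only five stages the t-approximation for the
  Spearman statistic is meaningless. For n ≤ 8 the permutation
  distribution is enumerated in full (n! ≤ 40 320 permutations, one
  matrix product), treating the observed tie pattern as fixed and using
  average ranks; perfect concordance at n = 5 yields p = 1/120 exactly.
  Beyond n = 8 the usual t-approximation takes over.

## 4. Methylome analysis

Sites are per-cytosine records (1-based positions, strand, context,
methylated/unmethylated counts); replicates are pooled by summing counts
per site. Analysis conventions:

* **Context summary.** A covered site is "methylated" when its methylated
  count exceeds what bisulfite non-conversion alone would produce
  (one-sided binomial test against `error_rate = 0.005` at α = 0.05).
  An absolute-fraction rule would misread high-coverage sites.
* **Conversion efficiency** is `1 − Σm/Σ(m+u)` over the unmethylated
  spike-in contig (`lambda` by default).
* **DMR calling** tiles chromosomes into 1 kb windows (methylKit-style
  defaults: `step = window`, `min_cpg = 10`), pools counts per group, and
  tests the two pooled proportions with a binomial likelihood-ratio test
  — algebraically identical to a logistic-regression LRT with a group
  term, since the group-wise MLE pools replicate counts. With a single
  replicate in either group the test switches to Fisher's exact test,
  whose two-sided p is computed by hypergeometric enumeration (summing
  point probabilities ≤ the observed one). Windows are
  Benjamini–Hochberg adjusted and must pass **both** q < 0.01 and
  |Δ| ≥ 25 percentage points. BH is used deliberately in place of the
  sliding-linear-model style correction some callers use: it is exactly
  specified, reproducible, and the planted-DMR experiments in the test
  suite verify both recovery and empirical false-discovery control under
  it.
* **Annotation** assigns one label per DMR by midpoint overlap with fixed
  precedence promoter > exon > intron > downstream > distal intergenic.
  The promoter is defined as 2 kb upstream of the TSS (strand-aware) and
  downstream as 2 kb past the gene end — conventional spans, configurable.
  Without an exon table, gene bodies collapse to a single `genic` label.
* **Meta-profiles** average site levels in 50 bp bins across ±2 kb of
  each DMR center (80 bins); empty bins are `NA` rather than zero.
* **Integration with expression** filters to genes with FPKM > 0 in any
  sample, row-standardizes, and runs k-means with `k = 3`, a fixed seed
  (42) and 20 restarts; a cluster's direction is the sign of its
  centroid's Y-minus-X mean. Hypermethylated genes in down-trending
  clusters and hypomethylated genes in up-trending clusters form the
  theory-concordant sets, which are then intersected with the DEG calls
  and reduced to promoter-annotated cases.

## 5. What the generator emulates — and what it does not

The synthetic module (`sim_config()`, `simulate_parents()`,
`simulate_embryo_series()`, `simulate_sperm_methylomes()`,
`simulate_sperm_expression()`) is first-class, tested code. Its defaults
encode the study design the pipeline targets:

* two chromosomes of 1 Mb, 200 genes of 2 kb, three informative SNPs per
  gene on average (planted exactly, distributed randomly over genes) plus
  decoys of every rejectable kind: shared-homozygous, heterozygous,
  missing, low-depth, low-quality and multi-allelic sites;
* five stages with activation at the low-blastocyst stage; maternal
  abundance multiplied by `maternal_decay_rate = 0.4` per stage; program
  mix maternal/zygotic/paternal/silent = 0.50/0.30/0.06/0.14, with the
  optional constitutive class (Section 2) off by default;
* three replicates per stage and cross; negative-binomial counts
  (dispersion 0.1) at `depth = 30` reads per expressed marker and
  replicate; allele error 0.2 % — post-filtering allele miscalls are
  rarer than raw sequencing error, and the test suite separately
  exercises the harsher 1 % error / 10× depth regime;
* sperm methylomes at a 0.95 CpG background, 30× coverage, CpGs every
  100 bp (ten per window), small CHG/CHH complements in which 0.5 % and
  1.4 % of sites are genuinely methylated, and a fully unmethylated
  spike-in contig with 0.4 % residual non-conversion;
* sperm expression with log-normal baselines (median 100) and planted
  fold changes, allowing the up/down asymmetry of real Y-vs-X contrasts.

Deliberately **not** modeled: read-level data (FASTQ, alignment,
duplicates), haplotype linkage between markers of one gene (classification
is per-site, so linkage adds nothing at this level), stage-dependent
library sizes, batch effects, allele-specific methylation, and any
sequencing-error structure beyond the flat allele-error rate. Passing the
synthetic suite therefore demonstrates the *logic* of the pipeline —
thresholds, priorities, calibration, recovery under its own noise model —
not robustness to artifacts the generator does not produce.

## 6. Numerical conventions and degenerate inputs

* Coordinates: gene intervals are stored 0-based half-open (BED
  convention); marker and cytosine positions are 1-based (VCF/report
  convention). A marker at position p belongs to a gene iff
  start < p ≤ end.
* Quantiles use type-7 interpolation; ECDFs drop non-positive values
  before the log10 transform.
* Ties in ranks use average ranks; the permutation null holds the
  observed tie pattern fixed.
* `detect_transition()` with no positive jump, a constant count series in
  the coupling statistic, zero-variance profiles in `spearman_exact()`,
  empty category sets and stages without covered sites all return
  flagged `NULL`/`NA` results with warnings rather than guessing.
* All simulators derive their RNG streams from `sim_config(seed)`
  (distinct fixed offsets per simulator), so a configuration is a
  complete, byte-reproducible description of a study.

## 7. Problem sizes used by the checks

The packaged test suite and `scripts/acceptance.R` run at sizes chosen to
exercise every property at comfortable statistical resolution on a single
CPU: 100 random 10⁴-site genotype tables for the marker-filter
equivalence; 2 000-gene series for clean and noisy label recovery; 100
seeded series for transition detection and coupling; 200 × 1 000 genes of
null simulation (and ten planted runs) for the differential-test
calibration; full permutation enumeration up to n = 6 for the Spearman
oracle; 40 planted 1 kb DMRs with three label permutations for the
methylome; and 10⁴ random p-vectors for the step-up adjustment oracle.

## 8. Known limitations

* The classifier inherits the absolute-count thresholds' behavior at high
  pooled depth: with deep coverage and a nonzero allele-error rate,
  single-parent genes accumulate spurious biparental site calls; a
  depth-scaled (binomial) evidence rule would control this but would
  depart from the explicit two-read evidence model implemented here.
* The DE test offers no outlier handling (Cook's-style) and no independent
  filtering; it is designed for the designed comparisons of this pipeline
  (3–5 replicates, moderate gene counts), not as a general DESeq2
  replacement.
* DMR windows are fixed tiles; a DMR straddling a tile boundary can split
  into two calls, and recovery is assessed window-wise.
* The PGC screen is a correlation screen; it identifies profile-similar
  genes, not PGC biology.
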