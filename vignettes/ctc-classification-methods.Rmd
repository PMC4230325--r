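---
title: "Classifying single circulating tumor cells: models and methods"
author: "CTCscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying single circulating tumor cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CTCscope)
```

# The scientific problem

Circulating tumor cells (CTCs) are rare tumor-derived cells in peripheral
blood. When candidate CTCs are captured without epitope selection and
profiled one cell at a time by RNA-seq, the resulting gene-by-cell count
matrix mixes viable tumor cells of several phenotypes (classical
epithelial, platelet-adhered, proliferative) with leukocytes,
fibroblast-like cells, cells with degraded RNA, and control material
(cultured cancer-line cells, diluted bulk tumor RNA, purified single
primary-tumor cells). CTCscope implements the full classification
workflow for such cohorts:

1. **Quality control** on housekeeping transcripts (Gapdh, Actb).
2. **Normalization** to reads per million (rpm), log10 transform with
   pseudocount 1, and Tukey median polish for display/clustering.
3. **Unsupervised hierarchical clustering** and PCA, with
   intracluster-correlation heterogeneity statistics (bootstrap CIs,
   permutation comparisons) and digital removal of transcript sets.
4. **Rank-product differential expression** between cell groups with
   permutation-based significance and false discovery rates.
5. **Marker-panel annotation** of clusters and the thresholded
   signature-selection screens (CTC-enriched genes; extracellular-matrix
   genes), coexpression counting, and a generic over-representation
   statistic for user-supplied gene sets.
6. A **synthetic-cohort generator** that emulates the cohort structure
   the pipeline assumes, so every stage is testable end-to-end with no
   external data.

# Statistical methods

## Rank-product differential expression

For cell groups $A$ and $B$ on the rpm scale, every between-group cell
pair $(a, b)$ yields per-gene stabilized fold changes
$(x_{ga} + c)/(x_{gb} + c)$ with pseudocount $c$ (default 1 rpm). Within
each pair the fold changes are ranked across genes (rank 1 = most
extreme; ties get average ranks), and a gene's score is the geometric
mean of its ranks over all pairs,
$\mathrm{RP}_g = \big(\prod_p r_{gp}\big)^{1/P}$. Because only ranks
enter, the statistic is insensitive to per-cell scale and to any
transformation that preserves the within-pair ordering — the property
that makes it suitable for single cells with very uneven transcriptome
representation. One-sided scores are computed separately for each
direction, as in the original rank-product formulation; a gene's
reported direction is the one with the smaller score.

Two single-cell adaptations are applied and exposed in the
configuration: a detection filter (a gene must be detected in at least
20% of the cells of one group, by default) and the rpm pseudocount. For
large groups the set of cell pairs is subsampled (seeded) to a cap of
10,000, which bounds cost without biasing the geometric-mean estimator.

Significance comes from permuting the group labels: the pooled null
scores over `n_perm` permutations give
$p_g = (1 + \#\{\mathrm{RP}^0 \le \mathrm{RP}_g\}) / (1 + n_\mathrm{perm} G)$,
the expected false-positive count
$E_g = \#\{\mathrm{RP}^0 \le \mathrm{RP}_g\}/n_\mathrm{perm}$, and the
q-value (pFDR) $q_g = E_g / \mathrm{rank}(\mathrm{RP}_g)$, enforced
monotone non-decreasing in the score and capped at 1. The attainable
p-value floor is $1/(1 + n_\mathrm{perm} G)$. Tests verify exact
agreement with an exhaustive enumeration oracle on small instances and
type-I calibration on null cohorts.

## Intracluster correlation heterogeneity

Heterogeneity of a cell group is summarized by $\bar r$, the mean
pairwise Pearson correlation over all unordered cell pairs, computed on
$\log_{10}(\mathrm{rpm} + 1)$ — deliberately *not* on the
median-polished values, so the statistic is independent of the display
transform. Lower $\bar r$ means more heterogeneity. The confidence
interval is a percentile bootstrap over cells (default 1000 replicates,
seeded): cells are resampled with replacement and $\bar r$ recomputed
over pairs of distinct resampled cells; pairs that duplicate one
original cell are excluded because their correlation is identically 1.
Cell-level rather than pair-level resampling avoids the dependence
between pairs that share a cell. Group comparisons use a two-sided
permutation test on the difference in $\bar r$, shuffling group labels;
with $n$ permutations the smallest attainable p-value is $1/(n+1)$.

## Clustering and display transform

The default distance is $1 - $ Pearson correlation over genes detected
($> 0$) in at least 2 cells, with average linkage — the standard
expression-heat-map choice, consistent with the correlation-based
heterogeneity metric. The number of clusters is a configuration
parameter (default $k = 7$, the number of labeled cohort groups); no
automatic $k$ selection is attempted. Clustering operates on
median-polished log rpm: removing gene (row) effects is what lets
cell-type structure rather than shared gene-abundance structure drive
the correlations. Median polish sweeps rows first, then columns (Tukey's
classical ordering, which matters if iteration stops before
convergence), and the decomposition
`overall + row + col + residual = input` is exact by construction. PCA
uses centered, unscaled profiles with a fixed sign convention (each
loading vector is flipped so its largest-magnitude entry is positive).

## Annotation rules and selection screens

Cluster annotation scores each marker panel as the mean over the
cluster's cells of the fraction of panel genes above 100 rpm, then
applies an ordered rule list (first match wins): platelet >
leukocyte > fibroblast > proliferative > classical-epithelial > tumor,
with unmatched clusters left unclassified. The precedence encodes that
platelet and proliferative signatures override epithelial content, and
that tumor-derived CTC classes carry the CTC-enriched transcript trio
that cultured cell-line cells and primary tumor material lack. The
proliferation call uses the cluster mean of Mki67 log10(rpm+1) against a
threshold of 2 (about 100 rpm) rather than a curated cell-cycle
signature, which would require an external catalog.

The selection screens follow the printed boundary rules exactly:
CTC-enriched genes must have RP score strictly below 300 *and* exceed
100 rpm (strict) in at least 90% (inclusive) of the target cells; the
human ECM screen requires more than 100 rpm in strictly more than 15% of
cells (the inclusive variant is available via a flag for the mouse
parameterization). The over-representation statistic builds the 2x2
table of a gene list against each set over a user universe, reports the
odds ratio with a Haldane 0.5 correction applied only when a cell is
zero (keeping reported ORs finite without altering the exact test), the
one-sided hypergeometric tail p, and Benjamini-Hochberg q-values across
sets.

# The synthetic cohort generator

## What it emulates

The generator reproduces the cohort structure the pipeline assumes, with
defaults matching the study design: 168 candidate single CTCs (41
classical, 24 platelet-adhered, 10 proliferative, 93 RNA-degraded — so
75/168 = 45% pass QC by construction), 12 leukocytes, 16 cancer
cell-line cells, 12 embryonic fibroblasts, 34 diluted bulk-tumor
replicates and 20 purified single primary-tumor cells, spread over five
mice (CTCs) and four tumors (bulk replicates).

The count model is deliberately simple and fully seeded:

* **Baselines.** 2,000 genes: named marker genes at fixed baseline
  abundances (the epithelial primary-tumor reference profile), seven
  expression modules (platelet transcripts, platelet-residual response,
  proliferation, stromal, CTC program, hematopoietic, mesenchymal), and
  log-normal filler genes (log10 mean 2.35, sd 0.55).
* **Class effects.** Deterministic log10 offsets per class: epithelial
  loss in leukocytes/fibroblasts, platelet and proliferation modules in
  the respective CTC subsets, partial ECM and EMT shifts plus the
  planted CTC-enriched trio (Klf4, Igfbp5, Dcn at ~4,000 nominal rpm) in
  all tumor-derived CTC classes, stromal/leukocytic admixture in bulk
  tumor. Pairs of control lineages carry opposite-signed module effects
  (e.g. leukocytes low on mesenchymal and proliferation modules), which
  keeps every pair of cell types separable under correlation distance
  even when a noisy class fragments.
* **Class-distinctness offsets.** Each class additionally draws a
  bounded uniform offset (±0.65 log10; the shared tumor lineage ±0.9)
  restricted to genes below ~200 nominal rpm and to non-marker genes.
  This models genome-wide cell-type differences beyond the named
  markers. The bound and the abundance restriction together guarantee
  that no background gene can cross the selection cascade's combined
  rank-product and 90%-ubiquity thresholds by offset alone, so the
  planted trio is recovered exactly.
* **Per-cell noise and heterogeneity calibration.** Each cell draws
  independent per-gene log-normal noise. The class noise scale is
  *calibrated numerically* to hit the configured mean intracluster
  correlation (cell line 0.86, CTC classes 0.42, purified tumor singles
  0.38, bulk replicates 0.90, leukocytes/fibroblasts 0.80): the expected
  mean and variance of log10(rpm+1) per gene are computed by
  Gauss-Hermite quadrature over the noise, with exact Poisson moments
  for weakly expressed genes, a delta-method approximation otherwise, a
  lognormal mass-inflation correction for the per-cell library
  renormalization, and the dropout contribution included; the predicted
  pairwise correlation (shared-profile variance over total variance) is
  then inverted for the noise scale on a monotone grid. Tests verify the
  realized correlations land within ±0.05 of their targets.
  Housekeeping genes and the planted trio receive damped noise
  (susceptibility 0.2 and 0.3): housekeeping transcripts are
  biologically stable, and the planted genes are by construction
  uniformly high in their carriers — this is what makes the QC margins
  and the 90%-ubiquity guarantee hold under the heavy-tailed cell noise
  that the 0.42 correlation target requires.
* **Sampling.** Counts are Poisson draws at a lognormal depth (mean
  2x10^5 reads; a scaled-down library that keeps the Poisson
  contribution negligible for expressed genes while the whole suite
  runs in minutes), followed by Bernoulli dropout (rate 0.3) on genes
  whose class-level abundance is below 10 rpm.
* **Degradation.** Degraded cells are classical CTCs whose housekeeping
  abundance is multiplied by 10^-3 and whose noise is fixed at sd 1.0;
  expected housekeeping rpm then sits at least 10-fold *below* the
  100-rpm QC threshold while every viable class sits at least 10-fold
  *above* it, so QC decisions are robust to the exact cutoff. The study
  reports the 45% pass rate as a data property without a quantitative
  degradation model; here it is reproduced purely by construction
  through the class counts.
* **Reproducibility.** All randomness flows from one root seed through
  named substreams (gene baselines, per-class offsets, per-class cells),
  so identical configurations are bit-identical and simulating one class
  never perturbs another.

Platelet-adhered CTCs are classical CTCs plus an additive platelet
transcript component *and* a residual platelet-induced expression module
on non-platelet genes, so digital removal of annotated platelet
transcripts has a defined ground truth: the class remains separable
afterwards, mirroring the corresponding observation on real data.

## What it does not emulate

No read-level sequencing artifacts, no UMIs, no batch effects beyond the
animal-of-origin label, no doublets, no gene-gene correlation beyond
class structure, and no quantitative model of RNA degradation kinetics.
Passing tests therefore demonstrate that the pipeline's statistics and
thresholds behave as specified under a controlled generative model —
not that the biological conclusions of any particular study follow from
real data.

# Numerical and design choices

* **QC threshold**: both housekeeping genes at >= 100 rpm. The study
  names the genes but not the cutoff; 100 rpm matches its "high
  expression" convention, and the generator's margins make QC decisions
  threshold-robust by an order of magnitude either way.
* **log10 with pseudocount 1**: expression figures in this field are
  conventionally drawn in log10(rpm); 0 rpm maps to 0.
* **Median polish order**: rows first, then columns; documented because
  the decomposition depends on sweep order at non-convergence.
* **k = 7** clusters by default, matching the seven labeled cohort
  groups; changing the cohort should change `cluster$k` accordingly.
* **Heterogeneity on log rpm, not polished values**, so the statistic
  does not depend on the display transform.
* **Bootstrap CI**: percentile over cells, 1000 replicates; this is a
  package choice among several defensible CI constructions, so tests
  of heterogeneity comparisons assert direction and order of magnitude
  rather than exact p-values.
* **Degenerate inputs**: constant cells are excluded from correlation
  statistics with a warning (an error if nothing remains); clustering a
  constant cell under correlation distance is an error naming the cell;
  all-zero cells survive rpm normalization as all-zero and are flagged;
  removal of a transcript set re-normalizes rpm matrices and records
  that it did.
* **Problem sizes in the test suite**: most tests use a 600-gene reduced
  cohort; the full 2,000-gene default cohort is simulated once and
  shared across test files; FDR calibration uses 20 null cohorts of 500
  genes at 8-vs-8 cells with 200 permutations. These sizes were chosen
  so the entire suite completes in a few minutes on one CPU while every
  statistical check retains adequate resolution.

# Known limitations

* The rank-product permutation null pools all genes, which is standard
  but slightly conservative for genes with extreme detection patterns.
* The generator's correlation calibration is approximate (quadrature
  plus a mean-field library-size correction); realized values track
  targets to about ±0.01 at the defaults, comfortably within the ±0.05
  acceptance band, but extreme configurations (very low depth, very
  high dropout) would degrade the approximation.
* Class annotation is rule-based on panel scores; it is stable under
  cell duplication and cluster splits, but a cluster merging two
  distinct control lineages will receive a single (then partly wrong)
  label. The generator's default contrasts make such merges rare; on
  real data the rules and thresholds are configuration, not truth.
* Gene identifiers are case-sensitive symbols with no cross-species
  mapping; mouse and human panels are distinct objects.
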