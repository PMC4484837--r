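---
title: "Choosing a between-sample normalization for RNA-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing a between-sample normalization for RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normbench)
```

## The problem

RNA-seq libraries are sequenced to different depths, so raw counts are not
comparable across samples. Each between-sample normalization method assigns
sample $j$ a scaling factor $d_j$ estimating its relative depth, but the
estimators make different assumptions and disagree on real data — and the
disagreement propagates into the list of differentially expressed genes
(DEGs). `normbench` treats the choice of normalization as an empirical
question about the data set at hand: compute all candidate factors, score
each candidate on a panel of criteria with known directions, and aggregate
the criterion ranks.

## The six candidates

Let $K_{gj}$ be the count of gene $g$ in sample $j$, $N_j = \sum_g K_{gj}$
the library size, $G$ the number of genes and $m$ the number of samples.

* **TMM** — against a reference sample $r$,
  $\log_2 d_j = \sum_{g \in G'} w_{gj} M_{gj} \big/ \sum_{g \in G'} w_{gj}$
  with $M_{gj} = \log_2 \frac{K_{gj}/N_j}{K_{gr}/N_r}$ and
  $w_{gj} = \frac{N_j - K_{gj}}{N_j K_{gj}} + \frac{N_r - K_{gr}}{N_r K_{gr}}$,
  where $G'$ excludes genes with a zero count in either sample and the
  trimmed tails of the $M$ and $A$ (average abundance) distributions.
* **UQ** — $d_j = UQ(K_{\cdot j}) / N_j$, the 75th percentile of the sample's
  counts after removing genes that are zero in every library.
* **DES** (median-of-ratios) — $d_j = \mathrm{median}_g\, K_{gj} /
  (\prod_v K_{gv})^{1/m}$, the median ratio to a geometric-mean
  pseudoreference; genes with any zero are unusable.
* **EBS** (quantile) — $d_j = 10^{\log_{10} Q_j - \frac{1}{m} \sum_v
  \log_{10} Q_v}$ with $Q_j$ the upper quartile of sample $j$'s counts.
* **PS** — total-count shares $d_j^{TC} = N_j / \sum_v N_v$ define expected
  counts $d_j^{TC} K_{g\cdot}$; the Pearson goodness-of-fit statistic
  $GOF_g$ flags genes deviating from pure depth scaling; genes in the
  central GOF window form $G''$, and $d_j^{PS} = \sum_{g \in G''} K_{gj} /
  \sum_{g \in G''} K_{g\cdot}$.
* **RD** — raw, unnormalized data, kept as the benchmark every method must
  beat.

### Divisor convention

The native factors live on different scales (TMM/UQ correct the library
size; DES/EBS/PS are already count-scale; the raw PS shares sum to 1). To
make the methods comparable in one plot and in the control-gene criteria,
every method also exposes a count-scale divisor — $N_j d_j$ for TMM and UQ,
$d_j$ for DES and EBS, $m\,d_j$ for PS — rescaled to geometric mean 1.
Normalized counts are always $K'_{gj} = K_{gj}/s_j$.

### Numerical choices

* **Upper quartile dialect.** All quantiles use linear interpolation on the
  sorted values (R's default type 7). Quartile dialects differ between
  software packages; fixing one makes the factors reproducible to machine
  precision against the package's brute-force test oracles.
* **TMM trimming.** "Trim 30% of M and 5% of A" is read as two-sided: the
  `floor(n * trim)` smallest and largest values by tie-averaged rank are
  removed from each tail. Both fractions are arguments.
* **TMM reference.** Chosen automatically as the sample whose upper quartile
  of library-size-scaled counts is closest to the mean of those quantities
  (overridable by sample ID).
* **TMM weights.** The weighted mean uses $w_{gj}$ — the delta-method
  variance expression — directly as the weight. Precision weighting by
  $1/w_{gj}$, the convention of the widely used implementation of TMM, is
  available via `inverse_variance = TRUE`; with no differential expression
  both give the same answer, and the package's tests cross-check the
  inverse-variance mode against that external implementation.
* **PS selection window.** A GOF statistic is nonnegative and
  chi-square-like, so a literal value window of $(0.25, 0.75)$ would usually
  be almost empty; the window is therefore interpreted as quantiles of the
  empirical GOF distribution (keep the central half). The literal reading
  remains available (`window_type = "value"`).
* **Zeros.** TMM drops genes with a zero in either member of the pair; DES
  drops genes with any zero; UQ drops genes zero in all libraries; EBS, PS
  and RD use all genes.

## Housekeeping genes and the bias/variance criteria

Curated housekeeping lists are not available for every organism and
condition, so the control set is defined analytically: the 1% of genes with
the lowest across-sample mean-square deviation of raw counts,
$MSE_g = \frac{1}{m} \sum_j (K_{gj} - \bar K_{g\cdot})^2$, min-max
normalized. Selection uses raw counts so that the control set is the same
for every method under comparison. Taking the square root (an RMSE) is a
strictly increasing transform and cannot change the selected set; both
values are reported. The set size is `floor(fraction * G)` with ties at the
boundary broken by input gene order; at the default 1% this gives 124, 131
and 127 genes for matrices of 12,410, 13,131 and 12,749 genes.

A truly constant gene has true log ratio 0 to its own mean, so after
normalization:

$$bias_i = \sqrt{\tfrac{1}{m} \sum_j \big(\log_2 K'_{ij}/\bar K'_{i\cdot}\big)^2},
\qquad
variance_i = \tfrac{1}{m-1} \sum_j \big(\log_2 K'_{ij}/\bar K'_{i\cdot} -
\overline{\log_2 K'_{ij}/\bar K'_{i\cdot}}\big)^2,$$

averaged over the control genes (unweighted). Both are evaluated on
*normalized* counts — on raw counts all methods would coincide — and RD is
evaluated on raw counts by construction. Control genes with a zero count in
any sample have undefined log ratios and are dropped per method with a
warning rather than patched with a pseudocount, because a pseudocount would
shrink ratios most exactly where the criterion is least reliable.

## The exact test

Differential expression uses the model $K_{gj} \sim NB(d_j \lambda_{gj},
\phi)$ with a single common dispersion. The test conditions on the per-gene
total of divisor-normalized group sums: the sum of $n$ i.i.d.
$NB(\mu, \phi)$ variables is $NB(n\mu, \phi/n)$, and given the total the
split follows a distribution free of $\mu$, so the two-sided p-value is the
sum of the probabilities of all splits at most as probable as the observed
one. At $\phi = 0$ this is a binomial test. Design choices:

* dispersion is estimated by matching within-group variance to
  $\mu + \phi\mu^2$, averaged over genes and groups, floored at 0; genes
  with a normalized within-group mean below 1 are skipped (the moment ratio
  explodes near zero);
* normalized group sums are rounded; totals above `total_cap` (default
  10,000) are proportionally rescaled before enumeration, which bounds the
  per-gene cost with negligible effect on the p-value at that resolution;
* log2 fold changes use a 0.5 pseudocount on the normalized group means to
  avoid infinities (configurable);
* multiplicity is controlled with Benjamini–Hochberg by default, and genes
  with adjusted $p < 0.05$ are called DEGs.

No tagwise dispersion shrinkage, trended dispersion or GLM machinery is
provided: the benchmark needs a test that consumes each method's scaling
factors on an equal footing, not a maximal DE toolkit.

## Classification, overlap, and rank aggregation

* **LOOCV.** The informative genes are the top `floor(0.75 * n)` by adjusted
  p-value (30/12/20 genes for 41/16/27 samples). Features are
  $\log_2(K'_{gj} + 1)$. Five classifiers — Gaussian naive Bayes, a
  single-hidden-layer perceptron (8 units, weight decay 0.01, standardized
  inputs), k-NN with $k = 5$, a radial-kernel SVM at library defaults, and
  a 500-tree random forest — are each refit $n$ times, holding out one
  sample per run; a fold that loses a whole class counts as an error. The
  per-method summary is the mean and median of the five classifier error
  percentages with a 95% t-interval (4 degrees of freedom) over the
  classifiers. Stochastic classifiers are seeded per fold from the supplied
  seed, making the whole benchmark reproducible.
* **Common DEGs.** $P_{ij} = 100\, D_{ij}/D_i$ is the percentage of method
  $i$'s DEGs also found by method $j$; pairs are symmetrized by averaging
  $P_{ij}$ and $P_{ji}$ and each method scores the mean over its partners.
  Methods whose calls are corroborated by the rest score high; a method
  producing idiosyncratic DEG lists is penalized.
* **Rank dendrogram.** Restricted to the genes every method calls DE, each
  method ranks them by adjusted p-value; methods are clustered on the
  Euclidean distances between rank vectors with Ward's method (the
  squared-distance-updating variant, `hclust(method = "ward.D2")`).
* **Final rank.** Each criterion converts to tie-averaged ranks (bias,
  variance, prediction error: lower is better; sensitivity, specificity,
  common DEGs: higher is better); the final rank is the unweighted mean and
  the minimizer is recommended. Criteria missing a method (e.g. no control
  panels supplied) are dropped, not imputed.

## The synthetic-data generator

`generate_counts()` draws $K_{gj} \sim NB(s_j \lambda_{gj}, \phi)$ with
log-normal baseline means, known size factors, designated DE genes
($\lambda$ shifted by $2^{\pm \mathrm{log2fc}}$ in group 2) and designated
housekeeping genes (identical $\lambda$ in all samples, dispersion
$\phi/10$). Defaults were chosen once to represent a typical two-condition
bulk RNA-seq study:

* size factors log-normal with $\sigma = 0.4$ (about a 2–3 fold
  library-size spread), reflecting that library size is the dominant
  between-sample variation the methods are meant to remove;
* common dispersion 0.1, a typical bulk value; DE genes at
  $|\mathrm{log2FC}| = 2$, split 50/50 up/down (the `aml_like` preset skews
  70/30 up, mimicking a leukaemia contrast where overexpression dominates);
* housekeeping genes at low constant abundance (three log-SDs below the
  median baseline). Raw-count stability selection necessarily favours
  low-abundance genes — absolute mean-square deviation grows with the mean —
  and analytic housekeeping sets in real data sit at low-to-medium counts,
  so the generator places its constant genes where such genes are actually
  found; with this choice about 0.1% of background genes sit below them and
  the 1% selection recovers the designated set almost completely.

Three presets (`cheung_like`, `bodymap_like`, `aml_like`) match the
gene/sample shapes of the public benchmark data sets (12,410 genes × 41
samples; 13,131 × 16; 12,749 × 27) with abundance skewed low, high and
middle respectively. The preset shape parameters are qualitative emulations,
not fits to the real data.

What the simulator does *not* emulate: gene-length and GC effects (the
benchmark is about between-sample depth only), correlated genes, batch
structure, outlier samples, and per-gene dispersion trends. Passing tests on
synthetic data therefore show that each component does what its formula says
under the stated generative model, and that the benchmark discriminates a
method that recovers the truth from no normalization at all — not that any
particular method is best on a given real data set. That question is exactly
what the workflow is meant to answer per data set.

## Problem sizes used in the tests

The packaged tests validate formulas on 50×4 random matrices against
brute-force oracles; parameter recovery and the bias/variance ordering on a
5,000-gene, 10-sample simulation; test calibration and power on 2,000-gene
simulations with 5 samples per group; and the end-to-end workflow (twice,
for byte-identical reports) on the full `aml_like` preset, 12,749 genes × 27
samples. These sizes keep the whole suite comfortably within a coffee break
on one CPU while exercising every code path at realistic scale.

## Known limitations

* The exact test uses one common dispersion; strongly gene-specific
  dispersion inflates its false-positive rate slightly (the calibration test
  checks the common-dispersion regime).
* With near-identical criterion values, ranks exaggerate tiny differences —
  the final ranking should be read together with the criterion values
  themselves (`summary()` reports both).
* The PS estimator implements the printed single pass, not the iterative
  published variant.
* Sensitivity/specificity require user-supplied control panels; none are
  bundled.

## A complete run

```{r example, eval = FALSE}
sim <- generate_counts(preset("aml_like", seed = 5))
fit <- run_workflow(sim$cm, output_dir = "aml_like_report", seed = 5)
summary(fit)
```

The output directory contains the scaling factors, per-method DE tables,
bias/variance table, the criterion/rank summary as TSV, a JSON report, and
the diagnostic figures (divisors per sample, DEG abundance composition,
LOOCV error bars, common-DEG balloon plot, method dendrogram, MA panels).
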