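---
title: "Multimodal radiomic subtyping of gliomas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal radiomic subtyping of gliomas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliotype)
```

## The problem

Gliomas of the same WHO grade differ widely in prognosis. The premise of
this package is that quantitative radiomic features extracted from two
conventional MRI sequences — contrast-enhanced T1 (T1CE) and T2-FLAIR —
carry enough phenotypic information to split a cohort into clinically
distinct subtypes without any labels, and that *fusing* the two
sequences recovers structure that neither carries alone. Around that
core, the package provides the feature-reduction steps, the statistics
used to characterize the subtypes (survival, genotype frequencies,
pathway activity, feature enrichment), a label-transfer mechanism for
external cohorts, and a non-linear classifier for IDH genotype.

Because the MRI cohorts behind this design are not redistributable, the
package ships a synthetic-cohort generator that reproduces the
*statistical* structure the pipeline assumes. Everything the test suite
asserts is computed on those synthetic cohorts or on printed count
tables; nothing is asserted about real images.

## Hierarchical multi-kernel subtyping

`hmkl()` proceeds in two learned stages plus a clustering step.

**Kernel bank.** Per modality, features are z-scored and a bank of 35
Gaussian kernels is built on Euclidean distances with locally adaptive
bandwidths: `K(i,j) = exp(-d_ij^2 / (2 eps_ij^2))`,
`eps_ij = sigma (mu_ik + mu_jk) / 2`, where `mu_ik` is the mean distance
of sample *i* to its *k* nearest neighbours. The grids
(`sigma` 1.0–2.5 by 0.25, `k` 10–30 by 5) follow the defaults customary
for multiple-kernel similarity learning; neighbour sets exclude the
sample itself, with distance ties broken by sample order.

**Stage 1 — similarity learning.** Each bank is distilled into one
row-stochastic similarity `S` by block-coordinate descent on

$$\min_{S, w, L}\; -\langle K_w, S\rangle + \beta\|S\|_F^2
  - \gamma\,\mathrm{tr}(L^\top S L) + \rho \sum_l w_l \log w_l$$

with simplex constraints on the rows of `S` and on the kernel weights
`w`, and `L` an orthonormal `n × k` matrix. The three block updates are
each exact (simplex projection, top-`k` eigenvectors, softmax), so the
objective is monotone non-increasing — a property the test suite checks
directly. Two numerical choices matter and were made once, on the
simulated design conditions, before the downstream analyses were run:

* *Kernel normalization.* Each kernel is made symmetrically
  row-stochastic (and rescaled so the mean entry is ~1) before entering
  the objective. Without this, the weight update rewards kernels that
  are uniformly large (a wide bandwidth maximizes `<K, S>` for any S),
  and `w` collapses onto the flattest kernel.
* *Regularization scale.* `beta = 2` keeps each similarity row spread
  over a neighbourhood of order 100 rather than collapsing onto 1–2
  entries, and `gamma = n/(50k)` makes the rank term a gentle pull
  toward `k` blocks. A hard rank term (`gamma ~ n/k`) makes each
  modality commit to its own, partially wrong, partition before fusion
  — exactly what fusion is meant to prevent.

**Stage 2 — modality fusion.** The per-modality similarities are
combined as `S = sum(beta_m S_m)` with consensus weights `beta`: the
leading eigenvector, normalized to the simplex, of the matrix of
pairwise Frobenius inner products between the `S_m`. The inner products
are deliberately *not* normalized to RV coefficients: with two
modalities, any correlation-like normalization fixes the 2×2 agreement
matrix's diagonal at 1 and forces equal weights regardless of content,
whereas raw inner products let the modality with stronger, more
concentrated structure earn a strictly larger weight (`rv_coefficient()`
is still exported for diagnostics).

**Clustering.** Spectral K-means: top-`k` eigenvectors of
`D^{-1/2} S D^{-1/2}`, rows scaled to unit norm, K-means with 100
restarts, deterministic given the seed. If the embedding has fewer
distinct rows than clusters (identical samples), any balanced
assignment attains the same optimum and one is chosen deterministically.

## Choosing the number of subtypes

`choose_k()` maximizes the sum of two criteria over `k = 2..8`:

* **CPI** (clustering prediction index): 20 repeats of a 70/30 split;
  the pipeline is fit on the training part, held-out samples are
  embedded and assigned to the nearest training centroid, and the
  repeat scores `1 - WSS/TSS` on the held-out embedding. Held-out
  samples get spectral coordinates as the cross-similarity-weighted
  average of training embedding rows — exact for a block-constant
  embedding. The cross-similarity rows are sparsified to the largest
  neighbour count in the kernel grid first: in high dimension the raw
  Gaussian kernel's within/between contrast is weak (ratio ~1.5 on the
  default cohort), while the identity of the nearest neighbours is
  reliable.
* **Gap statistic** (50 reference draws, uniform over the range box of
  the concatenated z-scored features, Tibshirani's standard-error
  formula). The simpler uniform reference was chosen over the
  PCA-rotated variant: it is cheap, deterministic given the seed, and
  adequate for standardized features.

Ties break toward the smaller k. Davies–Bouldin and Calinski–Harabasz
indices of the full-cohort clustering at each k are reported as
confirmatory diagnostics, not used in the selection.

## Label transfer

`group_predict()` mirrors the similarity-network-fusion route: joint
(train + test) adaptive Gaussian affinities per modality on per-cohort
z-scored features (features intersected per modality), SNF
cross-diffusion (20 neighbours, 20 rounds), then label propagation
`Y <- P Y` with training rows clamped, to a max-norm tolerance of 1e-8
within 1000 iterations. Per-cohort (rather than joint) standardization
was chosen so that a location/scale shift between cohorts — the typical
scanner effect — does not dominate the joint affinity.

## Between-subtype statistics

* Contingency tables use Pearson's chi-square with Yates continuity
  correction for 2×2 tables — the convention required to reproduce the
  printed cohort statistics exactly (the uncorrected values differ).
* The Mann–Whitney U test reports a tie-corrected normal-approximation
  Z with continuity correction.
* Survival: Kaplan–Meier curves, the two-group log-rank test, and Cox
  regression (Breslow ties) with the cohort's canonical covariate
  coding — subtype, age ≥ 52 years, gender, WHO grade 3/4 vs 2, tumor
  volume ≥ 91 cm³.
* Pathway activity: per sample, expression is regressed jointly on all
  14 pathway weight columns; the slope t-values are the pathway scores
  (positive = activation). Group contrasts use Welch's t-test on the
  per-sample scores; a mode fitting the model to a single per-gene
  contrast vector is available through the same scoring function by
  passing a one-row expression matrix.
* Radiomic enrichment: alteration calls at the pooled 75th/25th
  percentiles of the z-scored feature (linear-interpolation quantiles),
  an upper-tail hypergeometric test per (feature, cluster, direction),
  one Benjamini–Hochberg family across all tests, and the 2/3-in /
  1/3-out fraction filters. Note a structural constraint of this rule:
  with a 75th-percentile call, a cluster holding more than 3/8 of the
  cohort can never have two thirds of its members altered, so
  enrichment findings concentrate in minority clusters; the planted
  recovery experiments use a 25/75 design for this reason.

## IDH genotype model

`gakpls()` is a kernel partial least squares classifier with a Gaussian
kernel whose bandwidth (and component count, 1–15) is tuned by a small
generational GA — tournament selection, uniform crossover, Gaussian
mutation on log bandwidth, elitism — with 5-fold cross-validated AUC as
fitness (population 20, 50 generations by default). KPLS itself is
NIPALS-style: double-centered kernel, one component per deflation
round, dual regression coefficients; with a linear kernel it reproduces
linear PLS exactly, which the tests verify. Raw outputs are calibrated
by logistic regression and thresholded at 0.5.

The comparators (random forest with 500 trees, L1 logistic regression
with a 100-value path and tenfold CV, k-nearest neighbours, Gaussian
naive Bayes) keep their standard defaults; `k = 1` is used for kNN as
the common default of that implementation family, exposed as a flag.
Repeated evaluation uses stratified 80/20 splits; model comparison uses
one-way ANOVA followed by single-step Dunnett comparisons against
GA-KPLS, with adjusted p-values from the equal-correlation multivariate
t distribution (balanced design, correlation 1/2).

## The synthetic cohort generator

`simulate_cohort()` draws: two feature modalities with an informative
block (equicorrelated within-block noise, correlation 0.3) carrying a
between-subtype mean shift of `delta` within-SD units, split across
modalities — with `k = 2` there is a single separating direction, so
both modalities carry it at `delta/sqrt(2)`, preserving the premise
that fusion recovers the full signal; exponential survival with
per-subtype hazards (defaults 1/600 and 1/1200 per day, i.e. hazard
ratio 2) under administrative censoring at 2000 days; per-subtype IDH
and MGMT frequencies (defaults 0.39/0.60 mutant and 0.61/0.74
methylated, the two-subtype cohort proportions); log-normal per-subtype
tumor volume; and a non-linearly-separable (radial) IDH signal of
logit-scale strength 3 embedded in dedicated feature columns, so that a
kernel classifier can exceed any linear one. Default cohort sizes
mirror the motivating study (246 training, 144 external), with a
153/93 subtype split.

What the generator does *not* emulate: real radiomic feature
distributions (heavy tails, boundedness, strong cross-family
correlation), scanner/site effects, segmentation variability, or any
image content. Passing recovery tests therefore demonstrates the
pipeline's correctness under its stated assumptions, not performance
on real MRI data.

Sizes used in the shipped tests and acceptance script are scaled to
single-CPU runs: subtype recovery and cluster-number selection at
n = 200, transfer at 144 external samples, resampling comparisons over
100 splits (the full design uses 1000), Cox recovery at n = 2000.

## Known limitations

* Stage-1 learning uses a documented variant of the published
  multiple-kernel similarity objective; constants (`beta`, `gamma`,
  `rho0`) are package choices, stated above, not taken from a
  reference implementation.
* The CPI split scheme (70/30, 20 repeats) and its out-of-sample
  embedding are this package's explicit definitions.
* Enrichment's fraction filter is structurally insensitive for
  clusters holding more than 3/8 of the cohort (see above).
* GA fitness is cross-validated AUC; co-optimizing the component count
  can be disabled by fixing `ncomp`.
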