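# gliotype

Unsupervised phenotypic subtyping of gliomas from multimodal MRI
radiomic feature tables, and downstream characterization of the
subtypes.

Gliomas of identical WHO grade can have very different prognoses.
`gliotype` addresses non-invasive risk stratification: given
samples-by-features radiomic tables extracted from two MRI sequences
(contrast-enhanced T1 and T2-FLAIR), it

1. fuses the modalities by **hierarchical multi-kernel learning** —
   per modality, a bank of 35 adaptive Gaussian kernels
   `K(i,j) = exp(-d_ij² / (2 ε_ij²))`, `ε_ij = σ(μ_ik + μ_jk)/2`, is
   distilled into a learned similarity `S_m` by block-coordinate descent
   on the rank-constrained objective
   `min -⟨K_w, S⟩ + β‖S‖² - γ tr(LᵀSL) + ρ Σ w log w`,
   then the modalities are combined as `S = Σ β_m S_m` with consensus
   weights from the leading eigenvector of their Frobenius-agreement
   matrix, and subtypes come from spectral K-means on `S`;
2. chooses the number of subtypes by maximizing **CPI + Gap statistic**
   (with Davies–Bouldin and Calinski–Harabasz as confirmation);
3. transfers subtype labels to an external cohort via **similarity
   network fusion** and clamped label propagation;
4. characterizes subtypes with the field's standard statistics —
   chi-square (Yates for 2×2), Mann–Whitney, Kaplan–Meier/log-rank,
   Cox regression, point-biserial correlation, per-sample
   multivariate-linear-model **pathway activity scores** (slope
   t-values against a genes-by-pathways weight matrix), and
   **hypergeometric enrichment** of altered radiomic features
   (75th/25th-percentile calls, BH-FDR, 2/3 vs 1/3 fraction filters);
5. predicts IDH genotype with a **GA-tuned Gaussian-kernel PLS**
   classifier (`gakpls()`), benchmarked against random forest, L1
   logistic regression, kNN and naive Bayes over repeated stratified
   splits with an eight-metric battery (AUC, Se, Sp, ACC, Youden,
   F-measure, G-means, MCC) and ANOVA + Dunnett comparison.

A synthetic-cohort generator (`simulate_cohort()`) reproduces the
statistical structure the pipeline assumes — subtype-shifted correlated
feature blocks split across modalities, exponential survival with a
hazard ratio of 2, subtype-dependent IDH/MGMT frequencies, log-normal
tumor volume, and a radially non-separable IDH signal — so the whole
pipeline is testable without imaging data.

## Worked example

```r
library(gliotype)

co  <- simulate_cohort(sim_cohort_spec(n_samples = 200, delta = 3, seed = 11))
fit <- hmkl(co$tables, k = 2, seed = 11)
fit
#> <hmkl> 200 samples, k = 2 subtypes
#> cluster sizes: 123 / 77
#> modality weights: T1CE=0.502, T2FLAIR=0.498
ari(fit$labels, co$labels)
#> [1] 0.979949
```

The fused clustering recovers the planted subtypes almost perfectly
(adjusted Rand index 0.98); each modality alone reaches only ~0.94,
which is the point of the fusion. Survival then separates cleanly:

```r
lr <- km_logrank(co$clinical$os_days, co$clinical$event, fit$labels)
lr$chisq
#> [1] 15.46181
cox_subtype_table(co$clinical, fit$labels, high_level = 1)[1, c("term", "hr", "p")]
#>           term       hr            p
#> 1 subtype_high 1.946887 0.0001092187
```

(the generator plants a true subtype hazard ratio of 2; the one-seed
estimate above sits inside its Wald CI). For cluster-number selection
and IDH prediction:

```r
ck <- choose_k(co$tables, k_range = 2:8, seed = 11)   # ~90 s, one CPU
ck$k_star
#> [1] 2
```

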