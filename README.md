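# mtentropy

Intra-host mitochondrial DNA (mtDNA) entropy profiles for case/control
association — a liquid-biopsy analysis that measures *how diverse* each
position of the 16,569 bp mitochondrial genome is within a patient's
blood, instead of hunting for specific mutations.

## Who this is for

Bioinformaticians working with deep-sequencing read counts over mtDNA
(bam-readcount-style tables) who want to: quantify per-site heteroplasmy
robustly across samples sequenced at different depths; compare tissues or
case/control groups site by site; and test whether whole-genome
heterogeneity profiles discriminate disease status.

## The method

For site $j$ with symbol fractions $x_i$ over {A, C, G, T}, heterogeneity
is Shannon entropy

$$H_j = -\sum_i x_i \log_2 x_i .$$

Because the plug-in estimator's bias depends on sequencing depth, each
site's entropy is the mean over 100 random draws of 50 reads taken
without replacement (exact at depth ≤ 50). Before that, minor variants
compatible with sequencing error are removed by an exact binomial tail
test: a variant seen $k$ times at depth $n$ is dropped when
$P(X \ge k) > 10^{-5}$ for $X \sim \mathrm{Binomial}(n, q/3)$, $q = 0.01$.
Each sample's per-site entropies are standardized to Z-scores (the SMEP,
standardized mtDNA entropy profile). Downstream: consensus differencing
and paired/Welch per-site t-tests for group comparisons, iterative
ReliefF ranking of all 16,569 sites (top 1% = 166 sites selected by
default), and a random forest (101 trees, depth 4, min split 19,
balanced class weights) with stratified 10-fold cross-validation,
held-out testing, an HVS1-only model (positions 15,977–16,391), and
grade regression against a permutation baseline.

A synthetic cohort generator (`simulate_cohort()`,
`simulate_tissue_trios()`) reproduces the statistical structure the
analysis assumes — group-specific depths (~50x vs ~120x), a long-tailed
heteroplasmy spectrum, haplogroup-like backbones, planted differential
sites, per-read error — with recorded ground truth, so the whole
pipeline is testable without access to controlled patient data.

## Worked example

```r
library(mtentropy)

cfg <- sim_config(n_cases = 40, n_controls = 40)       # blood cohort, 50x vs 120x
sim <- simulate_cohort(cfg, seed = 7)
kept <- qc_filter(sim$cohort)$kept                     # >= 95% genome covered
eps  <- lapply(kept, entropy_profile, params = resample_params(seed = 7))
eps[[1]]
#> <entropy_profile> S0001 (blood, HCC): L = 16569, total entropy 0.000971 bits/site, 25 nonzero sites

cm <- cohort_matrix(eps)                               # samples x sites SMEP matrix
cm
#> <cohort_matrix> 80 samples x 16569 positions (HCC: 40, NC: 40)

te <- vapply(eps, total_entropy, numeric(1))
mean(te[cm$group == "NC"]) / mean(te[cm$group == "HCC"])
#> [1] 1.345

rw  <- relief_weights(cm)                              # iterative ReliefF
sel <- top_fraction(rw, 0.01)                          # 166 top-ranked sites
sim$truth$planted_lower %in% sel
#> [1] TRUE

crossval_classify(cm$X[, sel], cm$group, rf_config(seed = 7), n_folds = 10)
#> <cv_report> 10-fold CV: mean accuracy 97.50%, max 100.00%
```

Reading the output: the case profile has ~0.001 bits/site total entropy
(25 sites survive error filtering at 50x); controls carry ~1.3x more
total entropy — note this arises largely from the depth difference in
minor-variant detection, a confound discussed in the vignette; the
planted low-entropy site is recovered inside the 166 selected sites; and
the selected-site SMEPs separate the groups at 97.5% mean
cross-validated accuracy.

File-based workflows use `parse_readcounts()` / `load_cohort()` for
input and `run_pipeline()` (or `inst/scripts/run_pipeline.R` from a
shell) to emit per-stage TSVs plus run metadata.

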