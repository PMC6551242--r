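---
title: "Measuring intra-host mtDNA heterogeneity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intra-host mtDNA heterogeneity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtentropy)
```

## The measurement problem

Blood carries a population of mitochondrial genomes rather than a single
sequence: heteroplasmy — the coexistence of several mtDNA variants within
one host — means that every position of the 16,569 bp mitochondrial
genome has, in principle, its own variant spectrum. `mtentropy`
quantifies that spectrum per position as Shannon entropy and asks whether
the genome-wide *profile* of per-site entropies, rather than any specific
mutation, separates cancer cases from controls. Working at the level of
site diversity sidesteps two chronic problems of mutation-based liquid
biopsy: the idiosyncrasy of individual tumor mutations across patients,
and the dominance of host lineage (haplogroup) differences in any direct
comparison of sequences.

The package starts from per-sample, per-position nucleotide read counts
(a bam-readcount-style table); mapping, NUMT removal, duplicate marking
and quality trimming are upstream concerns and out of scope.

## Per-site entropy with depth normalization

For a site $j$ with symbol fractions $x_i$ (over A, C, G, T by default),

$$H_j = -\sum_i x_i \log_2 x_i,$$

so a monomorphic site scores 0 bits and a uniform four-symbol site 2
bits. The plug-in estimator is negatively biased at finite depth, and the
bias depends on depth — a fatal property when cases and controls are
sequenced at ~50x and ~120x respectively. The package therefore
subsamples: at every position, `n_resamples = 100` draws of
`reads_per_draw = 50` reads are taken **without replacement**
(multivariate hypergeometric on the counts) and the plug-in entropies of
the draws are averaged. Fifty reads matches the case-group mean depth
(~49.6x), so sites at or below that depth use all their reads — every
draw is the full site and the value is exact, not Monte Carlo. This
choice avoids fabricating reads at shallow sites and makes the dominant
depth class deterministic.

Zero-depth positions carry entropy 0 (with a retained mask) rather than
missing values, so all profiles have identical length; a sample must
cover at least 95% of the genome to pass QC in the first place.

Each profile is standardized per sample into Z-scores — the SMEP,
standardized mtDNA entropy profile — using the population
(divide-by-$N$) standard deviation so results are bit-reproducible. A
constant profile (no detected heteroplasmy anywhere) standardizes to all
zeros with a warning rather than an error, since such samples do occur
at shallow depth.

One RNG stream is derived per sample from `(seed, sample_id)`, so cohort
results do not depend on the order in which samples are processed.

## Separating heteroplasmy from sequencing error

A minor variant observed $k$ times at depth $n$ is kept only if error
alone is an implausible explanation. Errors are modeled as symmetric
substitutions at per-read rate $q$ (default 0.01, conservative for
Illumina), landing on a specific alternative base at rate $q/3$; the
variant is removed when $P(X \ge k) > 10^{-5}$ for
$X \sim \mathrm{Binomial}(n, q/3)$, computed exactly. The $10^{-5}$ bar
is the one parameter fixed by the upstream protocol this package
mirrors; the binomial-tail form itself is this package's documented
choice, made because the originally cited separation procedure is not
fully specified — the test is deliberately the simplest count-based rule
consistent with the stated threshold. The majority symbol is never
removed, and on an exact majority tie both symbols are exempt (removing
either would arbitrarily rewrite the consensus). Filtering is equivalent
to thresholding at the smallest retained count $k^*(n)$, which is how it
is vectorized; the equivalence is property-tested against per-variant
evaluation.

Two consequences worth knowing. First, a *true* 10% heteroplasmy at 50x
presents fewer than $k^*(50) = 5$ minor reads about 43% of the time —
no count-based rule at this threshold can keep those, so calibration
statements are made about *observed* minor fractions. Second, $k^*$
grows with depth more slowly than depth itself, so deeper samples detect
*lower-frequency* heteroplasmies: detection sensitivity is
depth-dependent even after entropy is depth-normalized. This matters
below.

## Group comparisons

Consensus sequences (per-position majority, ties broken A < C < G < T <
DEL, `N` at zero depth) support tissue differencing: tumor-specific
sites are positions where a patient's tumor and blood consensus differ,
pooled across patients with per-site prevalence. Per-site tests are a
paired t-test on per-patient differences (matched tissues) or Welch's
unequal-variance t-test (case/control); the headline site fractions use
raw $p < 0.05$, uncorrected, mirroring the comparison protocol this
package reproduces, with a Benjamini–Hochberg column emitted as
supplementary output. Fractions are reported both over polymorphic
positions and over all positions, because the denominator is ambiguous
in the source protocol. Zero-variance positions get $p = 1$ and no
direction.

## Site selection and classification

Sites are ranked by iterative ReliefF: each pass accumulates, per
feature, the range-normalized difference to each sample's $k = 10$
nearest misses minus nearest hits; the next pass measures nearness with
the previous pass's (clamped, normalized) weights, starting uniform, for
up to 20 passes or until the largest weight change is below $10^{-4}$.
All samples serve as anchors and ties break by sample index, so the
ranking is fully deterministic; a single pass is plain ReliefF and is
oracle-tested against an exhaustive implementation. The top 1% of
16,569 sites — exactly 166 — feeds the classifier by default.

The classifier is a random forest with the fixed structural
hyperparameters: 101 trees, depth ≤ 4, at least 19 samples to split, at
least 1 per leaf, balanced class weights. Forests are grown with
`ranger`, which offers Gini but not information-gain splitting; with
trees this shallow the two impurities almost always pick the same
splits, and the divergence is accepted and recorded rather than patched
with a hand-rolled forest. Cross-validation is stratified 10-fold. When
a feature selector is passed to `crossval_classify()` it is refit inside
every training fold; selecting once on the full optimization set and
then cross-validating (the protocol of the source analysis) is available
by simply passing the pre-restricted matrix, but note it is optimistic —
selection has seen every fold's test samples. Held-out evaluation with
`train_and_test()` is the honest estimate. The HVS1-only model restricts
columns to positions 15,977–16,391 (415 sites) first.

Grade regression uses the same forest structure in regression mode and
reports 10-fold mean absolute error against a label-permutation
baseline (100 permutations). On the printed grade distribution
(41/134/104/13 for grades 1–4) the permutation baseline is ≈ 0.77,
while an uninformative regressor that shrinks toward the central grade
already achieves ≈ 0.62 — essentially the headline MAE of the source
analysis — so a grade MAE near 0.6 on this distribution should not, by
itself, be read as evidence of association.

## The synthetic cohort generator

Controlled-access sequencing data cannot ship with the package, so every
stage is exercised against a generator whose defaults encode the study
conditions: 232 cases + 232 controls (with a 61 + 159 held-out
configuration available), negative-binomial depths with means 50x
(cases) and 120x (controls), 99.5% of positions covered, a pool of
0.5% of positions (~83) carrying heteroplasmy with long-tailed minor
fractions $0.5 \cdot \mathrm{Beta}(0.8, 4)$ clamped to $[0.01, 0.40]$,
five haplogroup-like consensus backbones assigned independently of case
status, and per-read error 0.003 applied as the closed-form mixture
$p_{obs} = p(1-q) + (1-p)q/3$. Differential sites are planted at 1.77%
(lower in cases) and 0.32% (higher) of the pool, with minor fractions
multiplied by 0.15 in the affected group; planted sites are drawn from
pool sites with baseline minor fraction ≥ 0.10, because an "effect" at
a site below the filter's detection limit at study depth would be
vacuous. The upper clamp at 0.40 exists because near-balanced
heteroplasmy makes the per-tissue majority call unstable under binomial
read sampling, which would contaminate consensus-difference statistics
with calls that flip by chance. Trio mode shares each patient's minor
fractions across blood/tumor/normal (depth means 50/100/350), giving
the tumor a Poisson(0.92) number of clonal consensus flips.

Ground truth (pool positions, per-site fractions, planted sites, flip
positions) is recorded, so selection recall, classifier performance and
consensus statistics can be checked against what was actually planted.

**What the generator does not emulate:** real haplogroup phylogeny,
strand- or quality-structured error, alignment artifacts, NUMT leakage,
amplification jackpots, or any linkage between sites. Tests passing on
this generator show the *machinery* is correct and calibrated under its
stated statistical structure; they do not certify performance on real
cohorts.

### The depth confound, on purpose

A finding worth stating plainly: with **no** planted effects and **no**
global diversity difference, simply sequencing cases at 50x and controls
at 120x produces an NC/HCC total-entropy ratio of ≈ 1.29 — the
magnitude of the headline ratio of the source analysis — purely through
the depth-dependence of minor-variant detection, and it drives most
pool sites to nominal case/control significance. The generator's default
global case scaling is therefore 1.0 (the knob `case_mf_scale` exists to
add genuine diversity loss), and the package's null-calibration checks
equalize depths, because with unequal depths the groups are genuinely
not exchangeable. Users comparing groups sequenced at different depths
should treat per-site significance fractions with corresponding caution
even after subsampled entropy normalization.

## Numerical and degenerate-case choices

* Entropy uses $0 \log 0 = 0$; all-zero sites are the caller's
  responsibility (`site_entropy()` errors, profile builders flag).
* Windows for the 201 bp sliding mean are circular, consistent with
  mtDNA topology; even widths are rejected.
* `top_fraction()` takes `round(fraction * L)` sites, descending weight,
  ties by ascending position.
* Seeds derive per-sample streams via a 31-bit polynomial hash of
  `(seed, sample_id)`; all results are bit-reproducible given the master
  seed, and sample order never matters.
* Paired tests with zero-variance differences, and Welch tests where
  both groups are constant, return $p = 1$ rather than `NaN`.

## Problem sizes used in the shipped checks

The package's own verification uses cohorts simulated at the study's
stated sizes (232+232 optimization, 61+159 held out, 300 trio patients)
on the full 16,569-position axis; calibration suites use 10,000
constructed sites (filter) and 200 samples × 2,000 sites (per-site test
null). The exact-expectation oracle for subsampled entropy enumerates
all 51 draw compositions of a two-symbol site. These sizes were chosen
so the whole verification runs comfortably on a laptop-class single
core in minutes.

## Known limitations

* The error model is a single scalar rate: no per-base quality, strand,
  or context structure, and the filter threshold applies per variant
  without multiplicity correction across the genome.
* Insertions are ignored end to end; deletions are carried as an
  optional fifth symbol but excluded from entropy by default (keeping
  the 2-bit bound of the four-base alphabet).
* The "number of reads" summary metric of the source comparison tables
  is not computable from mtDNA read counts alone and is omitted from
  `summarize_groups()`.
* ReliefF's variant space is large; the implementation is one defensible
  member of the family (re-weighted distances, all-anchor, deterministic
  ties) with its parameters exposed, not a reconstruction of any
  specific historical implementation.
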