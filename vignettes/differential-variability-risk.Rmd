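---
title: "Differential methylation variability and outlier-based risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation variability and outlier-based risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evorisk)
library(dplyr)
```

## The problem

In a prospective epigenome study, DNA methylation is profiled in
morphologically normal cells years before any sign of neoplastic
transformation, and the question is whether those profiles already carry a
risk signature. The empirical pattern that motivates this package is that
risk-associated CpGs do not shift their *mean* methylation appreciably
between future cases and controls; instead they become more *variable* in
future cases, because a small subset of "outlier" samples gains 20–30
percentage points of methylation while the rest stay at baseline. A mean
test (t-test) dilutes this signal across all samples; a variance test sees
it directly.

`evorisk` implements the full workflow around that observation:

1. **Differential variability.** For each CpG, an age-adjusted Bartlett
   test compares the case and control variances
   (`rank_dvcs()`): with group variances $s_1^2, s_2^2$ and sizes
   $n_1, n_2$ ($N = n_1 + n_2$),
   $$T \;=\; \frac{(N-2)\ln s_p^2 - (n_1-1)\ln s_1^2 - (n_2-1)\ln s_2^2}
   {1 + \tfrac{1}{3}\bigl(\tfrac{1}{n_1-1}+\tfrac{1}{n_2-1}-\tfrac{1}{N-2}\bigr)}
   \;\sim\; \chi^2_1 .$$
   The per-CpG $b$-statistic is $\log_2(s^2_{case}/s^2_{control})$; CpGs
   with $b > 0$ are *hypervariable*. Variances are estimated after
   ordinary-least-squares adjustment for age within each phenotype, so an
   age trend can neither mimic nor mask differential variability.
2. **Age association.** A supervised linear regression of each CpG's
   beta-value on age with case/control status as an additive covariate
   (`age_association()`) identifies CpGs drifting upward
   (*age-hypermethylated*) or downward with age.
3. **Candidate risk CpGs.** The candidate pool is the intersection:
   hypervariable at FDR `fdr_dv` *and* age-hypermethylated at FDR
   `fdr_age` (`select_candidates()`). Both FDRs are Storey q-values.
4. **Outlier basis.** Each CpG is COPA-transformed:
   $c = (\beta - \mathrm{med})/(1.4826\,\mathrm{MAD})$, median and MAD
   frozen on training samples (`copa_fit()`, `copa_transform()`). The
   transformation is invariant to per-CpG affine recalibration and puts
   every CpG on a common outlier scale: typical samples score below 1,
   clear outliers above 5.
5. **Adaptive-index classifier.** A sample's risk score is the fraction
   of risk CpGs whose COPA value strictly exceeds a threshold. Ten-fold
   stratified internal cross-validation picks the threshold and the
   risk-set size jointly by maximizing mean held-out AUC
   (`train_evora()`), then the model is refit on all training samples.

## Tunable parameters

| parameter | default | units | why this default |
|---|---|---|---|
| `fdr_dv`, `fdr_age` | 0.05 | q-value | conventional FDR level for both selection axes |
| `threshold_grid` | 2, 3, 4, 5, 7, 10 | COPA units | spans the "no methylation" (<1), moderate (<5) and extreme (>10) outlier bands |
| `size_grid` | 25, 50, 100, 140, 200, all | CpGs | bracket the typical size of a risk set on a 27K-style array |
| `folds` | 10 | — | standard internal CV depth; both classes must have at least `folds` members |
| `beta_threshold` | 0.2 | beta | a hit on the beta scale is a ≥ 20-point gain over the training median, the lower edge of the 20–30% outlier change |
| `clip_epsilon` | 1e-6 | beta | keeps R = β/(1−β) and M = log2 R finite at the boundaries |
| `train_fraction` | 2/3 | — | standard holdout split for `repeated_holdout()` |

Cross-validation ties are resolved toward the smaller risk set, then the
smaller threshold — the more parsimonious and more conservative model. A
hit requires a strictly greater value; a value exactly at the threshold is
not a hit (arbitrary but fixed, so scores are exact rational fractions).

## Scales

Beta-values (methylated fraction, in (0,1)) are strongly heteroscedastic:
their variance shrinks toward the boundaries. The package therefore
exposes the ratio scale $R = \beta/(1-\beta)$ and M-value
$\log_2 R$ (`beta_to_r()`, `beta_to_m()`), and `rank_dvcs(scale = "r")`
runs the variance testing on the R scale. Since only beta-values are
available in a normalized matrix, $R$ is defined through $\beta$ rather
than through raw channel intensities; the Illumina intensity offset is
ignored, which makes $R$ an approximation to the raw
methylated/unmethylated ratio whose error is largest at extreme
beta-values.

## Two scoring scales

COPA scoring is tuned to *heterogeneous outlier* profiles: a few samples
far from the bulk. In invasive cancer the same CpGs tend to become hemi-
or fully methylated in *most* case samples; the bulk itself moves, the MAD
inflates, and COPA scores compress. For such cohorts
`score_samples_beta()` (or `as_beta_scale()`) counts hits on the
median-normalized beta scale instead: a hit is a beta-value more than
`beta_threshold` above the frozen training median. The synthetic
`cancer_bimodal` regime reproduces exactly this compression and is the
test bed for the beta-scale variant.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the structure the method assumes, with full
ground truth:

* per-CpG Beta-distributed baselines — Beta(2, 18) (mean 0.1) for risk
  CpGs so that a +0.25 gain is an unambiguous outlier, and per-CpG means
  uniform on (0.05, 0.95) with precision $a+b = 20$ elsewhere (a choice
  unconstrained by published summaries; it gives baseline standard
  deviations of 0.05–0.11, typical of normalized array data);
* 75 cases / 77 controls, ages uniform on 19–55 years;
* age CpGs drift at 0.003–0.007 beta/year (planted drifts are upward,
  matching the hypermethylation direction the candidate definition
  needs); risk CpGs are a subset of age CpGs by default, reproducing the
  overlap between hypervariability and age-hypermethylation that the
  candidate intersection exploits;
* risk CpGs gain U(0.2, 0.3) beta in a Bernoulli(0.15) subset of case
  samples only — the mean case–control difference is then only
  $0.15 \times 0.25 \approx 0.04$ while the variance ratio is large, the
  regime in which variance tests dominate mean tests. The 15% outlier
  rate is this package's reading of "a relatively small number of
  outliers" and is an exposed parameter, not an empirical estimate;
* vCpGs: phenotype-independent CpGs spanning more than 0.8 of the beta
  range, emulating cell-composition variation; they are planted disjoint
  from risk CpGs, so the near non-overlap of vCpG and DVC rankings is
  forced by construction;
* polycomb-target labels on ~50% of risk CpGs plus a 5% background rate,
  enabling enrichment tests.

The simulator does **not** emulate probe-type chemistry, batch or chip
effects, spatial correlation between neighbouring CpGs, HPV-dependent
methylation, or realistic genome-wide correlation structure. Passing
tests therefore demonstrate that the *algorithms* behave as specified in
the regime they assume — not that the method attains any particular
accuracy on real arrays.

## Numerical and design choices

* **Missing values** are excluded pairwise from every mean/variance
  estimate, never imputed; CpGs with more than 20% missing samples can be
  dropped with `filter_missing_cpgs()`. Boundary beta-values are clipped
  to `[1e-6, 1 - 1e-6]`.
* **q-values.** Storey's smoother (cubic spline of $\hat\pi_0(\lambda)$
  over $\lambda = 0.05, \dots, 0.95$, df 3, evaluated at
  $\lambda = 0.95$), falling back to $\pi_0 = 1$ — i.e. plain
  Benjamini–Hochberg — whenever the estimate is unstable or fewer than 20
  p-values are available.
* **Age adjustment for aCpGs** uses explicit supervised regression
  (age + status) rather than surrogate-variable construction; with the
  synthetic generator there are no hidden confounders for surrogate
  variables to absorb, and the explicit model keeps the statistic exact
  and testable. Both `adjust_for_status` settings are exposed.
* **The t-test** is Welch's (unequal variances) — under differential
  variability the equal-variance assumption is exactly what fails.
  Mean differences are computed on unadjusted beta-values; the
  within-phenotype age adjustment cannot change group means.
* **Leakage.** Every fold re-estimates DVC statistics, age statistics,
  candidates and COPA parameters on its training part alone; shuffling
  held-out columns provably cannot change a trained model (tested).
* **Degenerate inputs.** CpGs with zero variance in both groups are
  flagged untestable (`NA` p) rather than erroring a whole matrix scan;
  zero-MAD CpGs are unusable in the COPA basis and excluded from
  candidacy; constant CpGs get slope 0 and `NA` p in the age scan.
* **Ties and ordering.** All rankings sort by ascending p with a
  lexicographic `cpg_id` tie-break, so outputs are deterministic.
* **Seeds.** One user seed is fanned out into independent child seeds
  (`derive_seeds()`), so each stochastic sub-step is separately
  reproducible and no step perturbs another's stream.

## The mean-methylation comparator

`train_mean_comparator()` swaps exactly one ingredient: candidates are
selected and ranked by the Welch t-test (positive mean difference)
instead of by Bartlett. When the comparator is run on outlier-regime
cohorts for the head-to-head contrast, its FDR gate is opened
(`fdr_dm = 1`) so that it always returns a model — by construction of the
regime almost nothing passes a mean-methylation FDR there, and a
comparator that refuses to train has no AUC to compare. With the gate
open it considers every positively shifted CpG in t-rank order and the
cross-validation still chooses its set size, which is the strongest
version of the mean-based strategy; EVORA is nevertheless expected to
beat it on held-out samples in the large majority of partitions.

The same reasoning applies to the permuted-label null calibration: labels
are re-permuted for every partition (`permute_labels = TRUE` in
`repeated_holdout()`). A single fixed permutation is not a null — each
sample keeps its arbitrary label across partitions, so chance
associations learned in training partially generalize to held-out samples
from the same cohort, and the mean AUC drifts off 0.5 for reasons that
have nothing to do with class signal.

## Problem sizes used by the shipped checks

The full-scale statistical checks run on the generator's default
conditions: 20,000 CpGs × 152 samples with 500 planted risk CpGs, and 25
train/test partitions for the comparator contrast. Unit tests use smaller
cohorts (500–3,000 CpGs) with the same proportions, which keeps the whole
suite fast while exercising identical code paths.

## Known limitations

* Bartlett's test is exact under normality but sensitive to kurtosis;
  on real (non-simulated) data heavy tails inflate its type-I error, and
  a robust alternative (e.g. Brown–Forsythe) may be preferable. The
  package deliberately implements the classical test that defines this
  workflow.
* $R = \beta/(1-\beta)$ ignores the Illumina intensity offset (see
  above).
* The q-value smoother can be unstable for small CpG panels; the
  conservative fallback is automatic but costs power.
* `relative_odds_ratio()` refits the full ranking per permutation and is
  the one deliberately expensive operation; its default of 50
  permutations bounds the attainable p at 1/51.
* Scores are fractions over at most a few hundred risk CpGs, hence
  coarsely discrete; AUC confidence intervals account for ties, but
  calibration of the scores as probabilities is out of scope.
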