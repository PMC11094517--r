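---
title: "Methods: polygenic scoring, conversion prediction, and the causal brain-structure chain"
author: "neuroprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scoring, conversion prediction, and the causal brain-structure chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis chain

`neuroprs` implements a complete analysis chain from discovery GWAS
summary statistics and target-cohort genotypes to:

1. **quality control** of variants (call rate, minor-allele frequency,
   exact Hardy–Weinberg test, strand ambiguity) and samples (sex
   concordance, relatedness by method-of-moments IBD, heterozygosity,
   call rate), plus genotype principal components for population
   stratification;
2. a **clumping-and-thresholding polygenic risk score** with a p-value
   threshold sweep, covariate-adjusted model selection by Nagelkerke
   pseudo-R², permutation correction of the selection, z-scaling and
   ±2 SD outlier masking;
3. **prediction of conversion** from amnestic mild cognitive impairment
   (aMCI) to Alzheimer's disease: logistic regression (odds ratio per
   SD of score), ROC/AUC, Cox survival on time-to-conversion, and
   dichotomized/trichotomized risk-group contingency tests;
4. a **brain-structure association scan**: covariate-adjusted Pearson
   correlations of the score against regional surface area, cortical
   thickness and volume, with Benjamini–Hochberg FDR control;
5. **one-sample Mendelian randomization** by two-stage least squares
   (TSLS), with the score as instrument, a regional measure as
   exposure, and conversion as outcome.

Because the motivating cohorts (ADNI-1, UK Biobank) are
access-restricted, the package ships a synthetic-study generator whose
statistical structure matches the assumptions of every downstream
stage, so the whole chain is testable end to end.

# The synthetic-study generator

## Genotypes

Genotypes are biallelic SNVs on one synthetic chromosome with fixed
10 kb spacing (so the 250 kb clumping window spans 25 variants — a
deliberate choice that makes window semantics directly testable).
Variants are grouped into contiguous LD blocks. Within a block each
haplotype allele copies its left neighbour with probability `ld_copy_prob`
(a first-order Markov chain) and is otherwise drawn fresh at the
variant's base frequency; across blocks variants are independent, as
are the two haplotypes of a sample. At matched allele frequencies the
adjacent-variant correlation is the copy probability, so adjacent r²
≈ `ld_copy_prob²` and r² decays geometrically with index distance. The
copy chain pulls each variant's marginal frequency toward its
neighbour's (`f_j = c·f_{j−1} + (1−c)·p_j`); the panel records this
implied marginal in `variants$freq` and the generator's frequency
tests check empirical frequencies against it.

Allele pairs are drawn with only ~10% strand-ambiguous (A/T, C/G)
pairs, emulating array designs that avoid ambiguous assays, so the
ambiguity filter is exercised without discarding a third of the panel.

## Discovery summary statistics

Rather than adding closed-form noise to true effects, the generator
simulates an explicit discovery cohort (default 5,000 samples) under
the same LD process, builds a continuous neuroticism-like phenotype
with heritability `h2` from `n_causal` standard-normal effects, and
reports per-variant *marginal* least-squares effects, standard errors
and p-values. Marginal effects at non-causal variants therefore carry
real LD tagging (a neighbour at correlation r to a causal variant has
expected marginal effect r·β), which is exactly the structure that
clumping is meant to handle.

## Cohort phenotypes and the mediation chain

Covariates mirror the published cohort: age ~ Normal(75.02, 7.20²),
sex (66% male), four sites, education years, APOE ε4 allele count
(binomial with allele frequency 0.3). The standardized true score `S`
is the genotype-weighted sum of the true effects. One designated
mediator region (`region001_surface_area`) has standardized value
`−gamma_med·S − 0.1·age_z + noise`; all other region-measure columns
(130 regions × surface area / thickness / volume by default) are
independent noise, stored on realistic measurement scales (means and
SDs per measure type) — partial correlations are unaffected by these
affine scales.

Conversion is generated so that the binary indicator and the event
time cannot disagree: the 1-year conversion probability follows the
logistic model `logit(p) = logit(base_rate) + beta_med_out·M +
beta_direct·S`, and the event time is exponential with hazard
`−log(1−p)`, censored at 10 years. Then `P(T ≤ 1 year) = p` exactly,
so the 1-year indicator follows the stated logistic model while times
are exponential in the same linear predictor. Covariate effects on
conversion default to zero, which keeps the null configuration
(`gamma_med = beta_direct = beta_med_out = 0`) exactly at `base_rate`.

Defaults (`n_target = 304`, `base_rate = 0.15`, `gamma_med = 0.5`,
`beta_med_out = −0.9`, `beta_direct = 0.45`, `h2 = 0.3`,
`n_causal = 50`) are chosen for *detectability at n ≈ 300*: no public
scale links neuroticism genetics to conversion risk, and the
score→mediator correlation observable in the cohort is attenuated by
the correlation between the measured PRS and the true score (~0.7 at
these settings), so the mediator loading is set high enough that the
designed chain is visible in a cohort of this size. The generator
emulates the *statistical structure* of the published design — LD,
marginal tagging, covariate confounding, a single mediated pathway —
not human LD maps, admixture, X-chromosome biology, imputation
uncertainty, or the correlated multi-region atrophy patterns of real
cortex. Passing tests therefore demonstrate that the machinery is
correct under the stated model, not that real-data effect sizes would
be reproduced.

## QC violation injection

`inject_qc_violations()` plants labelled failures for the filters:
reported-sex flips; near-duplicate samples (0.5% mutation rate,
expected PI_HAT near 1); simulated first-degree relatives (one
transmitted allele per variant, expected PI_HAT near 0.5); inflated
heterozygosity; per-sample missingness pushing call rate below 97%.
Ground-truth labels are returned so tests can assert per-reason
removals exactly.

# Quality control

Thresholds follow the published filters: variants with call rate
< 0.95, MAF < 0.01 (0.001 in the UKBB-style preset), exact HWE
p < 5×10⁻⁷ (the printed `0.5 × 10⁻⁶` read literally; configurable
since the notation is unusual), or ambiguous strand are removed;
samples with sex mismatch, call rate < 0.97, heterozygosity outside
mean ± 5 SD, or a partner with PI_HAT > 0.1875 are removed. Reasons
are assigned in the precedence order sex → call rate → heterozygosity
→ relatedness, each computed on the survivors of the previous step, so
removal counts reconcile exactly (input = output + per-reason counts).

The HWE test is the exact conditional test: given the allele counts,
heterozygote counts of matching parity are enumerated, and the p-value
sums the probabilities of configurations no more probable than the
observed one. It is validated against a full-enumeration oracle for
every configuration with n ≤ 25. A chi-square variant is exposed for
comparison with pipelines that used the asymptotic test.

Relatedness uses the classical method-of-moments estimator: observed
IBS category counts are equated to their expectations under IBD state
0/1/2, the solved probabilities are clamped to [0, 1] and
renormalized, and PI_HAT = P(IBD=2) + P(IBD=1)/2. Two desk-scale
caveats are deliberate and documented:

* the estimator assumes (near-)independent markers, so
  `filter_samples()` first LD-prunes the panel (r² ≤ 0.2 in 250 kb);
* at a few thousand markers the null PI_HAT distribution is noisy and
  right-skewed (the clamping rectifies noise upward), so occasional
  unrelated pairs can cross 0.1875. The filter warns when relatedness
  removals exceed 10% of samples, which on clean data indicates too
  few markers rather than real relatedness. The default generator
  panel (8,000 variants) keeps this tail negligible; real studies use
  10⁵–10⁶ markers and do not face it.

Among a related pair the member with the lower call rate is removed
(ties: lexicographic id); the published pipeline does not state its
rule. Sex concordance compares reported sex against a genetic-sex
field supplied with the data — no X chromosome is modelled, so
X-heterozygosity inference is out of scope by design. PCs come from
the SVD of the standardized (mean-imputed) dosage matrix with a
deterministic sign convention (largest-magnitude loading positive);
PC outliers beyond 6 SD on the top four components can be flagged with
`flag_pc_outliers()`.

# The score: clumping and thresholding

Discovery effects are aligned to the panel's counted allele (same
orientation keeps β, swapped alleles negate it, mismatching or
ambiguous pairs are dropped and logged). Clumping is greedy: variants
are processed in ascending discovery p (ties broken by position), each
surviving variant becomes an index, and unprocessed variants within
250 kb with dosage r² > 0.5 are removed. LD is computed from the
target panel itself — in the published design the target cohort is the
only individual-level genotype source — and r² is the squared Pearson
correlation of unphased dosages. The raw score at threshold `p_T` is
`Σ_j G_ij β_j` over index variants with `p_j ≤ p_T`, with missing
dosages imputed to twice the counted-allele frequency; the published
formula is a raw sum, not a per-allele average, and the downstream
z-transform makes the distinction immaterial.

The sweep uses the 1,000-point grid `p_T ∈ {0.001, …, 1.000}` (the
stated range and step produce exactly 1,000 scores; the permutation
count is a separate parameter). For each threshold the z-scored PRS
enters a covariate-adjusted logistic regression of conversion
(covariates: sex, age, site, education, APOE ε4 count, first four
PCs), and the recorded Nagelkerke R² is the increment of the full
model over the covariate-only baseline — the argmax over thresholds is
identical to using the intercept-only baseline because covariates are
constant across thresholds, and the increment is what reads as
"variance explained by the score". Ties go to the smaller (sparser)
threshold. Thresholds that share an identical variant set reuse one
score and one fit. The best score is z-transformed and samples outside
mean ± 2 SD of the *scaled* score are masked (scale first, then trim,
matching the published order); the mask is applied downstream rather
than deleting rows, so sensitivity analyses can toggle it. Under
normality the mask removes ≈ 4.6% of samples in expectation.

Permutation correction permutes the outcome vector only, re-runs the
full threshold sweep per permutation (scores and covariates fixed, so
only the logistic stage is refit), and reports
`p = (1 + #{permuted best R² ≥ observed}) / (1 + n_perm)`. By
exchangeability under the null this is valid at any permutation count;
the default is 1,000 and the calibration test uses 200 permutations ×
200 replicates, which keeps the check inside a small CPU budget while
the binomial interval around 0.05 is still informative.

# Prediction models

Logistic fits use `stats::glm` (IRLS); the package reports per-term
odds ratios with Wald intervals, Nagelkerke R² — computed as
`(1 − exp((2/n)(ℓ₀ − ℓ₁)))/(1 − exp((2/n)ℓ₀))` — and the AUC of the
fitted linear predictor via the Wilcoxon rank statistic
(`P(score_case > score_control) + ½P(tie)`). Quasi-separation is
flagged. Cox fits use the Breslow tie convention with the Breslow
baseline cumulative hazard; cumulative risk for a covariate profile is
`1 − exp(−Λ₀(t)·e^{xβ})`. Contingency tests are Pearson chi-square
*without* continuity correction and group comparisons use the
pooled-variance Student t — both conventions reverse-engineered by
matching every reproducible statistic in the published demographic
table to its printed two-decimal value. Risk groups are median or
tertile splits with the remainder assigned to the upper groups,
reproducing the published 139/139 and 92/93/93 splits at n = 278; ties
are broken by stable input order.

Conversion at a horizon (1 or 10 years) uses diagnosis status at that
horizon; the Cox model uses time-to-conversion censored at last
follow-up. Both are exposed.

# Brain-region scan and FDR

For each regional column the scan computes the partial Pearson
correlation of the z-scored PRS with the measure given the covariate
set: both variables are residualized on `[1 | C]` by least squares,
the residuals are correlated, and `t = r√((n−2−k)/(1−r²))` on
`n−2−k` df gives the p-value. Benjamini–Hochberg correction is applied
jointly across the full region × measure family (390 tests in the
default layout) — the conservative reading, since the publication does
not state whether measure types were corrected jointly; a per-measure
family is a config option. A replication-style second scan restricted
to the discovery-significant set at unadjusted p < 0.05 with matching
sign is provided by `region_replicate()`.

# Mendelian randomization

`tsls_fit()` is a hand-rolled two-stage least squares: stage 1
regresses the exposure on `[1 | Z | C]`, stage 2 regresses the outcome
on `[1 | X̂ | C]`. The binary outcome is treated as a linear
probability — matching the published estimator choice — rather than a
probit/logit control function. Standard errors are classical: the
stage-2 covariance formula is evaluated with residuals recomputed from
the *observed* exposure; HC0 robust errors are an option. The exposure
is standardized to unit SD first so the estimate reads "change in
outcome per SD of exposure attributable to the instrument". The
stage-1 instrument F (squared t) is reported and F < 10 flags a weak
instrument. Correctness rests on three identities tested to tight
tolerances: single-instrument covariate-free TSLS equals the Wald
ratio `cov(Z,Y)/cov(Z,X)` (10⁻¹⁰); residualizing Z, X, Y on C first
and running covariate-free TSLS reproduces the covariate fit (10⁻⁸);
and a confounded-mediation simulation shows ≈95% CI coverage where
naive OLS is visibly biased. The published MR coefficient's
units/orientation cannot be reconciled without the restricted data, so
no numerical target is asserted for it; the package asserts the *sign
pattern* of the chain (negative stage-1, negative TSLS coefficient).

# Numerical choices and degenerate inputs

* IRLS runs to a 10⁻⁸ coefficient-change tolerance (100 iterations
  max); non-convergent thresholds are skipped with a log message, and
  an all-skipped sweep is an error.
* Zero-variance variants have r² defined as 0; clumping treats an
  undefined correlation as 0.
* A monomorphic HWE configuration has p = 1 (single configuration);
  all-zero genotype counts are an error.
* `stratify_groups` requires n ≥ k and no missing scores; logistic
  fits refuse constant outcomes and name collinear columns; Cox fits
  refuse zero events and all-constant predictors; TSLS refuses an
  instrument with zero partial variance given covariates.
* Seeds: `sim_config(seed =)` drives stage-specific derived seeds (all
  below 2³¹), so a study is bit-reproducible end to end; the pipeline
  records the seed in every manifest and output.

# Problem sizes used by the test suite

The suite's study fixtures use 250 samples × 6,000 variants (module
chain tests), 304 × 8,000 (the default generator, exercised by the
acceptance script), and smaller panels for oracle comparisons (40-
variant clumping instances, 20 × 30 scoring panels, n ≤ 25 HWE
enumeration). Monte-Carlo checks use 200–500 replicates with fixed
seeds. These sizes were chosen so the whole suite runs comfortably on
one CPU while every stochastic check retains a meaningful binomial
interval.

# Known limitations

* PI_HAT at a few thousand markers is noisy near the 0.1875 threshold
  (see above); this is a marker-count limitation of the desk-scale
  setting, not of the estimator's implementation.
* The generator's non-mediator regions are independent noise; real
  regional measures are strongly correlated, so the FDR family in real
  data is effectively smaller than 390 independent tests.
* The linear-probability TSLS estimand for a binary outcome is an
  approximation; a control-function variant is deliberately out of
  scope to match the published estimator.
* Imputation (and imputation-quality filtering) is upstream of this
  package: synthetic panels are treated as post-imputation data.
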