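---
title: "Methods: serum miRNA marker discovery and incremental risk value"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum miRNA marker discovery and incremental risk value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seromir)
```

## The analysis problem

Circulating microRNAs are candidate markers for the presence of
atherosclerosis, but a new marker is only useful if it adds estimation power
to the clinical and laboratory markers that are already measured (HbA1c,
lipid fractions, lipoprotein(a), hs-CRP, and so on). `seromir` implements
the complete chain of such a study on two-card qPCR array panels:

1. **Serum quality control.** Hemolysed serum is contaminated with
   red-cell miRNAs, so samples with free-oxyhemoglobin absorbance of 0.2 or
   more at 415 nm are excluded (`hemolysis_filter()`; the retention rule is
   strict, `A415 < 0.2`).
2. **Ct cleaning.** Wells that never crossed the fluorescence threshold
   within the 40-cycle run are *undetermined*; they are replaced by the
   maximal cycle number, 40, and marked undetected
   (`impute_undetermined()`). A well is *detected* only when its original
   Ct was determined and strictly below the limit — this keeps the
   detection flags and the imputed values mutually consistent.
3. **Reference selection.** Candidate normalisers must be detected in
   every sample, show a mean between-group expression fold change within
   0.9–1.1, and show no significant group difference (t-test p > 0.05)
   (`candidate_reference_filter()`). Candidates are then ranked by a
   model-based stability value over all singles and pairs
   (`normfinder_stability()`), and the set with the lowest value becomes
   the reference (`best_reference()`).
4. **Relative quantification.** Per sample, ΔCt = Ct(miRNA) − Ct(reference)
   and Q~rel~ = 2^−ΔCt^ (`delta_ct()`). The reference Ct of a pair is the
   unweighted arithmetic mean of the members' Cts, which on the expression
   scale is geometric-mean normalisation; because every miRNA in a sample
   shares that sample's extraction/loading offset, the subtraction cancels
   it exactly.
5. **Marker discovery.** miRNAs with a Q~rel~ fold change below 0.5 or
   above 2.0 and a two-sided equal-variance t-test p < 0.05 are candidate
   markers (`differential_candidates()`); forward stepwise linear
   discriminant analysis on partial Wilks' Λ F statistics reduces them to a
   putative marker set (`stepwise_discriminant()`), which is then
   re-tested in an independent validation cohort (`validate_marker()`).
6. **Risk modelling.** Forward logistic regression over the clinical
   covariates plus the validated marker(s) identifies independent
   correlates of atherosclerosis presence (`forward_logistic()`);
   overfitting is gauged by leave-one-out cross-validation with the
   covariate set held fixed (`loocv_accuracy()`).
7. **Incremental value.** The clinical-only and clinical-plus-marker models
   are compared by sensitivity/specificity/accuracy at a 0.5 threshold
   (`classification_metrics()`), by paired ROC AUC with a DeLong test
   (`roc_auc()`, `compare_auc()`), and by the category-free net
   reclassification improvement and the integrated discrimination
   improvement (`nri()`, `idi()`).

`run_pipeline()` executes the whole chain deterministically and writes
JSON/CSV artifacts with a configuration hash.

## The stability model

`normfinder_stability()` implements the two-group model-based estimator for
normaliser selection. Input values must be on a log scale on which
expression is additive; for qPCR data this is the negative Ct (Ct is
already a log2 quantity, so no further transformation is applied). The
model writes each value as gene effect + sample effect + gene-by-group
interaction d~ig~ + noise, with the interactions constrained to sum to zero
over genes within each group. The algorithm:

1. centre each sample across the k candidate genes (this removes sample
   effects and makes the score invariant to per-sample offsets);
2. per gene and group, compute the mean (an estimate of d~ig~) and the
   within-group variance s²~ig~;
3. bias-correct the variances for the centring step by solving
   E[s²~ig~] = σ²~ig~(1 − 2/k) + (1/k²) Σ~i′~ σ²~i′g~, clamping negative
   solutions at zero;
4. shrink the interaction estimates empirically,
   d̃~ig~ = d̂~ig~ · γ²/(γ² + σ̂²~ig~/n~g~) with
   γ² = max(0, Var~i~(d̂~ig~) − mean~i~(σ̂²~ig~/n~g~));
5. score each gene as the mean over groups of |d̃~ig~| + √(σ̂²~ig~/n~g~).

A pair is scored as the pseudo-gene formed by averaging the two members'
centred values, with the same variance correction and shrinkage constants;
averaging two independent, unbiased genes roughly halves the noise
variance, which is why a good pair can beat its best member. The search
space is all singles plus all unordered pairs; when more than
`max_pair_candidates` (default 20) candidates pass the filter, pairs are
formed among the 20 most stable singles to bound the quadratic search.
Exact numeric agreement with any particular legacy implementation of this
estimator is not a goal; the estimator is validated against panels with
known per-gene variance and known (sum-to-zero) group bias, where the gene
minimising |d| + √(σ²/n) must rank first.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| hemolysis threshold | 0.2 | absorbance at 415 nm | standard serum hemolysis screen; strict `<` |
| `max_cycles` | 40 | PCR cycles | run length of the array protocol; also the undetermined replacement |
| reference fold window | 0.9–1.1 | fold change | near-unity expression across groups |
| marker fold window | outside 0.5–2.0 | fold change | two-fold up or down |
| `ref_alpha`, `marker_alpha` | 0.05 | probability | conventional two-sided test levels |
| `alpha_discriminant`, `alpha_logistic` | 0.05 | probability | entry levels for stepwise procedures |
| classification threshold | 0.5 | probability | symmetric cost assumption |

No multiple-testing correction is applied anywhere in the discovery chain;
the design relies on the validation cohort, not on per-test adjustment, to
control false discoveries.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws a 754 × 2n Ct matrix in which Ct behaves as a
negative log2 abundance: per-miRNA baselines (mean 30 cycles, SD 3.5
across miRNAs), within-group noise of 1 cycle, a per-sample global offset
(SD 0.5 cycles) mimicking extraction efficiency, planted reference miRNAs
(no group effect, SD 0.2 cycles, abundances safely below the detection
limit), and planted differential miRNAs whose log2 fold change f appears
as an additive Ct shift of −f in the event group — so Q~rel~ fold changes
are exactly 2^f in expectation. Wells whose simulated Ct exceeds the
40-cycle limit are emitted as undetermined *before* imputation, so the
imputation rule is genuinely exercised. Clinical covariates are drawn per
group from the means/SDs and prevalences of an elderly ischemic-stroke
cohort stratified by severe multi-vessel stenosis (e.g. HbA1c 5.7 ± 0.7 vs
6.4 ± 1.1 %); strictly positive laboratory values are truncated at
physiologic lower bounds. The default `hemolysis_fraction` is 0 because an
analysed cohort contains only samples that already passed the serum
screen; tests that exercise the QC stage raise it explicitly.

The default planted effect alternates log2 fold changes of +2 and −2
(4-fold up/down), the magnitude regime in which a two-panel discovery
study with ~8–15 samples per group has high per-miRNA power. A
consequence worth knowing: with cycle-scale noise of 1 and a 4-fold shift,
a validation cohort of ~30 per group is close to perfectly separable by
the marker, so the joint logistic model sits near complete separation —
enormous odds ratios with astronomically wide Wald intervals, a maximal
continuous NRI of 2, and an AUC near 1. This mirrors what weakly
regularised logistic models do on strong markers in small cohorts (odds
ratios of order 10^11 with 10-decade confidence intervals are what such
studies print); the package flags separation rather than hiding it.

What the generator does **not** model: panel-specific chemistry or
preamplification bias, batch effects beyond the per-sample offset,
correlated miRNA co-expression, hemolysis actually contaminating the
measured Ct values (only the absorbance flag is drawn), or heavy-tailed
laboratory covariates. Passing tests therefore demonstrate that the
pipeline recovers structure *of the assumed form* — additive group shifts
on the Ct scale with Gaussian noise — not that it is robust to every
artefact of real serum profiling.

## Numerical and design choices

- **Reference pair combination.** The combined Ct of a pair is the
  unweighted mean of the members (geometric mean on the expression scale);
  summing instead would change the ΔCt scale, and the mean is the
  scale-consistent choice.
- **Global-mean normalisation for the reference filter.** The candidate
  fold-change criterion is evaluated on expression normalised by each
  sample's across-miRNA mean Ct, since no reference exists yet at that
  stage. On a 754-miRNA panel a single imputed well perturbs that mean by
  ~1/754 of a cycle, which is negligible.
- **Stepwise discriminant F-to-enter.** With g = 2 groups and p variables
  already entered, F = (n − g − p)(Λ~p~/Λ~p+1~ − 1) on (1, n − g − p)
  degrees of freedom. This makes the first-entry F exactly the squared
  two-sample t statistic, which is the anchor property the tests check.
  Numerically collinear candidates (reciprocal condition number of the
  total scatter below 1e−12) are skipped with a warning, which also
  covers exact duplicates of entered variables.
- **Discriminant scale.** The discriminant stage runs on Q~rel~, the scale
  on which the filter is defined. Wilks' Λ is scale-invariant, so running
  it on standardised Q~rel~ or on ΔCt changes nothing about the selected
  set unless the monotone transform reorders separability; the choice is
  therefore cosmetic for selection but is fixed for reproducibility.
- **Forward logistic entry test.** Likelihood-ratio tests (the common
  stepwise default) with entry level 0.05; final coefficients are reported
  with Wald standard errors, odds ratios Exp(B) and 95% intervals
  exp(B ± 1.96·SE). Complete separation is detected from non-convergence
  or runaway coefficients and flagged; the coefficients are still
  reported, labelled non-convergent.
- **LOOCV protocol.** Coefficients are re-estimated in every fold but the
  covariate set is fixed; re-running selection inside each fold is a
  different (more conservative) estimand and is deliberately not the
  default, because the quantity of interest here is the optimism of the
  *final reported model*. At an exactly balanced null, LOOCV with a 0.5
  threshold is systematically pessimistic (each held-out patient tilts the
  refitted intercept toward the opposite class); users should expect
  below-chance LOOCV accuracy for uninformative covariate sets rather
  than 50%.
- **AUC and its comparison.** The AUC is the Mann–Whitney statistic with
  ties counted as one half; the paired comparison uses the DeLong
  placement-value covariance. For nested models fitted to the same data,
  this test is *conservative* under the null (near-zero rejection rather
  than the nominal 5%) — a known property, verified in the tests — so a
  significant result is trustworthy but a non-significant one is weak
  evidence of no improvement.
- **NRI convention.** The category-free (continuous) NRI is used: any
  probability increase for an event counts +1, any decrease −1, ties 0.
  Threshold-based reclassification counts are informative but define a
  different quantity, so they are reported separately
  (`reclassification_counts()`) and never mixed into the NRI. Asymptotic
  z-tests give the p-values; a seeded bootstrap (2000 resamples by
  default when enabled) is available as a cross-check.
- **Ties and degenerate inputs.** Stability ties break lexicographically
  by set name; constant score vectors give AUC 0.5 with a warning; a
  candidate table with a constant factor or an empty margin is flagged
  unreliable rather than tested.

## Problem sizes in the test-suite and acceptance runs

The shipped checks use discovery cohorts of 15 per group (754 miRNAs, 14
planted markers at |log2FC| = 2, where the filter is expected to recover
at least 90% of the planted set), validation cohorts of 33 per group,
200-replicate stability panels (k = 20, n = 50 per group), 100-seed
forward-logistic recovery runs (n = 200, planted log odds ratio 1.0 on 2
of 15 covariates), and 1000-replicate null-calibration runs for the
selection procedure. These sizes give Monte-Carlo error comfortably below
the asserted margins while keeping a full run under a minute.

## Known limitations

- The stability estimator is validated against its own model assumptions
  (sum-to-zero interactions, Gaussian noise); real panels with correlated
  normaliser candidates will shrink differently.
- Equal-variance t-tests on Q~rel~ operate on a right-skewed scale; with
  equal group sizes the level is close to nominal (the skewness largely
  cancels in the difference), but heavily unbalanced designs should
  prefer the log scale.
- The forward procedures inherit the usual selection biases: entry
  fractions under the null run slightly above the 1 − (1 − α)^m
  independence approximation, and post-selection Wald intervals are not
  selection-adjusted (coverage measured ~92–94% at strong effects).
- No missing-covariate imputation: patients with incomplete laboratory
  data are expected to be excluded upstream, as is standard for this
  design.
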