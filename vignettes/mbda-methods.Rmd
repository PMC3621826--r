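---
title: "Methods: scoring and developing a multi-biomarker disease activity test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and developing a multi-biomarker disease activity test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbda)
```

## The problem

Rheumatoid arthritis (RA) disease activity is conventionally graded with
composite clinical indices such as the DAS28-CRP, which combine a tender
joint count (TJC28), a swollen joint count (SJC28), a patient global
assessment (PGA) and C-reactive protein (CRP). Clinical assessments are
subject to substantial inter-assessor variability. A multi-biomarker disease
activity (MBDA) test replaces the clinician-dependent components with
predictions from serum protein concentrations, yielding an objective integer
score on a 1–100 scale with remission/low/moderate/high categories aligned
to the DAS28-CRP bands.

This package implements both the final scoring algorithm and the
development machinery around it — biomarker prioritization, penalized
component-model training with Curds-and-Whey shrinkage, performance
evaluation, assay quality-control rules, and a comorbidity confounding
analysis — together with a synthetic cohort generator so that every stage
runs and is testable without patient-level data (none is publicly
deposited).

## The scoring model

Twelve analytes enter the score. Eleven (TNF-RI, IL-6, VCAM-1, EGF, VEGF-A,
YKL-40, MMP-1, MMP-3, SAA, leptin, resistin) feed three component models;
CRP enters the combination directly. The pipeline is:

1. **Transform.** Concentrations are raised to the power 0.1
   (`transform_concentration()`), which renders typical right-skewed
   immunoassay marginals approximately normal and bounds the leverage of
   extreme readings.
2. **Component prediction.** Each DAS28-CRP component except CRP is a
   linear model over a subset of the transformed analytes: predicted TJC28
   (PTJC28), predicted SJC28 (PSJC28), predicted PGA (PPGA).
3. **Curds-and-Whey improvement.** The two joint-count predictions are
   multiplied by a 2×2 shrinkage matrix and truncated at zero
   (`curds_whey_improve()`). The truncation precedes the square root taken
   in the next step: joint counts are non-negative and the root must be
   defined. PGA and CRP are excluded from the shrinkage — cross-validation
   during development showed their inclusion impairs performance.
4. **Combination and scaling.** The improved predictions are combined in a
   DAS28-CRP-analogous equation,
   `pre_scale = 0.56·√IPTJC + 0.28·√ISJC + 0.36·ln(CRP+1) + 0.14·PPGA + 0.96`
   (PPGA on the 0–10 scale), then
   `score = clamp(round(pre_scale × 10.53 + 1), 1, 100)`.
5. **Categories.** Remission ≤ 25, low 26–29, moderate 30–44, high ≥ 45;
   these are the images of the DAS28-CRP cutoffs 2.3, 2.7, 4.1 under the
   scaling relation.

### Numerical choices

- **Rounding** is half-away-from-zero, applied once, after scaling. This
  reproduces the published cutoff mapping (2.3→25, 2.7→29, 4.1→44) exactly
  and avoids parity-dependent surprises at halves, which banker's rounding
  (R's `round()`) would introduce.
- **Units.** CRP is carried in mg/L throughout; all other analytes in
  pg/mL. The coefficient file records the expected CRP unit explicitly.
- **PGA scale.** The DAS28-CRP weight 0.014 presumes a 0–100 mm VAS; the
  package stores PGA on 0–10 and multiplies by 10 inside `das28_crp4()`
  (equivalently, the combination weight on PPGA is 0.14). A `pga_scale`
  argument makes the convention explicit at every entry point.
- **Boundary conventions.** DAS28-CRP = 2.3 sits formally between the
  published "< 2.3" remission band and the "≤ 2.7" low band; it is assigned
  to *low* (the remission inequality is strict). The duplicate-well CV rule
  flags strictly above 20%; the ±3 SD control band is inclusive.
- **Missing analytes.** Scoring refuses records missing any panel analyte;
  no imputation is defined for the final test (out-of-curve imputation is a
  study-level QC operation, not a scoring fallback).

### The shipped default coefficients are synthetic

The printed source presents the component equations and the
biomarker-to-component map only as display figures whose numeric content is
not machine-readable, so a transcription cannot be shipped. The default
file `inst/extdata/coefficients_default_synthetic.json` therefore contains
component sub-models and a shrinkage matrix produced by this package's own
CW-LASSO trainer on the "training-like" synthetic preset (seed 20130413),
combined with the *published* constants: the DAS28-CRP combination weights,
scale 10.53, offset 1, bounds 1–100, exponent 0.1. The file is labelled
synthetic in its name and metadata; every coefficient is configuration, and
a laboratory with the true values can drop in its own file
(`load_coefficients()`), leaving the code unchanged.

## Development machinery

### Prioritization

Candidate markers are screened univariately (Pearson and Spearman
correlation against eight clinical measures, overall and within
serostatus/sex/therapy subgroups), with Benjamini–Hochberg control at FDR
20% applied within each endpoint × subgroup × correlation-type family — the
family that matches the per-cell counting that follows. A marker's
univariate rank counts passed cells (Pearson and Spearman counted
separately by default; switchable). Multivariate priorities record order of
entry into forward-stepwise OLS/LASSO/elastic-net models; the multivariate
score sums inverse priorities across models, never-entered markers sharing
a common lowest rank. Combined and grand ranks are inverse-rank sums within
and across studies. Ties use competition ("1224") ranking everywhere, so
inverse-rank sums stay well-defined and order-independent.

BH rejection uses the canonical step-up rule (adjusted p ≤ q). For
continuous p-values the difference from a strict inequality has measure
zero; the inclusive form is the one equivalent to the literal step-up
procedure the test suite's brute-force oracle implements.

### Training

"LASSO with forward stepwise selection" is implemented as the glmnet
penalty-path entry order with OLS refits at each size: one mechanism that
yields both sparse models and the order-of-entry priorities prioritization
needs. Model size is chosen by nested 10-fold cross-validation, folds
stratified by outcome tertile (emulating the development cohort's
enrichment for balanced activity levels), MSE loss by default with held-out
correlation also reported.

The size rule is the **one-standard-error rule**: the smallest size whose
mean held-out loss is within one SE of the minimum. The plain fold-mean
minimum (`rule = "min"`, retained) overselects — on a strong 3-variable
signal at n = 300 it lands outside 3 ± 1 in roughly a quarter of
replicates, while the 1-SE rule recovers exactly 3 essentially always and
picks size ≤ 1 on signal-free data. This is the standard parsimony
correction in penalized regression practice.

The Curds-and-Whey matrix uses the Breiman–Friedman GCV form: with
`r = p/n` and squared canonical correlations `c²ᵢ` between the response
pair and its predictions, `dᵢ = (1−r)(c²ᵢ−r) / ((1−r)²c²ᵢ + r²(1−c²ᵢ))`,
truncated to [0, 1], assembled as `M = T⁻¹ D T` in original coordinates.
The population formula needs unknown true canonical correlations; the GCV
variant is the standard data-only substitute. As `r → 0` the factors tend
to 1 (no shrinkage with infinite data); `c² ≤ r` shrinks fully. Only the
two joint-count predictions enter `M`. The degenerate point `c² = r = 0` is
defined as full shrinkage. The elastic-net mixing parameter defaults to 0.5
(unstated in the source; grid-searchable).

Family comparison (`compare_families()`) uses repeated 70/30 splits shared
across families, measuring held-out Pearson r to DAS28-CRP and AUROC at the
2.67 cutoff and at the study median. Nested CV loss: MSE was chosen as the
default (the source does not state the loss); correlation is reported
alongside.

### Evaluation

AUROC is the Mann–Whitney probability with ties counted ½, computed from
midranks and verified against brute-force pair enumeration. Leave-one-out
cross-validation holds out *patients*, not visits, so multi-visit cohorts
cannot leak within-patient information. Median-threshold AUROC assigns
patients exactly at the median to the low class (documented, switchable).
CRP contribution is reported both as a share of the full score and of the
non-constant portion (score minus the scaled 0.96 constant and offset).

### QC rules

Duplicate wells: two-replicate CV with the n−1 standard deviation
(`|a−b|/(√2·mean)`), flag above 20%, "no signal" when both wells read zero.
Controls: ±3 SD of expected, inclusive. Plate review: ≥ 2 failing controls
for any one analyte (the source says "multiple" without a number; 2 is the
documented, overridable default). Out-of-curve readings are imputed to the
study's in-curve minimum/maximum, which can never leave the observed range.

## The synthetic cohort generator

A single latent disease-activity factor θ drives every observable:

- markers are log-normal, `conc = baseline · exp(loading·θ + ε)`;
- joint counts are beta-binomial over 28 joints with logit-linked mean —
  bounded counts, overdispersed, monotone in θ;
- PGA is a logit-linked 0–10 value; CRP is log-linked;
- DAS28-CRP is *computed* from the generated components, never drawn.

The single-factor structure is the minimal model consistent with the
premise that diverse serum markers track one disease-activity construct.
Baselines, loadings and noise SDs (`default_marker_params()`) were chosen
once to resemble typical serum immunoassay medians and moderate
marker–composite correlations; acute-phase reactants load strongest with
the widest dynamic range, leptin weakly, EGF negatively.

Three presets pin the links so that θ = 0 reproduces the published cohort
medians: `"studyI-like"` (n = 128, median DAS28-CRP ≈ 5.7, high activity),
`"training-like"` (n = 249, three-component latent mixture emulating
enrichment for similar numbers in low/moderate/high), and
`"inform512-like"` (n = 512, median ≈ 3.3, with six null-effect comorbidity
flags at registry prevalences of 0.10–0.44).

What the generator does *not* emulate: multi-factor biology (e.g. adiposity
driving leptin independently of disease activity), assay batch/plate
effects, treatment dynamics, or informative missingness. A green test on
synthetic cohorts therefore establishes that the machinery is correct and
that the qualitative development claims (multi-marker models beat single
markers; shrinkage helps correlated components) hold in a world with the
stated structure — not that the published cohort-specific performance
figures are reproduced. Those figures (mean r = 0.60, AUROC 0.89/0.77,
pilot-imaging correlations, the comorbidity ratio table) depend on
undeposited patient data and are out of reach at desk scale by design.

## Known limitations

- The shipped default component coefficients are synthetic stand-ins (see
  above); scores from the default config are internally consistent but not
  the clinical test's scores.
- Spearman p-values use the large-sample t approximation at n ≥ 10 and the
  exact permutation distribution below that; heavy ties at small n fall
  back to the approximation with a suppressed warning.
- `stepwise_fit()` entry order for LASSO depends on the glmnet lambda grid
  (200 points, ratio 1e-4); near-simultaneous entries can swap order at
  grid resolution.
- The plate-to-plate adjustment assessed in the source has no stated
  method and is not computed; include/exclude decisions driven by
  non-statistical criteria (assay availability, drug interference, biology
  add-backs) are configuration, not computation.
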