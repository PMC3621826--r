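# mbda

Development and scoring toolkit for a multi-biomarker disease activity
(MBDA) test in rheumatoid arthritis.

## What this is

Rheumatoid arthritis activity is usually graded with composite clinical
indices — most commonly the four-variable DAS28-CRP,

```
DAS28-CRP = 0.56·√TJC28 + 0.28·√SJC28 + 0.36·ln(CRP+1) + 0.014·PGA + 0.96
```

(TJC28/SJC28 tender/swollen joint counts, PGA patient global assessment in
mm, CRP in mg/L). These indices depend on clinician assessment and vary
between assessors. An MBDA test replaces the clinician-dependent components
with predictions from 12 serum proteins: 11 analytes (TNF-RI, IL-6, VCAM-1,
EGF, VEGF-A, YKL-40, MMP-1, MMP-3, SAA, leptin, resistin) predict TJC28,
SJC28 and PGA through sparse linear models on power-transformed
concentrations (`x^0.1`); a Curds-and-Whey shrinkage matrix improves the
correlated joint-count predictions; the result is combined with measured
CRP in a DAS28-CRP-analogous equation and mapped to an integer score,

```
MBDA = clamp(round(pre_scale × 10.53 + 1), 1, 100)
```

with categories remission ≤ 25, low 26–29, moderate 30–44, high ≥ 45 —
the images of the DAS28-CRP cutoffs 2.3 / 2.7 / 4.1 under that scaling.

The package is for biostatisticians and test developers: it implements the
final scoring algorithm *and* the machinery used to build such a test —
univariate/multivariate biomarker prioritization with FDR control and
inverse-rank scoring, LASSO forward-stepwise training with nested 10-fold
cross-validation, Breiman–Friedman Curds-and-Whey shrinkage estimation,
AUROC/correlation evaluation with patient-level LOOCV, immunoassay plate QC
rules, a comorbidity confounding analysis, and a latent-factor synthetic
cohort generator so everything runs without patient-level data.

**Note:** the shipped default coefficient file is *synthetic* (trained by
this package on a synthetic cohort); the published component coefficients
are available only as display images and could not be transcribed. All
constants are configuration — see `load_coefficients()`.

## Worked example

```r
library(mbda)

cohort <- generate_cohort(preset_spec("inform512-like", n = 6), seed = 42)
res <- mbda_score(cohort)   # uses the shipped synthetic default coefficients
cbind(round(res[, c("ptjc28","psjc28","ppga","iptjc","isjc","pre_scale")], 2),
      res[, c("score","category")],
      crp_pct = round(100 * res$crp_fraction, 1),
      das28crp4 = round(cohort$das28crp4, 2))
#>  ptjc28 psjc28 ppga iptjc  isjc pre_scale score category crp_pct das28crp4
#>   10.61  11.00 6.28 11.30 10.19      5.41    58     high    14.5      4.55
#>    4.32   3.59 3.15  4.10  3.70      3.44    37 moderate    10.4      2.32
#>    5.60   6.62 3.81  6.42  5.78      3.85    42 moderate     6.7      2.83
#>    5.88   5.00 4.19  5.65  5.09      3.97    43 moderate    11.2      3.21
#>    7.61   8.88 5.74  8.66  7.80      4.93    53     high    14.5      3.24
#>    5.97   3.60 3.45  4.91  4.42      3.99    43 moderate    17.5      4.52
```

`ptjc28/psjc28/ppga` are the biomarker-predicted DAS components,
`iptjc/isjc` the shrinkage-improved joint-count predictions, `pre_scale`
the DAS28-CRP-analogous combination, `score` the integer MBDA value with
its category, and `crp_pct` the percentage of the score contributed by the
CRP term. The last column is the clinical DAS28-CRP computed from the same
synthetic patients for comparison: the score tracks it.

On a larger synthetic registry sample the agreement is quantified the way
the development studies quantified it:

```r
cohort <- generate_cohort(preset_spec("inform512-like", n = 300), seed = 42)
res <- mbda_score(cohort)
ev <- eval_report(res$score, cohort$das28crp4)
#> pearson 0.773  spearman 0.771  auroc(2.67) 0.867  auroc(median) 0.873
crp_contribution(res)$mean
#> 14.5   # mean % of the score from the CRP term

mbda_equivalent_of_das(c(2.3, 2.7, 4.1))
#> 25 29 44   # the published category cutoffs
```

Training your own model and scoring with it:

```r
train <- generate_cohort(preset_spec("training-like"), seed = 7)
model <- train_cw_lasso(train, family = "cw-lasso", seed = 7)
scores <- mbda_score(cohort, model$coefficients)
```

## Command line

Every stage has a CLI subcommand (`exec/mbda`, installed with the package),
all tabular I/O as CSV and configs as JSON:

```sh
mbda synth --preset training-like --seed 7 --out cohort.csv
mbda train --cohort cohort.csv --family cw-lasso --seed 7 --out model.json
mbda score --cohort cohort.csv --coeffs model.json --out scores.csv
mbda evaluate --scores scores.csv --truth cohort.csv --out report.json
mbda prioritize --cohort cohort.csv --endpoints das28crp4,cdai --out ranks.csv
mbda comorbid --cohort cohort.csv --measures crp,das28crp4,mbda --out table.csv
mbda demo --outdir demo/ --seed 5   # end-to-end pipeline
```

Each run writes a `.manifest.json` with the seed, paths and output hashes.

## Documentation

`vignettes/mbda-methods.Rmd` describes the model, every tunable parameter
and numerical convention, what the synthetic generator does and does not
emulate, and the design decisions taken where the source left the design
open.
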