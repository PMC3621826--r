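Package: mbda
Title: Development and Scoring Toolkit for a Multi-Biomarker Disease
    Activity Test in Rheumatoid Arthritis
Version: 0.1.0
Authors@R:
    person("MBDA", "Maintainers", email = "maintainers@mbda.dev",
           role = c("aut", "cre"))
Description: Implements a 12-biomarker multi-biomarker disease activity
    (MBDA) score for rheumatoid arthritis together with the statistical
    machinery used to develop such a score: biomarker prioritization by
    univariate and multivariate ranking, penalized component-model training
    with forward stepwise selection and nested cross-validation,
    Curds-and-Whey multivariate-response shrinkage, performance evaluation
    against DAS28-CRP (correlation and AUROC), immunoassay plate quality
    control rules, comorbidity confounding analysis, and a synthetic cohort
    generator so every stage runs without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
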