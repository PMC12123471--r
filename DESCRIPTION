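Package: fairadmit
Title: Intersectional and Marginal Debiasing for Clinical Admission Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how fairness interventions on clinical risk
    prediction models transfer from marginal patient subgroups (defined by a
    single protected attribute) to intersectional subgroups (defined by joint
    attribute values). Provides a seeded synthetic emergency-department cohort
    generator with a logistic outcome model and plantable interaction bias,
    subgroup collection construction with a prevalence cutoff, fairness
    metrics (binned expected calibration error, subgroup false-negative and
    false-positive rates, balanced accuracy, AUROC/AUPRC), a multicalibration
    boosting postprocessor with replayable updates and audit certificates,
    fairness-oriented multiobjective training of group-reweighted learners
    (nondominated-sorting evolutionary search over per-group sample weights),
    and a paired multi-trial experiment harness with Wilcoxon signed-rank
    tests under Holm-Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ranger,
    pROC,
    withr
Config/testthat/edition: 3
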