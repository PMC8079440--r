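Package: cortexeval
Title: Statistical Evaluation Framework for Regional Cortical Thickness Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating regional cortical thickness measurement
    pipelines at the level of tidy per-region tables (62 Desikan-Killiany-
    Tourville regions). Provides synthetic multi-site cross-sectional,
    three-group longitudinal, and scan-rescan cohort generators with paired
    two-pipeline measurement variants; a Bayesian hierarchical linear
    mixed-effects model fitted per region by a conditionally conjugate Gibbs
    sampler with half-Cauchy variance priors, summarized by the
    between-subject to residual variance ratio; a Monte-Carlo cross-validated
    random-forest age-prediction harness; lifespan regional linear models
    with relative (radar) predicted thickness; baseline-change linear mixed
    models with Tukey diagnostic contrasts and Benjamini-Hochberg false
    discovery rate adjustment; and two-way random-effects average-measures
    intraclass correlation for scan-rescan repeatability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
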