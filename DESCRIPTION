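Package: sustainz
Title: Subtype and Stage Inference for Control-Referenced Atrophy Z-Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Event-based disease-progression modelling for cross-sectional
    cohorts. Regional brain volumes are converted to atrophy-positive
    z-scores against a control-fitted covariate model, a z-score
    event-based subtype-and-stage mixture model is fitted by greedy
    sequence optimisation with expectation-maximisation over subtypes and
    selected by BIC, and inferred disease stage is related to regional
    volumes, connectome edges and clinical scores by permutation-based
    partial Spearman correlation with Benjamini-Hochberg FDR and
    max-statistic family-wise error control. A seeded synthetic cohort
    generator with planted progression sequences, edge effects and
    clinical slopes supports end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
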