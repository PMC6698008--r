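Package: mvdmorph
Title: Digital Morphometry of Microvessel Density with Stereology and
    Survival Analysis for Tumour Cohorts
Version: 0.1.0
Authors@R:
    person("M.", "Verhoeven", email = "m.verhoeven@example.org",
           role = c("aut", "cre"))
Description: Quantifies microvessel density (MVD) on CD31-immunostained
    whole tumour sections as the percentage of chromogen-positive,
    size-filtered pixel clusters within a delineated, exclusion-corrected
    tissue area; estimates tumour-stroma percentage (TSP) by systematic
    point-grid stereology; and provides the accompanying cohort statistics
    (ROC/Youden dichotomization of continuous markers, contingency tests,
    Kaplan-Meier/log-rank, univariate and backward-stepwise Cox regression
    for disease-free survival). Includes synthetic-data generators for
    slide images with exact pixel-level ground truth and for two-stage
    patient cohorts with configurable proportional-hazards structure, so
    that every stage of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    png,
    Rcpp,
    stats,
    survival,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mgcv,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
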