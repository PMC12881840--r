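Package: netorigin
Title: Primary-Site Prediction for Neuroendocrine Tumor Liver Metastases with
    Abstention
Version: 0.1.0
Authors@R:
    person("NET", "Origin Maintainers", email = "netorigin@example.org",
           role = c("aut", "cre"))
Description: Two-step machine-learning pipeline that predicts the primary site
    (pancreas versus small intestine) of neuroendocrine-tumor liver metastases
    from patch embeddings of H&E whole-slide images. A binary patch-level
    classifier (support vector machine or logistic regression) produces signed
    decision scores that are summed per patient; calibrated lower/upper
    thresholds on the summed score define an "uncertain" abstention class that
    protects against misclassifying tumors of other origins. Includes patch
    sampling from polygon annotations, a deterministic toy feature extractor,
    leave-one-out and external evaluation harnesses, a synthetic-cohort
    simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    png
Config/testthat/edition: 3
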