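Package: dlbclsig
Title: Gene Expression Signature Pipeline for Diffuse Large B-Cell Lymphoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify diffuse large B-cell lymphoma (DLBCL) samples
    profiled on a targeted NanoString-style gene panel. Implements
    housekeeping/control-probe count normalization, an elastic-net MYC
    activity classifier with leave-one-out cross-validation, resampling
    consensus clustering with three base algorithms (hierarchical,
    self-organizing map, Gaussian mixture), meta-consensus with naive-Bayes
    extension of unassigned samples, an immune effector-to-checkpoint
    expression ratio, immunohistochemistry decision rules (Hans,
    double-expressor, MYC class, double-hit), and the integration of all
    signatures into six overlap groups with association and survival
    statistics. Includes a synthetic cohort generator with planted
    cell-of-origin, MYC-activity and host-response structure so the whole
    pipeline can be exercised and tested without restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    mclust,
    survival
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
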