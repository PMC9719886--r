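Package: dectrod
Title: Lesion-Node Similarity of Dual-Energy CT Parameters for Predicting
    Axillary Lymph Node Metastasis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative dual-energy CT (DECT) parameter derivations for
    paired breast lesion and axillary lymph node measurements: the spectral
    Hounsfield-unit slope, aorta-normalised iodine/water/effective-Z values,
    and the rate-of-difference (ROD) similarity statistic between the primary
    lesion and the node.  Includes a calibrated synthetic cohort generator
    (latent-Gaussian copula with group-specific lesion-node rank
    correlation), circular-ROI extraction from 2-D parameter maps,
    nonparametric group comparisons, forward logistic modelling with the
    similarity-score transform, and ROC/Youden threshold analysis of the
    markers in the full cohort and the small-node subgroup.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
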