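Package: vertrad
Title: Radiomics and Segmentation Evaluation for Fractured Vertebral Bodies on CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of vertebral compression
    fractures on computed tomography: synthetic vertebra phantoms with
    benign and malignant fracture appearance, volume resampling and
    fixed-bin-number intensity discretisation, maximum-intensity-projection
    preprocessing, segmentation training losses (binary cross-entropy,
    Dice, propagation) and agreement metrics (Dice similarity coefficient,
    cross-sectional-area error, average surface distance), a 280-feature
    IBSI-style radiomics extractor (morphology, local intensity,
    intensity statistics, intensity histogram, grey-level co-occurrence,
    run-length, size-zone and dependence matrices, with
    Laplacian-of-Gaussian filtered variants), a segmentation-robust
    feature-selection cascade (zero-variance filter, standardisation,
    concordance-correlation stability filter, correlation pruning,
    cross-validated LASSO), and the published 12-feature signature for
    predicting fracture malignancy together with ROC, DeLong, Youden and
    exact McNemar diagnostic statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
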