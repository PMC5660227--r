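Package: serumpeaks
Title: Serum MALDI-TOF Profiling, Biomarker Panel Discovery and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for serum MALDI-TOF mass-spectrometry biomarker
    discovery and validation: mzXML/CSV spectrum input, undecimated-wavelet
    denoising, top-hat baseline correction and total-ion-current
    normalization, peak detection and cross-sample peak clustering into a
    sample-by-cluster intensity matrix, Wilcoxon rank-sum marker ranking
    with per-marker AUC, genetic-algorithm panel selection scored by
    SVM leave-one-out cross-validation with a Youden-index objective,
    blind-set evaluation, and a validation layer with empirical ROC
    analysis, Youden-optimal cutoffs, logistic marker combination and
    Kaplan-Meier/log-rank survival comparison. Includes a synthetic-cohort
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    survival,
    jsonlite,
    glmnet,
    mzR,
    xml2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
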