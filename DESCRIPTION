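Package: swerad
Title: Deep-Learning Radiomics for B-Mode Ultrasound and Shear-Wave
    Elastography of Breast Masses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end deep-learning radiomics pipeline for classifying
    breast masses from paired B-mode ultrasound and shear-wave elastography
    (SWE) images. Provides a synthetic phantom cohort generator, lesion-patch
    extraction with segmentation-agreement metrics (Dice), a small
    convolutional neural network trained from scratch whose penultimate
    fully connected layers supply 768 deep radiomic features per modality,
    intraclass-correlation (ICC) reproducibility screening, LASSO rad-score
    signature construction with Youden thresholds, quantitative SWE
    parameters (maximum, mean and ratio elasticity and elastic-modulus
    standard deviation) with the triplicate aggregation rule, and the full
    diagnostic-performance battery: sensitivity/specificity with exact
    confidence intervals, likelihood ratios with interpretation bands,
    DeLong AUC confidence intervals and paired tests, McNemar tests,
    Bonferroni correction and cohort comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    glmnet,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    pROC,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
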