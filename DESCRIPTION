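Package: gliodx
Title: Information-Theoretic Diagnostic Workflows for IDH-Mutant Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the diagnostic value of clinical,
    histologic, immunohistochemical and molecular biomarkers in brain
    tumors. Provides a Monte-Carlo brain-cancer population simulator with
    classifier-based feature-scramble importance, a discrete
    information-theory engine (entropy, mutual information, conditional
    mutual information, percent-of-maximum information, permutation
    significance), unsupervised nuclear segmentation of H&E and DAB
    photomicrographs (color deconvolution with Otsu thresholding and
    watershed, k-means pixel clustering, Cut-Cluster-Classify), a
    stain-colored image-noise robustness assay, per-nucleus morphometric
    feature extraction with kNN density features in PCA space, a
    self-normalizing on-slide-control p53 positivity quantifier with Lin's
    concordance correlation, and a composite 1p/19q-codeletion predictor
    feeding a molecular-test triage rule. Seeded synthetic-data generators
    produce every input the pipeline needs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    randomForest,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
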