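Package: slidewise
Title: Patch-to-Slide Aggregation for Weakly Supervised Whole-Slide
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A patch-to-slide analysis pipeline for histopathology
    whole-slide images (WSIs), built around frozen-section thyroid
    classification tasks: tile extraction with blank filtering and
    region-of-interest (ROI) coverage bookkeeping, Vahadane-style stain
    normalization by sparse non-negative stain separation, four patch
    labeling strategies (supervised by ROI coverage, weakly supervised
    by slide label, ROI-only, and whole-slide), a small trainable patch
    classifier, slide-level feature construction by Patch Likelihood
    Histogram (PLH) and TF-IDF bag-of-words aggregation, correlation
    filtering and cross-validated LASSO feature selection, slide-level
    logistic regression / SVM / random forest classifiers, a
    multiple-instance bag-pooling head for per-patch feature bags, and
    ROC/AUC evaluation with slide probability maps.  A synthetic-data
    module generates tiled slides, patch-likelihood corpora, and
    feature bags with planted structure so the whole pipeline is
    testable without access to clinical slides.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    e1071,
    randomForest,
    jsonlite,
    png,
    withr,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
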