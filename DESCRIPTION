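Package: gaitssc
Title: Stable Sparse Classification of Cognitive Status from Trunk-Accelerometer Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting cognitive status from wearable-sensor gait
    recordings. Implements trunk-accelerometer signal conditioning (axis
    alignment, dynamic tilt correction, zero-lag low-pass filtering), gait
    event detection from the vertical acceleration via Gaussian
    continuous-wavelet derivatives, extraction of sixteen spatio-temporal
    gait features per walking task plus dual-task costs, a Mahalanobis-distance
    summary cognitive index with k-means group definition, and the Stable
    Sparse Classifiers procedure: resampled elastic-net stability selection
    followed by ROC/AUC validation, with permutation two-way ANOVA and
    SVM/regularized-LDA baselines for comparison. A synthetic-cohort
    generator with ground-truth gait events makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    pracma,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC
Config/testthat/edition: 3
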