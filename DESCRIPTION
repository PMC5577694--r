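Package: mammotex
Title: Texture Features of Mammograms and Prediction of Mammography Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting mammography failure ("masking",
    an invasive tumor visible on ultrasound but unsuspicious on the
    mammogram) from automatically generated mammogram texture features.
    Computes 363 named texture features in seven families (moment-based,
    histogram, Markovian/co-occurrence, regional, run-length, Fourier,
    wavelet) inside a breast-region mask, prunes them by skewness and
    rank-ordered Spearman correlation, predicts percentage mammographic
    density (PMD) with univariate selection, lasso, component-wise gradient
    boosting and random forest (tuning parameter chosen by inner 10-fold
    cross-validation or out-of-bag error), substitutes the predicted PMD
    into a clinical logistic risk model for masking, and evaluates the
    competing risk models by repeated double (nested) cross-validation with
    Brier-type MSE, AUC, continuous net reclassification improvement and
    discovery rates. A synthetic-data module generates textured images with
    controllable percent density and cohorts with realistic covariate
    distributions so the whole pipeline runs without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    glmnet,
    png,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
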