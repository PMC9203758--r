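Package: triopred
Title: Joint Trait and Disease Risk Prediction from Polygenic Scores and Family History
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A latent factor model that partitions the heritability of a
    complex trait or disease into a component captured by a polygenic risk
    score and an under-captured component inferable from parental phenotypes
    or parental disease history. Provides estimation of the under-captured
    heritability from published summary statistics (variance explained for
    continuous traits, odds ratios for binary diseases), conditional
    multivariate-normal joint predictors combining a child's polygenic score
    with parental trait measures, an importance-sampling posterior-liability
    predictor combining a polygenic score with parental disease history under
    a logit-link liability model, a parent-child trio simulator matching the
    model's covariance structure, and evaluation metrics (variance explained,
    RMSE, AUROC, AUPRC, DeLong's paired test, net reclassification
    improvement, integrated discrimination improvement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
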