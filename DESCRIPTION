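Package: autoassl
Title: Self-Training and Active-Learning Lasso Logistic Regression for
    Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Combines pool-based active learning (uncertainty sampling) and
    self-training semi-supervised learning around an L1-penalized logistic
    regression classifier for gene-expression data with few labeled samples.
    An expanding probability-window schedule selects high-confidence samples
    for pseudo-labeling and decision-boundary samples for uncertainty
    handling, and a pseudo-label update mechanism routes samples whose
    predicted class flips under later models either back to the unlabeled
    pool or to in-place label revision. Includes a correlated-Gaussian
    gene-expression simulator with sparse causal support, six comparison
    training variants, and classification (accuracy, ROC, AUC) and
    gene-selection (support recovery) evaluation with replicate-averaged
    experiment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
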