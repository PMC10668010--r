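Package: pticlass
Title: PMI/TF-IDF Topic Classification for Biomedical Literature Triage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interpretable topic classification of title+abstract records,
    built around the PMI/TF-IDF classifier (PTIC): per-class sums of
    tf-idf weighted normalized pointwise mutual information, decided by
    argmax. Includes a gradient-trained extension with per-word weights
    composed through a sigmoid (logit PTIC) trainable with cross-entropy
    or focal loss, a multinomial Naive Bayes baseline, evaluation tools
    (confusion-matrix metrics, ROC/AUC, threshold moving, class-imbalance
    projections), a seeded synthetic corpus generator with controllable
    class imbalance and label-flip noise, and a benchmark driver for
    dictionary-size, minimum-count, imbalance and label-noise experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
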