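Package: pgmelm
Title: Self-Adaptive Multilayer Extreme Learning Machines for Imbalanced
    Biomedical Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies small, high-dimensional, class-imbalanced biomedical
    feature tables with PGM-ELM: principal-component feature reduction under
    a cumulative-contribution threshold, minority-class oversampling by a
    dynamically repeated generative adversarial network (GAN), and a
    multilayer extreme learning machine whose hidden-node and hidden-layer
    counts adapt to the change in imbalance ratio induced by balancing.
    Includes the standard comparison methods (weighted ELM, SMOTE plus ELM,
    hierarchical ELM), imbalance-aware evaluation metrics (G-mean, F-measure,
    ROC/AUC), kernel maximum mean discrepancy for generated-sample quality,
    Friedman/Nemenyi rank statistics for classifier comparison over multiple
    datasets, and a seeded generator of imbalanced synthetic feature tables
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
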