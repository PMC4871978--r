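Package: wkelm
Title: Wavelet-Kernel Extreme Learning Machines with Genetic-Algorithm
    Hyperparameter Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form training of kernel Extreme Learning Machine (ELM)
    classifiers for two-class biomedical voice-measurement tables, built
    around a translation-invariant wavelet kernel whose three parameters
    and hidden-neuron count are tuned by a binary-encoded genetic
    algorithm.  Includes the classic random-feature ELM baseline,
    diagnostic-test evaluation (sensitivity, specificity, overall
    accuracy, ROC curves and AUC), repeated-holdout and k-fold
    protocols, a reader for the UCI Parkinsons voice CSV dialect, and a
    seeded generator of synthetic dysphonia feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
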