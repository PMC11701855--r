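Package: decorrens
Title: Decorrelative Ensembles for Robust ECG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Training, attack, and evaluation stack for deep-ensemble
    electrocardiogram (ECG) classifiers that are robust to adversarial
    perturbations and aware of their own uncertainty. Implements linear
    feature-decorrelation training with random projections, Fourier-domain
    input partitioning across ensemble members, white-box projected gradient
    descent (PGD) and smooth adversarial perturbation (SAP) attacks for 1D
    signals, ensemble adversarial training and DVERGE-style feature
    distillation, mutual-information uncertainty estimation with min/max
    normalization, and the correct-certain / incorrect-uncertain / deferral
    evaluation metrics. Ships a seedable generator of ECG-like labeled
    signals and a compact trainable 1D convolutional classifier so the whole
    pipeline runs end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
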