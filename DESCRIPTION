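Package: usvnet
Title: Segmentation, Acoustic Features and Neural-Network Classification of Mouse Ultrasonic Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mouse ultrasonic vocalizations (USVs) from
    300 kHz audio: spectrogram-based call segmentation (percentile
    sparsification, energy, spectral-continuity and frequency criteria with
    gap merging), curvature-flow denoising, fundamental-frequency tracking
    and a formula-defined acoustic feature suite (Wiener entropy, spectral
    purity, spectral salience, tremolo, spectral moments and marginals), a
    family of convolutional and dense neural-network classifiers for
    emitter sex, strain and individual identity with Adam training,
    batch normalization, dropout and on-the-fly augmentation, ridge and
    support-vector baselines, leave-one-subject-out cross-validation, and
    interpretation analyses (activation sparsity, deconvolution, PCA and
    t-SNE embeddings with nearest-neighbour decoding and density maps).
    Includes a synthetic-USV generator with class-conditioned call
    parameter distributions so the full pipeline can be exercised against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    e1071,
    EBImage,
    MASS,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
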