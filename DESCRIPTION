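Package: ecgvae
Title: Unsupervised ECG Feature Learning with a 1-D Convolutional
    Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised representation learning for single-lead (lead II)
    electrocardiogram waveforms using a one-dimensional convolutional
    variational autoencoder. Provides a synthetic PQRST rhythm generator
    with controllable heart rate, RR-interval variability and artifacts;
    a preprocessing chain (Butterworth baseline removal, resampling to
    250 Hz, z-score normalization, segmentation into 2,048-sample
    windows); a residual convolutional encoder to a 60-dimensional
    diagonal Gaussian latent with a symmetric transposed-convolution
    decoder trained by ELBO minimization with patience-based early
    stopping; reconstruction-error anomaly scoring with F1-maximizing
    grid threshold selection; latent-space exploration and 2-D embedding
    (t-SNE, LLE); and two transfer-learning protocols (gradient-boosted
    classification of latent features, and encoder-weight reuse for a
    supervised rhythm classifier).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
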