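Package: dpae
Title: Dual-Pathway Autoencoder Denoising of EEG Segments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removal of ocular (EOG) and myogenic (EMG) artifacts from
    single-channel EEG segments with a dual-pathway denoising autoencoder:
    two parallel encoder pathways with different width-shrinkage ratios, a
    symmetric fusion block, residual connections and batch normalization,
    with multilayer-perceptron, 1-D convolutional and GRU backbones.
    Includes band-limited surrogate generators for clean EEG, EOG and EMG
    segments, SNR-controlled linear artifact mixing, supervised training
    with Adam, relative root-mean-square error (temporal and spectral via
    Welch power spectral density) and Pearson correlation evaluation at
    each SNR level, channel-by-channel multichannel denoising, and an
    ablation/benchmark experiment harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
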