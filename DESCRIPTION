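Package: mhcgt
Title: Multi-Head Transformer Classification of Multi-Temporal Hyperspectral Grassland Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species classification of multi-temporal hyperspectral reflectance
    spectra of grassland vegetation with a transformer encoder (sinusoidal
    positional encoding, multi-head scaled dot-product self-attention,
    convolutional feed-forward blocks and an MLP head), trained natively in R
    with Adam, early stopping and best-checkpoint selection.  Includes a
    parametric simulator of multi-temporal vegetation reflectance (chlorophyll
    absorption wells, green peak, red edge, NIR plateau with phenological
    phase modulation), Savitzky-Golay spectral smoothing, stratified repeated
    train/test splitting, confusion-matrix and per-phase accuracy reporting,
    a training-fraction ablation harness, and baseline comparisons (1-D CNN,
    LSTM, linear SVM, random forest, decision tree).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
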