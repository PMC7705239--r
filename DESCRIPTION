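Package: mnlnet
Title: Multi-Scale Non-Local 1D Convolutional Networks for EEG Seizure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects epileptic seizure activity in single-channel EEG segments
    with a 1D convolutional neural network augmented by two multi-scale
    feature layers: a signal pooling layer that runs parallel max-pooling
    branches at window sizes 1, 2 and 4 and re-aligns them by asymmetric
    zero padding, and a non-local attention layer that reweights the pooled
    feature channels by their softmax-normalized pairwise similarities.
    Includes readers for Bonn-style ASCII records and UCI-style segment CSV
    files, a surrogate EEG generator with a controllable class-separability
    knob, z-score preprocessing and chunk segmentation, stratified k-fold
    cross-validation with Adam optimisation and plateau learning-rate decay,
    and confusion-matrix metrics (accuracy, precision, sensitivity,
    specificity, F1) with macro averaging for multi-class tasks. The network,
    including backpropagation, is implemented directly on base R matrix
    algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
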