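---
title: "Multi-scale non-local networks for EEG seizure detection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale non-local networks for EEG seizure detection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnlnet)
```

## The problem

Visual review of scalp EEG for epileptic activity is slow and
reader-dependent. This package implements an automatic classifier for
single-channel EEG *segments*: short fixed-length windows (178 samples at
173.61 Hz, about one second) that are labeled by recording condition. The
five canonical conditions follow the classic five-set corpus layout: sets
A and B are surface recordings of healthy volunteers (eyes open/closed),
C and D are intracranial recordings from epilepsy patients between
seizures (interictal), and E contains seizure (ictal) activity.
Classification *tasks* merge these sets into classes with a small scheme
grammar — `"A-E"` is healthy-versus-seizure, `"ABCD-E"` is
everything-versus-seizure, `"A-B-C-D-E"` keeps all five apart.

## The model

The classifier is a 1D convolutional network whose distinguishing parts
are two multi-scale layers inserted between the convolutional feature
extractor and the fully connected head.

**Backbone.** Each segment is z-scored (`(s - mu)/theta`, population SD)
and passed through three convolution stages. With 178-sample input the
geometry is:

| stage | operation | output |
|---|---|---|
| 1 | conv, 20 filters, kernel 40, stride 1, length-preserving padding; batch norm; ReLU | 178 × 20 |
|   | max pool 2, stride 2 | 89 × 20 |
| 2 | conv, 40 filters, kernel 20, stride 2, no padding; batch norm; ReLU | 35 × 40 |
|   | max pool 2, stride 2 | 17 × 40 |
| 3 | conv, 80 filters, kernel 10, stride 2, no padding; batch norm; ReLU | 4 × 80 |

The first convolution must use "same" padding: that is the only reading
under which a kernel of 40 maps 178 to 178 at stride 1. The later
convolutions are unpadded with floor division; both choices are asserted
by `shape_trace()` rather than assumed.

**Signal pooling layer.** Three parallel max-pooling branches with
windows 1, 2 and 4 (stride 1) run over the 4 × 80 feature map. A branch
with window `p` shortens the map to `o = w - p + 1`; it is padded back to
length `w` with `l = ceiling((w - o)/4)` leading and `r = w - o - l`
trailing zeros, so the three branches align and concatenate to `w × 3c`.
A trainable pointwise (window-1) convolution then reduces `3c` back to
`c` channels. The reduction step is a design decision: the literal
concatenation has `3c` channels, while the published layer table reports
the layer as shape-preserving (4 × 80); a pointwise reduction is the
smallest trainable operation that reconciles the two, and
`pooling_reduce = "none"` keeps the literal concatenation available.

**Multi-scale non-local layer.** Three independent pointwise convolutions
embed the pooled map `x_ms` (w × c) into `phi`, `delta`, `rho` (each
w × c_hat). The raw similarity is the channel affinity

  R = phi^T delta  (c_hat × c_hat),

row-softmaxed into attention weights `R_hat`; the attended features are
`rho %*% t(R_hat)` (w × c_hat), mapped back to `c` channels by an inner
pointwise convolution, added to `x_ms` (residual), and passed through an
outer pointwise convolution. Decisions worth stating:

* *Channel vs position attention.* `phi^T delta` correlates embedding
  channels, which after the pooling layer carry the different scales —
  consistent with the stated aim of correlating multi-scale features. The
  conventional non-local orientation (position-by-position, w × w) is
  implemented behind `affinity = "position"` for comparison; channel
  affinity is the default.
* *Shape of the attended product.* `R_hat × rho^T` is c_hat × w, but the
  layer's declared output is w × c_hat; the product is computed as
  `rho %*% t(R_hat)` (its transpose) so the declared shape holds.
* *Two fusion convolutions.* The final fusion is read as two distinct
  trainable pointwise convolutions (c_hat → c before the residual, c → c
  after); shared weights would be dimensionally impossible when
  c_hat ≠ c.
* *Embedding width.* `c_hat` defaults to `c/2` (40 here), the common
  convention in the non-local-attention literature; it is configurable.
* *Softmax axis.* Row-wise, so each output channel's weights over source
  channels sum to 1.

**Head.** Flatten (320), FC 64 + ReLU, FC 32 + ReLU, FC `n_classes` +
softmax. The head width follows the active task's class count (2–5); the
published layer table prints a single row with two different experiment's
values, which is read accordingly.

## Training protocol

`train_config()` captures the protocol: cross-entropy loss, Adam with
initial learning rate 5e-4, mini-batches of 100, and a
reduce-on-plateau schedule that multiplies the rate by 0.1 whenever
validation accuracy has not improved for 10 epochs (the schedule then
re-arms). The checkpoint with the highest validation accuracy is
retained. The maximum epoch count (default 100) and an early stop when
the learning rate falls below 1e-7 are both configurable — the source
protocol does not state a horizon.

The evaluation protocol is stratified k-fold cross-validation (k = 10 by
default): each class is randomly divided into k equal folds; each fold in
turn is held out for testing while the rest trains a fresh model. Because
checkpointing needs validation data that the protocol description does
not provide, a stratified 10% slice of each fold's *training* data is
held out for the schedule and checkpoint selection — any other reading
would leak test data. Folds are drawn over segments, following the
protocol text literally; chunks of one record can therefore span train
and test, which likely flatters accuracy relative to record-disjoint
folding. The mapping is deterministic given the seed, and per-fold
training seeds are derived from it, so a full `cross_validate()` run is
bit-reproducible.

Metrics are accuracy, precision, sensitivity, specificity and F1 from
one-vs-rest confusion counts, with the seizure class (the group that is
exactly set E) as "abnormal"/positive. For three or more classes the four
non-accuracy metrics are macro-averaged (unweighted one-vs-rest mean);
the source tables do not state their multi-class averaging rule and are
not reproducible under any standard convention, so the most common one is
used and per-class values are attached for recomputation under any other
rule. Ratios with zero denominators score 0 with a warning rather than
aborting a fold.

## Implementation notes

No deep-learning framework is used: forward passes, exact analytic
backpropagation (including through the batch-norm statistics, the pooling
argmax and the attention softmax), Adam, and Glorot-uniform
initialization are implemented directly on base R matrix algebra.
Convolutions are one BLAS matrix product per layer via an im2col
transform whose gather/scatter geometry is precomputed and cached; the
overlapping-window scatter in the backward pass is a sparse cross
product. The backward pass is verified against central finite differences
in the test suite (worst relative error ~1e-7 on sampled weights; conv
biases that feed batch norm have exactly-zero gradients and are excluded,
since finite differences only see rounding noise there).

Numerical conventions: population (divide-by-n) standard deviation in the
z-score, matching a fixed choice rather than a stated one; softmax rows
are max-shifted for overflow safety; max-pooling ties resolve to the
earliest window position; batch norm uses epsilon 1e-5 and running-stat
momentum 0.1 for inference. The z-score is applied per segment, with each
segment's own statistics: the network input is the segment, and
per-segment normalization keeps the pipeline order-independent. (The
source prose describes the z-score as mapping to the [0, 1] range, which
contradicts its own formula — z-scores are unbounded; the formula is
implemented.)

Segmentation divides each 4097-sample record into 23 contiguous chunks of
`floor(4097/23) = 178` samples and discards the 3-sample tail — the only
rule consistent with both the published segment count (23 × 100 × 5 =
11,500) and the 178-sample segment layout.

## The surrogate generator

`generate_bonn_like()` emulates the corpus layout (five sets × 100
records × 4097 samples at 173.61 Hz) with standard EEG phenomenology: a
1/f-shaped Gaussian background everywhere; a ~10 Hz alpha rhythm on A and
B (stronger on B, eyes closed); sparse biphasic transients on C and D
(denser and larger on D); and a harmonic-rich ~3 Hz spike-and-wave train
with a slow amplitude envelope on E. One `separability` knob scales every
set-specific component: at 0 all five sets collapse to the identical 1/f
distribution (the null), at 3 the classes are easily separable. The
default is 1, a moderate contrast. A per-set, per-record seed sequence
derived from the global seed makes any subset reproducible independently
of generation order.

What passing tests on this surrogate do and do not show: they verify the
pipeline end to end — segmentation, normalization, folding, optimisation,
checkpointing, scoring — and that the network can exploit spectral class
structure. They do not certify performance on real EEG: the surrogate has
no artifacts, no inter-subject variability, no amplitude statistics
matched to clinical data, and its class differences are cleaner than real
interictal/ictal morphology. Published headline accuracies can only be
checked against the real corpus (`scripts/reproduce_uci.R` reruns the
full protocol given the downloaded segment CSV).

## Problem sizes used in tests and the acceptance script

The packaged checks run a deliberately scaled-down study: 40 records per
set (920 segments per class), scheme A-E, 3 folds, 20 epochs — chosen as
a desk-scale size that still trains to convergence on separable data.
Chance level for the null (separability 0) check is 0.5 with a ±0.05
band, comfortably wider than the binomial noise of a ~600-segment test
fold. The reproducibility check reruns a 2-fold, 2-epoch configuration
twice and compares report files byte for byte.

## Known limitations

* Single-channel only; no montages, no EDF/BDF readers, no filtering or
  artifact rejection (none are part of the protocol).
* Segment-level folding is the default (see above); `make_folds()` on
  record identifiers can be used for subject-disjoint splits, but the
  packaged protocol follows the published one.
* The channel-affinity attention is the literal reading of the published
  equations; whether the authors intended position attention cannot be
  settled from the text, so both are implemented.
* Training is CPU-bound R; the full 10-fold, 100-epoch protocol on the
  real corpus is an overnight run, not a test-suite run.
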