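---
title: "Detecting atrial fibrillation in single-lead ECG with a 1D CNN: models and methods"
author: "afdetect1d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atrial fibrillation in single-lead ECG with a 1D CNN: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afdetect1d)
```

## The problem

Atrial fibrillation (AF) shows up in a single-lead ECG as three coupled
signatures: the R-R intervals (times between successive heartbeats) become
irregular, the P wave that normally precedes each QRS complex disappears, and
the baseline carries a low-amplitude fibrillatory oscillation at roughly
4–8 Hz. `afdetect1d` classifies 300 Hz single-lead recordings into four
rhythm classes — AF, Normal, Noisy, Other — with an end-to-end
one-dimensional convolutional network: the raw time series goes in, class
probabilities come out, and no hand-crafted features or 2D spectrogram
conversion sit in between.

The recordings the pipeline targets (the PhysioNet/CinC Challenge 2017
training-set layout) are variable in length, from 9 s to 61 s, which a fixed
CNN input cannot accept directly. The package therefore consists of two
jointly designed parts: a length-normalization stage that turns every
recording into one or more fixed-length labeled segments, and the
convolutional classifier with its training, evaluation, and hyperparameter
search machinery.

## Length normalization

The segment length is not a free constant. `compute_length_threshold()` bins
the recording durations into 1-s histogram bins and takes the left edge of
the modal bin; on the Challenge length distribution the mode sits at 30 s,
giving 9000 samples at 300 Hz. The bin width of 1 s is the resolution at
which the duration histogram is meaningful for this dataset; a tie between
equally full bins resolves to the smaller duration (shorter segments lose
less data to tiling), a case constructed in the tests but absent from the
real distribution.

Each recording then takes one of three branches in `normalize_dataset()`:

* **Equal** to the threshold: kept unchanged.
* **Longer**: chopped by `segment_long()` into windows of exactly the
  threshold length at 50% overlap, i.e. stride `T/2`. When the last
  stride-aligned window stops short of the end of the recording, one
  additional end-anchored window covering the final `T` samples is appended,
  so every sample of the recording is covered. This end-anchor is what makes
  an 18,600-sample (61 s) recording yield four segments (starts 0, 4500,
  9000, 9600) rather than three: the stride rule alone leaves the last 600
  samples uncovered, and dropping them would discard signal from exactly the
  recordings that carry the most of it.
* **Shorter**: periodically tiled by `tile_short()` — the recording is
  repeated end-to-end and truncated to exactly `T` samples, so
  `output[i] == input[i mod len]`. The alternative reading of
  "concatenate the recording with the same label" — splicing in a different
  recording of the same class — would blend unrelated hearts into one
  segment; self-tiling preserves the rhythm statistics the classifier is
  supposed to learn and is what the normalization pseudocode's
  "copy the recording" step describes.

Every segment inherits its source recording's label, and segment order is
deterministic (input order, then window order), so the whole stage is a pure
function of its inputs.

## The network

The reference architecture (`make_variant("Proposed-1")`) stacks ten
convolutional blocks. Each block is a valid (no-padding, stride-1)
convolution with kernel 5, a ReLU, and a size-2/stride-2 pooling layer;
block 1 additionally carries a batch-normalization layer after its ReLU, and
the final block has no pooling. Filters start at 32 and double every two
blocks (32, 32, 64, 64, …, 512, 512). Dropout 0.5 sits after blocks 6, 8
and 9 and after the first dense layer. The head flattens the final
9 × 512 feature map into 4608 units, passes dense layers of 128 and 32
units, and ends in a 4-way softmax. `make_variant("Proposed-2")` swaps every
max pooling for average pooling and is otherwise identical; the other five
named variants (`All-BN`, `No-BN`, `Maxpooling`, `Max-Average`,
`Extra-Average`) move or add batch-normalization and pooling layers to
isolate those components' contributions. The `Max-Average` variant is
defined here as the reference stack plus one average pooling before the
flatten — the construction that "combines" the two pooling types while
staying consistent with its printed parameter count.

Two conventions are forced by the arithmetic of the published layer table
and are therefore fixed, not configurable: convolutions are valid
(9000 input and kernel 5 give 8996, not 9000), and pooling uses floor
division on odd lengths (273 pools to 136, feeding the 132-length
convolution).

### The analytic calculator

`compute_layer_summaries()` derives every layer's output length, channel
count and parameter count without instantiating a network:
`out = in − kernel + 1` for convolutions, `floor(in / 2)` for pooling,
`kernel · in_ch · filters + filters` convolution parameters,
`in · out + out` dense parameters. Batch normalization carries four numbers
per channel — trainable scale and shift, non-trainable running mean and
variance — so its `params_total` is `4c` while `params_trainable` is `2c`.
Summing the ten-block stack gives 3,212,804 parameters in total, of which
3,212,740 are trainable (the 64 non-trainable statistics of the single
32-channel BN layer account for the difference). `count_trainable()` is the
package's oracle for network size: `build_network()` checks its own
parameter tensors against it at construction time and refuses to return a
model that disagrees, and the grid-search report always quotes the analytic
number rather than the engine's.

Deep stacks can run out of samples: with pooling in every block but the
last, eleven blocks with kernel 5 or 7 leave a convolution with fewer
samples than its kernel. `check_feasible()` walks the shape chain and flags
such combinations; the grid search reports them as `N/A` rather than
dropping them.

For layer counts other than ten (the 8-, 9- and 11-block grid
architectures), the same schedule is extrapolated: filters start at 32 and
double every two blocks, pooling in every block but the last, dropout after
blocks `n−4`, `n−2`, `n−1`. The published record underdetermines those
stacks' exact composition, so their parameter totals are not claimed to
match any external reference — the package treats them as its own canonical
family, and only the ten-block totals are asserted exactly.

### The training engine

No deep-learning framework is part of the package's dependency set; the
backing engine is implemented in C++ (RcppArmadillo) inside the package:
im2col + GEMM valid convolution, batch normalization, max/average pooling,
inverted dropout, dense layers, softmax with categorical cross-entropy, and
bias-corrected Adam. Arithmetic is single-precision (the standard training
precision for CNNs); a double-precision instantiation of the same templated
code exists solely so the test suite can verify the analytic gradients
against central finite differences, which it does to about 1e-7 relative
error. One caveat the tests document: with zero-initialized biases, a ReLU
whose entire input window was clipped sits exactly on its kink, where a
two-sided difference quotient measures a mixture of the one-sided slopes;
the gradient tests therefore jitter all parameters before differencing.

Numerical conventions, all of which the tests pin down:

* Weights are Glorot-uniform initialized from a seeded generator; two
  builds with the same seed produce identical models (the engine is
  single-threaded, so this is exact, not approximate).
* Cross-entropy is the per-sample sum over the four class terms, averaged
  over the minibatch — the only reading on which the loss of a perfect
  prediction is zero per sample regardless of batch size. Predicted
  probabilities are clipped at 1e-12 before the logarithm.
* Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-8 with bias-corrected moments —
  the optimizer's standard constants, which the source method defers to its
  reference implementation.
* Batch normalization uses population (biased) batch variance, ε = 1e-3,
  and running-statistic momentum 0.9; inference uses the running statistics,
  and dropout is inference-disabled, so `predict()` is deterministic for a
  fixed trained model.
* Max-pooling ties keep the earlier sample; argmax ties in prediction
  resolve to the lowest class index in the fixed order AF, Normal, Noisy,
  Other.

The default epoch budget is 50 — the published record never states one —
with optional early stopping on the monitored loss (`patience`) and an
optional convergence shortcut (`target_train_acc`) that stops once training
accuracy reaches a target, useful on separable synthetic data where further
epochs only burn time.

## Evaluation

Metrics follow the four-class confusion matrix with predictions in rows and
ground truth in columns. Per-class scores come from the one-vs-rest
collapse to a 2 × 2 table; precision, recall, accuracy and F1 are reported
in percent, and the headline score is the unweighted mean of the four
per-class F1 values (`average_f1`), with the three-class mean over AF,
Normal and Other also reported for cross-method comparisons. Two
conventions are the package's own choices where the source is silent: a
zero denominator (a class never predicted, or absent from the truth) yields
a 0 score with a warning rather than `NaN`, the conservative choice for
model comparison; and the fold spread σ in cross-validated reports is the
population standard deviation of the fold-level average F1
(`sd_type = "sample"` switches to the `n−1` divisor).

Cross-validation is stratified: each fold holds every class's share of
segments to within one segment. Stratification is at segment level by
default, which matches how the pre-processed Challenge segments were
cross-validated but lets sibling segments of one long recording appear on
both sides of the train/test boundary; `cross_validate(grouped = TRUE)`
instead assigns whole source recordings to folds, which is the right mode
when leakage matters more than comparability.

## Hyperparameter grid search

The search space is the Cartesian product of layer counts {8, 9, 10, 11},
kernel sizes {3, 5, 7}, batch sizes {30, 50, 70, 90, 110} and learning
rates {5e-5, 1e-4, 5e-4, 1e-3, 5e-3} — 300 points, each scored by
stratified K-fold cross-validation (K = 5 by default, since each point's
score is a fold mean with a spread). Infeasible (layers, kernel)
combinations stay in the report flagged `N/A`. The best point is the pure
argmax of mean average-F1 among feasible points; ties (not encountered in
practice, but defined) break toward fewer parameters, then lower learning
rate. `refine_batch_search()` re-evaluates the winner at extra batch sizes,
deduplicating against already-evaluated points. A full-fidelity sweep is a
long computation; the `--smoke` CLI mode and the `epochs` argument exist so
the machinery itself can be exercised at desk scale.

## The synthetic generator

`gen_recording()` builds ECG-like signals from a Gaussian-bump template —
P, Q, R, S, T bumps with per-class amplitudes and widths — rather than a
biophysical model. That choice is deliberate: the template carries exactly
the class-defining structure the detection problem names, it is fast enough
to regenerate every test run, and nothing in the pipeline depends on
morphological realism beyond those signatures.

* **Normal**: regular R-R intervals (Gaussian jitter, coefficient of
  variation ≈ 0.02 around a 0.8 s sinus cycle) with a 0.15 mV P wave before
  every QRS.
* **AF**: gamma-distributed R-R intervals with shape 9 (CV = 1/3, well
  above any regular rhythm), no P wave, and a 0.2 mV baseline sinusoid at a
  per-recording frequency drawn from 4–8 Hz. The mean cycle is 0.6 s — the
  rapid ventricular response typical of untreated AF — so rate, rhythm and
  baseline all discriminate, which is what makes the class structure
  recoverable by a network trained for tens of epochs on a few hundred
  segments.
* **Other**: regular rhythm but altered ventricular morphology — QRS
  widened 2.5×, reduced R amplitude, inverted T wave.
* **Noisy**: a faint beat template buried in white noise and slow drift at
  a signal-to-noise ratio well below 0 dB, since the class is defined by
  being unreadable, not by any rhythm.

All classes share a small measurement noise and a slow respiratory drift.
Durations come from a mixture — a point mass at 30 s with weight 0.7,
otherwise uniform on 9–61 s — so the duration histogram of a generated
cohort has its modal bin at 30 s and the threshold selection reproduces
9000 samples on synthetic data. Generation is bitwise reproducible: every
recording's stream derives from the master seed.

The generator's contract is checked, not assumed: tests verify the AF
R-R coefficient of variation exceeds 0.15, the P-window energy is far below
Normal's, the 4–8 Hz band power exceeds Normal's, and — the invariant the
end-to-end test rests on — that a linear classifier on two hand-crafted
features (R-R CV and P-window energy) separates synthetic AF from Normal
with at least 95% accuracy. The feature extractor skips P-window
measurement on cycles shorter than 0.55 s, where the preceding T wave
intrudes into the window — the same confound that makes P-wave assessment
hard in real rapid AF.

What passing the synthetic tests does **not** show: the generator does not
reproduce real ECG spectra, electrode artifacts, the heterogeneity of the
real "Other" class (a single altered morphology stands in for "anything
classifiable that is neither AF nor Normal"), or the real class imbalance
unless asked. End-to-end recovery of the synthetic classes demonstrates
that the pipeline — normalization, network, optimizer, evaluation — is
internally correct and trainable, not that it attains any particular score
on clinical data; the full-scale reproduction script
(`inst/scripts/reproduce.R`) exists for the latter and requires downloading
the Challenge dataset.

## Desk-scale problem sizes

The shipped tests exercise every stage at sizes chosen to keep the whole
suite in a few minutes of CPU time while leaving the conclusions
meaningful: the end-to-end recovery test trains the ten-block
average-pooling network on a cohort of 320 synthetic recordings (80 per
class, about 400 segments after normalization), for at most 30 epochs at
learning rate 1e-3 and batch 30 with the convergence shortcut enabled, and
requires average F1 of at least 90 on a held-out stratified fold; in
practice the network reaches perfect training accuracy around epoch 11 and
a perfect held-out score. Unit-level training tests use a three-block
network on 300-sample segments, where an epoch costs milliseconds. The
learning rate 1e-3 is the optimizer's base rate, appropriate for strongly
separable data; the 1e-4 default in `train_config()` is the setting
selected for the full-scale problem, where the cleaner optimum matters more
than speed.

## Known limitations

* The engine is single-threaded CPU code. It trains the desk-scale
  problems in minutes and the full Challenge problem in hours; it is a
  correctness-first reference implementation, not a performance-competitive
  one.
* Segment-level cross-validation (the default, for comparability) permits
  sibling-segment leakage; use `grouped = TRUE` for leakage-free folds.
* The MAT-v5 reader supports the single-variable uncompressed layout the
  Challenge uses, not arbitrary MATLAB files.
* The synthetic "Other" class is one fixed morphology; a classifier that
  separates it perfectly has not thereby learned the real class's
  heterogeneity.
* Per-recording aggregation of segment predictions (voting) is out of
  scope; evaluation is per segment throughout.
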