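# afdetect1d

Automatic detection of atrial fibrillation (AF) in variable-length,
single-lead ECG recordings with an end-to-end one-dimensional convolutional
neural network. The package targets the four-class rhythm classification
problem posed by the PhysioNet/CinC Challenge 2017 training data — AF,
Normal sinus rhythm, Noisy, Other rhythm — and is aimed at biomedical
signal-processing researchers who want a fully inspectable, reproducible
reference pipeline in R rather than a black-box framework model.

AF is marked in the ECG by irregular R-R intervals, absent P waves, and a
low-amplitude 4–8 Hz fibrillatory baseline oscillation. Instead of
extracting such features by hand, the package feeds raw 300 Hz samples to a
CNN and learns them from data.

## What the package implements

**Length normalization.** CNNs need fixed-length input but the recordings
run 9–61 s. The segment length *T* is chosen automatically as the modal
1-s bin of the duration histogram (30 s → *T* = 9000 samples at 300 Hz).
Recordings of exactly *T* samples pass through; longer recordings are
chopped into windows of *T* samples with 50% overlap (stride *T*/2, plus
one end-anchored window when a tail would otherwise go uncovered — an
18,600-sample recording yields windows at 0, 4500, 9000, 9600); shorter
recordings are periodically tiled, `output[i] = input[i mod len]`, up to
exactly *T*.

**The network.** Ten convolutional blocks — valid convolution (kernel 5,
stride 1), ReLU, size-2 pooling — with filters doubling every two blocks
(32 → 512), batch normalization in block 1 only, dropout 0.5 after blocks
6, 8, 9, then dense layers 128 → 32 → 4 and a softmax:

    P(class j | x) = exp(z_j) / Σ_k exp(z_k)

Training minimizes categorical cross-entropy J(x, y, θ) = −Σ_i x_i log y_i
(one-hot truth x, predicted probabilities y, averaged over the minibatch)
with bias-corrected Adam, θ_t ← θ_{t−1} − η·m̂_t/(√v̂_t + ε). The
reference variant `Proposed-1` uses max pooling; `Proposed-2` (the best
performer) replaces every pooling with average pooling; five further
variants (`All-BN`, `No-BN`, `Maxpooling`, `Max-Average`, `Extra-Average`)
isolate the effect of batch-normalization and pooling placement. The
training engine (C++/RcppArmadillo, single precision, seeded and
deterministic) is part of the package; its gradients are verified against
finite differences in the test suite.

**An analytic shape/parameter calculator.** `compute_layer_summaries()`
derives every layer's output shape and parameter count without building a
network — for the ten-block stack, conv outputs 8996, 4494, 2243, 1117,
554, 273, 132, 62, 27, 9 and 3,212,740 trainable parameters — and serves
as the independent oracle against which every built network is checked.

**Evaluation and model selection.** Four-class confusion matrices
(predictions in rows), one-vs-rest collapse, precision/recall/accuracy/F1
in percent, the headline unweighted mean F1 over the four classes,
stratified K-fold cross-validation (per-fold class counts within one
segment of exact proportionality), and an exhaustive 300-point grid search
over layers {8–11} × kernel {3, 5, 7} × batch {30–110} × learning rate
{5e-5–5e-3}, with infeasible deep/wide combinations reported as N/A.

**A synthetic ECG generator**, so every stage is testable without
downloading the Challenge data: Gaussian-bump beat morphology, per-class
rhythm and waveform signatures (irregular rapid RR + no P + 4–8 Hz
oscillation for AF), the 9–61 s duration mixture with its mode at 30 s,
and writers for the on-disk record layout the package reads.

## Worked example

```r
library(afdetect1d)

# a small synthetic cohort in the Challenge's shape
d    <- gen_dataset(synth_config(c(AF = 10, Normal = 10, Noisy = 10, Other = 10), seed = 7))
segs <- normalize_dataset(d$recordings)
print(segs)
#> <segment_dataset> 54 segments of 9000 samples
#>   class counts: AF=14, Normal=12, Noisy=15, Other=13
```

Forty recordings became 54 segments: the threshold landed on 9000 samples
(the modal 30-s duration), long recordings were chopped into overlapping
windows, short ones tiled. The architecture and its analytic layer table:

```r
spec <- make_variant("Proposed-2")
count_trainable(spec)
#> [1] 3212740
head(subset(compute_layer_summaries(spec), params_total > 0), 4)
#>  layer_kind output_len channels params_total params_trainable
#>        conv       8996       32          192              192
#>          bn       8996       32          128               64
#>        conv       4494       32         5152             5152
#>        conv       2243       64        10304            10304
```

The first convolution turns 9000 raw samples into 8996 × 32 feature maps
with 192 parameters (5·1·32 weights + 32 biases); batch normalization adds
128 numbers of which 64 (scale, shift) are trainable. Training and
evaluation:

```r
model <- build_network(spec, seed = 11)
model <- fit(model, segs, train_config(learning_rate = 1e-3, epochs = 10, seed = 11))
pred  <- predict(model, segs)
metrics_report(confusion4(segs$info$label, pred$labels))
```

A `metrics_report` prints per-class precision/recall/F1 and the averages,
e.g. for a small hand-built confusion matrix:

```r
cm <- confusion4(truth     = c("AF", "AF", "Normal", "Other", "Noisy", "AF"),
                 predicted = c("AF", "Other", "Normal", "Other", "Noisy", "AF"))
metrics_report(cm)
#> <metrics_report>
#>   class precision recall     f1
#>      AF       100  66.67  80.00
#>  Normal       100 100.00 100.00
#>   Noisy       100 100.00 100.00
#>   Other        50 100.00  66.67
#>   accuracy 83.3%, average F1 86.7% (3-class 82.2%)
```

One of three AF segments was called Other, costing AF recall (66.67%) and
Other precision (50%); the headline average F1 is the unweighted mean of
the four per-class F1 values.

A command-line front end wraps the same functions
(`inst/cli/afdetect1d.R`): `synth`, `preprocess`, `describe`, `train`,
`evaluate`, `gridsearch`.

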