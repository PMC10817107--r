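---
title: "Sleep staging from EEG scalograms: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging from EEG scalograms: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the approach

Clinical sleep studies score overnight EEG in 30-second epochs into five
stages — wake (W), three non-REM depths (N1–N3) and REM — following the
AASM manual. Manual scoring is slow and requires trained experts.
`sleepwave` implements an automatic pipeline that treats staging as an
image-classification problem:

1. **Preprocessing.** Each channel passes a 50 Hz powerline notch and a
   2nd-order Butterworth bandpass (0.3–30 Hz), the band that contains the
   stage-discriminating delta/theta/alpha/sigma/beta activity.
2. **Epoching.** The filtered record is cut into non-overlapping 30-s
   epochs, the AASM scoring unit.
3. **Time–frequency transform.** Every epoch is mapped to a scalogram by
   a continuous wavelet transform (CWT) with the *bump* analytic wavelet,

   $$C_a(b) = \frac{1}{\sqrt{a}} \int x(t)\,
     \varphi^*\!\Big(\frac{t-b}{a}\Big)\,dt ,$$

   with scale $a$ converted to physical frequency by
   $F = F_c F_s / a$, where $F_c$ is the wavelet's center frequency in
   cycles/sample and $F_s$ the sampling rate. The magnitude is rendered
   as a 64×64 RGB image through min–max normalization, a fixed viridis
   lookup table, and antialiased bilinear resizing.
4. **Classification.** A compact 19-layer convolutional network — four
   conv/batch-norm/ReLU blocks with 128, 64, 32 and 16 filters (kernels
   7×7, 5×5, 3×3, 3×3), max pools of 3×3, 3×3 and 2×2 (stride 2), a
   5-way fully connected layer, softmax and a cross-entropy head — maps
   each image to stage probabilities. Weights start from glorot
   (fan-based) zero-mean Gaussians; training uses Adam at learning rate
   0.001 with mini-batches of 128.
5. **Evaluation.** Stratified 70/15/15 train/validation/test splits,
   one-vs-rest confusion-matrix metrics (sensitivity, specificity,
   precision, F1, binary accuracy), trapezoidal one-vs-rest AUC, and
   stratified k-fold cross-validation reported as mean ± sample
   standard deviation.

```{r}
library(sleepwave)
res <- run_sleep_pipeline(n_per_class = 200, seed = 1, verbose = TRUE)
res
glance(res$metrics)
```

## The bump wavelet

The bump wavelet is defined in the frequency domain:
$\hat\Psi(s\omega) = \exp\!\big(1 - 1/(1 - w^2)\big)$ for $|w| < 1$ with
$w = (s\omega - \mu)/\sigma$, and $0$ outside. Its compact, bell-shaped
support gives the narrowest frequency variance of the common analytic
wavelets, which benefits EEG work where close-by rhythms (e.g. theta at
5 Hz vs. spindles at 13 Hz) must stay separated in the image. The
defaults $\mu = 5$, $\sigma = 0.6$ (hence
$F_c = \mu/2\pi \approx 0.796$ cycles/sample) are the de-facto defaults
of mainstream CWT implementations; both are arguments of
`bump_wavelet()`. Admissibility requires $\mu - \sigma > 0$ and is
enforced.

The transform is computed by frequency-domain multiplication (FFT of
the epoch × conjugate scaled window, inverse FFT), which implies
periodic boundary extension; no reflection padding is applied. The
package's test suite pins the FFT route against direct numerical
integration of the transform sum on short signals (relative error
below $10^{-6}$) and checks that the ridge of a pure sinusoid lands
within one voice of its true frequency.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `notch_hz` | 50 | Hz | European powerline frequency |
| `notch_q` | 35 | — | ≈1.4 Hz stop width at 50 Hz; leaves the 30 Hz edge intact |
| `bp_order` | 2 | — | analog prototype order before the bandpass transform |
| `bp_low_hz`, `bp_high_hz` | 0.3, 30 | Hz | the conventional sleep-EEG band |
| `zero_phase` | TRUE | — | forward–backward filtering; no phase distortion of scalogram morphology |
| `epoch_seconds` | 30 | s | AASM scoring epoch |
| `f_min`, `f_max` | 0.5, 32 | Hz | scalogram band; covers the passband, 0.5 Hz floor keeps wavelet support usable on 30-s epochs |
| `voices_per_octave` | 12 | — | frequency resolution of the scale grid (73 scales over 6 octaves) |
| `image_size` | 64 | px | network input side |
| `learning_rate` | 0.001 | — | Adam initial step |
| `batch_size` | 128 | — | optimizer mini-batch |
| `max_epochs` | 100 | — | training budget cap |
| `validation_frequency` | 100 | iterations | mid-training validation cadence |

Zero-phase application squares the magnitude response, so the −3 dB
single-pass edges act as −6 dB edges in the two-pass chain; a
`zero_phase = FALSE` flag restores single-pass causal filtering. Filter
*design* (and the acceptance figures derived from it) always refers to
the single-pass response.

## The synthetic-data generator

Real polysomnography cannot be redistributed with a package, so
`sleepwave` ships a generator whose 30-s epochs carry the textbook
band-power signatures of the five stages: W = 10 Hz alpha (amplitude
1.0) + 20 Hz beta (0.5); N1 = 5 Hz theta (1.0); N2 = 5 Hz theta (0.8) +
13 Hz spindle bursts (1.0, 1-s bursts about every 6 s with raised-cosine
edges); N3 = 1 Hz delta at double amplitude (2.0); REM = mixed
low-amplitude 6 Hz (0.6) + 22 Hz (0.4). Every component receives a
per-epoch random phase and a small frequency jitter so images are not
pixel-identical; Gaussian noise (sd 0.3) and 50 Hz interference
(amplitude 0.2) are added so the notch filter genuinely has work to do.
All draws derive from a single integer seed and equal seeds give
bit-identical recordings.

What this emulates is *spectral* stage structure. It does **not**
emulate K-complex or vertex-wave morphology, artifacts (movement, EOG,
EMG, ECG bleed), stage transitions inside an epoch, inter-subject
variability, or class imbalance of real hypnograms. Consequently, tests
passing on synthetic data demonstrate that the pipeline's mechanics —
filtering, transform, rendering, optimization, evaluation — are
correct and that the network can learn separable spectral classes; they
do not certify clinical-grade accuracy on real recordings.

## Numerical and design choices

* **Engine.** No deep-learning framework is used: the network is a
  spec-driven interpreter over layer records, with im2col/col2im,
  pooling and batch-norm kernels in C++ and convolution GEMMs in BLAS.
  On single-CPU machines large allocations dominate runtime, so all
  bulky intermediates live in a recycled buffer pool.
* **Ghost-batch normalization.** Activations of the first block at
  mini-batch 128 would need several hundred MB per cached tensor;
  batch-norm statistics are therefore computed over sub-batches of 16
  images while gradients still accumulate to the full 128 per Adam
  step. After training (and before each epoch-end validation) the
  running statistics are replaced by exact population moments of the
  training set — the standard finalization step; without it, the
  exponential moving average (momentum 0.1 from a unit-variance start)
  needs hundreds of updates to forget its initialization.
* **Early stopping.** `train_config(early_stop_val_acc = …)` stops at
  the first epoch whose validation accuracy reaches the target; the
  pipeline default (0.995) keeps the end-to-end run to the few epochs
  it actually needs. `max_epochs` remains the hard cap.
* **Pooling.** Table-style "same" convolutions with ceil-mode pooling
  give the spatial trace 64 → 32 → 16 → 8, keeping all 19 layers viable
  at a 64×64 input. The conv layers are linear; the separate ReLU
  layers carry the activations (counting them separately is what makes
  the stack 19 layers deep).
* **Degenerate metric cells.** One-vs-rest metrics with a zero
  denominator (e.g. a class absent from both truth and prediction)
  return `NA` and are excluded from macro averages; the count of
  excluded classes is reported. Per-class *recall* is additionally
  reported under the explicit name `recall_as_accuracy` because some
  published per-class tables label recall as "accuracy"; the package
  reports both rather than silently matching either convention.
* **AUC.** Multiclass AUC is one-vs-rest with unweighted macro
  averaging, computed by the trapezoidal rule over all score
  thresholds (tie-aware, equal to the normalized Mann–Whitney
  statistic; tested against brute-force pairwise comparison and
  against pROC).
* **Ties.** Argmax ties in classification break toward the lowest
  class index (the earlier stage in W < N1 < N2 < N3 < REM).
* **Degenerate rendering.** A constant scalogram (min = max) renders as
  the colormap's zero color rather than dividing by zero.
* **Resizing.** Images are resized bilinearly *with antialiasing*
  (triangular kernel widened by the downscale factor, implemented as
  two weight-matrix products). A 30-s epoch has 6000 scalogram columns
  mapped to 64 pixels; plain bilinear sampling would alias away 1-s
  spindle bursts. Resizing happens on the RGB image after colormap
  lookup, the common image-pipeline order.
* **EDF.** The EDF writer/reader covers continuous recordings with a
  shared sampling rate, 16-bit integer samples and 1-s records —
  sufficient for this pipeline's interchange needs; EDF+ annotations
  are out of scope. Channel labels are treated as opaque strings.
* **Problem sizes.** The shipped end-to-end evaluation uses 200
  epochs per class (1000 epochs, a 700/150/150 split) and trains at
  most 20 epochs with early stopping — a deliberately desk-scale
  surrogate for a full overnight-database experiment, chosen so the
  whole suite runs on one CPU core in tens of minutes. Full-scale
  training on a real database (tens of thousands of epochs per
  channel, 100 training epochs) uses the same code paths unchanged.

## Known limitations

* The CNN engine is CPU-only and single-threaded apart from BLAS; it is
  sized for the package's desk-scale experiments, not for
  full-database training runs.
* The synthetic generator's simplifications (above) mean reported
  synthetic accuracies overstate what any method would achieve on
  clinical data.
* 10-fold cross-validation retrains the network per fold; on desk-scale
  data this is minutes per fold, but it is the correct (and expensive)
  protocol.
* The EDF subset does not parse EDF+ or per-signal sampling rates.
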