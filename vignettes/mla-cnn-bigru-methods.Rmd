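---
title: "Methods: lead-attentive spatiotemporal ECG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lead-attentive spatiotemporal ECG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Myocardial infarction (MI) leaves characteristic fingerprints on the
12-lead electrocardiogram — ST-segment deviation and T-wave changes — but
not uniformly across leads: each lead views the heart from a different
angle, so an inferior infarct shows mainly in leads II, III and aVF, an
anterior one in V3–V4, and so on. `mlaecg` implements a hybrid neural
network that makes this lead-selectivity explicit and learnable.

For a segmented heartbeat $L \in \mathbb{R}^{k \times t}$ ($k = 12$ leads,
$t = 651$ samples at 1000 Hz), the **multi-lead attention** (MLA) module
computes

$$M_1 = \tanh(W_1 L + b_1), \qquad
  \alpha_1 = \mathrm{StepReLU}(M_1 w_1), \qquad
  x_i = \alpha_{1i}\, l_i ,$$

with $W_1 \in \mathbb{R}^{k\times k}$, $b_1 \in \mathbb{R}^k$,
$w_1 \in \mathbb{R}^t$ trainable. StepReLU is the clipped identity
($0$ below $0$, $x$ on $[0,1]$, $1$ above $1$): a differentiable surrogate
for a step function that confines each lead weight to $[0,1]$, so a lead
can be fully kept, partially weighted, or eliminated outright
($\alpha_{1i} = 0$ zeroes its row of the weighted beat $X$).

Two parallel branches then extract features from $X$:

* a **spatial 2-D CNN**: two stages of convolution (three kernel shapes —
  $3\times3$, $5\times1$, $7\times1$, 20 kernels each, stride 1) → ReLU →
  batch normalization → $2\times2$ max pooling with stride 1 → dropout;
  the tall $5\times1$/$7\times1$ kernels read 5 or 7 *leads* at one time
  point. The 60 final feature maps are flattened and pooled by a
  tanh–softmax attention ($\alpha_2$, summing to 1) into the spatial
  feature $f_s$;
* a **bidirectional GRU** over the 651 columns of $X$ (update gate $z_t$,
  reset gate $r_t$, candidate $\tilde h_t$, with
  $h_t = (1-z_t)\ast h_{t-1} + z_t \ast \tilde h_t$), whose 651
  concatenated forward/backward states pass batch normalization and
  dropout before a second attention ($\alpha_3$) pools them into the
  temporal feature $f_t$.

The fused vector $F = [f_s, f_t]$ goes through batch normalization,
dropout and a single fully connected layer: a sigmoid for MI *detection*
(HC vs MI) or a softmax for MI *localization* (HC, AMI, ALMI, ASMI, IMI,
ILMI). Training minimizes mean binary / categorical cross-entropy with
Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-7}$).

## Preprocessing

`preprocess_records()` applies, per record:

1. **Standardization** — per-lead affine min–max map to $[-1, 1]$
   (a constant lead maps to zeros with a warning). Per-lead rather than
   per-record, so every channel exercises the network's input range.
2. **Denoising and baseline removal** — a multilevel Daubechies-6 DWT
   (periodized filter bank; level 9 at 1000 Hz, putting the discarded
   approximation band below ~1 Hz, where baseline wander lives). Fine
   detail bands (levels 1–3, ≈62–500 Hz, above diagnostic ECG content)
   are soft-thresholded with the universal rule
   $\sigma\sqrt{2\ln N}$, $\sigma$ estimated from the finest detail by
   MAD/0.6745. Because detrending shifts the resting level, each lead is
   affinely re-mapped to $[-1,1]$ afterwards; a re-map preserves waveform
   morphology where a hard clip would flatten R peaks into plateaus (and
   an argmax-based peak refinement would then land on a plateau edge).
3. **QRS detection** — Pan–Tompkins on lead II (the conventional
   monitoring lead): zero-phase 5–15 Hz Butterworth band-pass, five-point
   derivative, squaring, 150 ms moving-window integration, adaptive
   signal/noise thresholds with search-back and a 200 ms refractory
   period. A stronger integrator maximum inside the refractory window
   replaces the previous candidate (the integrator ripples within one
   QRS). Accepted peaks are refined to the raw lead-II maximum within
   ±40 ms, and the lead-II indices are applied to all 12 leads so beats
   stay time-aligned.
4. **Segmentation** — the inclusive window $[p-250, p+400]$ around each
   R peak gives a $12 \times 651$ beat; windows leaving the record are
   skipped (no padding — padding would fabricate signal), and the first
   and last surviving beats of every record are dropped.

The pipeline is fully deterministic.

## The synthetic generator

`generate_dataset()` emulates exactly what the downstream modules need and
no more: P/QRS/T as Gaussian bumps (centers 0.08/0.25/0.50 s, widths
0.025/0.012/0.05 s, amplitudes 0.15/1.0/0.3 mV), a rectangular ST segment
from 0.06 s after the QRS center to half a T-width before the T center,
fixed per-lead projection gains (aVR and V1 inverted), per-patient
amplitude gain ~ U(0.7, 1.3) and heart rate ~ U(55, 95) bpm, additive
white noise (default sd 0.05 mV), sinusoidal baseline wander (default
0.1 mV, 0.15–0.4 Hz), and class deformations — an ST shift (default
0.3 mV) plus T-amplitude scaling (default 0.6) on the anatomical lead
set of each MI class (AMI → V3–V4, ALMI → I, aVL, V3–V6,
ASMI → V1–V4, IMI → II, III, aVF, ILMI → II, III, aVF, V5, V6). A
`noise_leads` option replaces chosen leads with pure Gaussian noise
(sd 0.2 mV) — a deliberately uninformative channel for lead-weight
diagnostics.

What it does **not** emulate: realistic beat-to-beat morphology variation,
arrhythmia, electrode artifacts, pathological Q waves, or the
class-imbalance and inter-patient heterogeneity of clinical databases.
Passing the package's tests therefore demonstrates that the machinery is
correct and that the model can exploit lead-localized ST/T structure — not
that clinical-grade accuracy transfers to real recordings.

## Evaluation protocol

Five-fold cross-validation in two schemes, both built from a seeded
partition into five near-equal parts rotated as 3 train : 1 validation :
1 test. *Intra-patient* partitions beats; *inter-patient* partitions
patients (stratified by class so every part retains all classes, which
requires ≥ 5 patients per class) and beats follow their patients — the
clinically realistic protocol, asserted patient-disjoint in the test
suite. Metrics are accuracy, sensitivity and specificity in percent; for
localization they are computed one-vs-rest per class, the per-class
accuracy column reporting the overall multi-class fraction-correct (the
convention that makes every class of one evaluation share a single Acc
value) with the one-vs-rest accuracy exposed separately. Fold spread is
reported as the population standard deviation over the five fold values.
Lead weights are reported as the mean $\alpha_1$ over each fold's test
beats, averaged over folds.

## Numerical and design choices

* **SAME zero padding** for all three kernel shapes: the parallel groups
  must produce identical spatial dimensions to concatenate on the channel
  axis. Pooling is taken literally as $2\times2$ *with stride 1* (valid),
  so each pooling stage shrinks each spatial dimension by exactly one and
  the flattened spatial feature has length $(12-2)\times(651-2) = 6490$.
* **Batch normalization after activation** (the layer order conv → ReLU →
  BN → pool → dropout), per-channel over batch × positions, momentum
  0.99, $\epsilon = 10^{-3}$; over the feature axis (shared across time)
  for the BiGRU states; over features for the fused vector.
* **Precise-BN recalibration.** After the last epoch the running moments
  are replaced by the average batch statistics from one dropout-free pass
  over the training set. With short schedules the momentum-0.99 running
  moments otherwise remain near their initialization and corrupt
  evaluation-mode predictions; recalibration makes evaluation behavior
  independent of schedule length.
* **StepReLU gradient**: exactly the clip subgradient — 1 on $[0,1]$
  (corners included, keeping at-bound leads trainable), 0 outside. A
  straight-through variant (gradient 1 everywhere) is available behind
  `straight_through = TRUE`, default off. The flat branches are absorbing
  under the exact subgradient: a lead pushed below 0 stays eliminated.
* **MLA initialization.** $b_1 = 0.1$ and $w_1 \sim U(0, c)$ with $c$
  chosen so initial lead weights sit near 0.5, and $W_1$ deliberately
  small-uniform ($\pm 0.1/k$). For standardized inputs this keeps every
  initial lead score strictly inside the identity branch. A conventional
  Glorot-width $W_1$ saturates the $\tanh$ and scatters initial scores
  onto the absorbing flat branches — leads frozen at birth by accident.
  Because batch normalization follows both branches, the *global scale*
  of $\alpha_1$ is only weakly identified; lead weights are therefore
  interpreted as a ranking, not as absolute magnitudes.
* **GRU**: hidden size default 64 per direction (32 in the self-contained
  experiments below); independent forward/backward parameter sets; zero
  initial states; input-to-hidden Glorot, hidden-to-hidden random
  orthogonal; the candidate line carries no bias, as printed in the
  recurrence — `use_candidate_bias = TRUE` adds one for users who read
  the omission as a typo.
* **Convolutions in float32** (im2col + BLAS gemm in compiled code): the
  conv stack dominates training cost, and single precision halves it;
  parameters, every other layer, and all reductions stay double. A
  float64 instantiation of the identical algorithm is selectable
  (`precision = "double"`) and is what the finite-difference gradient
  verification runs against, since central differences through a float32
  forward are quantization-limited near $10^{-2}$ relative.
* **Training loop**: one seeded shuffle per epoch, then sequential
  slices of size `batch_size`. The printed procedure slices without
  stating a shuffle; class-ordered slices would break SGD, so the shuffle
  is a deliberate deviation. No early stopping; the final-epoch model is
  returned and validation data only steer grid search. Defaults
  (batch 24, learning rate 0.001, 20 epochs, dropout 0.3) follow the
  reference grid search; `grid_search()` reproduces the full search
  (dropout 0.2/0.3/0.4 × lr 0.0008/0.001 × batch 16/24/32 × epochs
  10/20/30) with ties broken toward fewer epochs, then smaller batches.

## Problem sizes in the shipped experiments

The self-contained experiments (test suite and worked examples) use 10
patients per class × 24 beats per record, which survives preprocessing as
≈220 beats per class; detection models run with hidden size 32,
attention width 32 and the full 60-kernel conv stack, trained for two
epochs with precise-BN recalibration — on strongly separable synthetic
data (ST shift 0.3 mV, noise 0.05 mV) accuracy saturates within the
first epoch, and the second epoch lets the lead ranking settle; the
package's own five-fold cross-validation reaches ≥ 95 % mean
intra-patient accuracy and ranks a deliberately pure-noise lead below
every class-informative lead. Unit tests exercise the same code paths on short
(12 × 64) beats where the conv stack is light.

## Known limitations

* Lead-weight rankings on few-epoch schedules are noisy: the global
  $\alpha_1$ scale drifts (see above) and the separation between
  uninformative and informative leads emerges slowly, so single-fold
  rankings should not be over-read. The cross-validated mean — five
  models trained with independent seeds — is the reported quantity and
  separates far more reliably.
* The Pan–Tompkins implementation assumes 1000 Hz input; resample first.
* Batch statistics need at least two beats; `predict()` always uses the
  (recalibrated) running moments, so single-beat prediction is fine.
* No class re-weighting: imbalanced datasets inherit the imbalance in
  the loss, as in the reference procedure.
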