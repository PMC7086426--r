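---
title: "Detecting moderate TBI from resting-state EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting moderate TBI from resting-state EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The detection problem

Moderate traumatic brain injury (TBI, Glasgow Coma Scale 9–13) is hard to
triage quickly: imaging is expensive and slow, while quantitative EEG
carries known spectral biomarkers — injured brains show reduced alpha-band
activity and increased theta-band activity relative to healthy controls.
`eegtbi` implements a complete detection pipeline around this signal:
resting-state eye-closed EEG is recorded from a 64-channel 10-10 cap at
1000 Hz, the `CPz` channel (used for electrooculography) is excluded, the
first 60 s are discarded, and the next 60 s are cut into one-second
segments. Each segment is a plain amplitude matrix

\[ M_{i,t} = x_i(t), \qquad i = 1,\dots,N,\; t = 1,\dots,F_s, \]

with \(N = 63\) retained channels and \(F_s = 1000\) samples, so a subject
contributes sixty \(63 \times 1000\) matrices. A convolutional network
classifies each segment as `healthy` or `tbi`; four conventional
feature-engineered classifiers act as comparators under the identical
evaluation protocol.

## The convolutional network

The reference topology (`build_reference_topology()`) has nine layers: five
convolution layers, an average-pooling layer, a sixth convolution, a second
average pooling, and a softmax fully connected layer. Every convolution
uses six 5×5 filters with stride 1 and is followed by batch normalization
and ReLU. Convolutions and poolings are *valid* (unpadded); a layer maps an
\(h \times w\) map to

\[ h' = \left\lfloor \frac{h - f + s}{s} \right\rfloor, \qquad
   w' = \left\lfloor \frac{w - f + s}{s} \right\rfloor, \]

with filter size \(f\) and stride \(s\). The floor matters only for the
2×2/stride-2 poolings (e.g. height 43 → 21). Folding this algebra over the
layer list (`trace_shapes()`) gives the canonical trace

```
63×1000×1 → 59×996×6 → 55×992×6 → 51×988×6 → 47×984×6 → 43×980×6
          → 21×490×6 → 17×486×6 → 8×243×6 → 2 logits
```

so the fully connected layer sees 8·243·6 = 11664 flattened activations.
The topology is data, not code: any chain of convolution/pooling layers can
be declared (`make_topology()`), serialized to YAML, and validated before
training — an over-deep chain fails with the offending layer index.

Training (`train_cnn()`) is plain mini-batch SGD: constant learning rate
1e-4, momentum 0.9, mini-batch 128, 30 epochs, and an L2 penalty of 5e-4
times the squared weight norm added to the 2-class cross-entropy. An epoch
is \(\lceil n/\text{batch} \rceil\) iterations (680 segments at batch 128
→ 6 iterations). These defaults are the reference regime; every one of
them is a `train_config()` field.

Implementation notes, for the record:

* Convolutions are evaluated as im2col gathers plus one BLAS matrix
  product per layer and mini-batch; the backward pass uses the transposed
  convolution as a second gather with a re-indexed kernel, so no explicit
  scatter loops remain on the hot path. Gradients of every parameter kind
  were validated against central finite differences (worst relative error
  below 1e-4; conv biases under batch norm have true gradient zero).
* Batch normalization is per filter over the batch and both spatial axes,
  with running statistics (momentum 0.1) used at inference. The order is
  batch-norm then ReLU. Conv biases are kept although batch normalization
  makes them redundant; they stay at their near-zero initialization.
* Weight initialization is fan-in-scaled Gaussian under the run seed;
  fixing `seed` fixes the entire trajectory (initialization, shuffling,
  final weights), which the tests assert bit-for-bit.
* The loss penalizes convolution and fully connected weights only; biases
  and batch-norm scale/shift are unpenalized, as is conventional.
* Classification is per segment. No subject-level vote is applied anywhere,
  so reported accuracies are segment accuracies.

## Evaluation protocol

Accuracy is computed from the confusion counts with TBI as the positive
class,

\[ \text{ACC} = 100 \cdot \frac{TP + TN}{TP + TN + FP + FN}, \]

under *subject-level* threefold cross-validation: whole subjects, with all
their segments, are assigned to train or test, so subject identity can
never leak across the split. For a 15 + 15 cohort, `make_fold_plan(...,
scheme = "fixed_threefold")` reproduces the literal reference assignment
(fold 1 tests subjects 11–15 of each class, fold 2 tests 1–5, fold 3 tests
6–10); `balanced_random` deals shuffled subjects into class-balanced folds
for everything else.

Because thirty subjects is a small cohort, the cross-validation is wrapped
in a bootstrap (`run_bootstrap_cv()`): each of (by default) 100 iterations
resamples the subjects with replacement to the original cohort size, builds
a balanced fold plan on the resample, and records the mean fold accuracy.
The summary is the mean, the sample standard deviation (n−1), and a 95%
confidence interval. Design choices here were genuinely open:

* **CI method.** The percentile bootstrap (2.5th/97.5th percentiles of the
  per-iteration accuracies) is used — the standard assumption-free
  estimator.
* **Resampling unit.** Subjects, not segments, are resampled, preserving
  the subject-level guarantee. A subject drawn twice contributes its
  segments twice, and all copies stay on one side of every fold split (a
  dedicated test spies on every fit/predict call to confirm the
  intersection is always empty).
* **Degenerate resamples** in which a class has fewer distinct subjects
  than folds are redrawn and counted in `n_redrawn`.

Oracle and coin-flip reference pipelines calibrate the machinery: the
oracle yields mean 100, SD 0, CI [100, 100]; the coin flip centres on 50%;
and the expected fraction of distinct subjects per resample matches
\(1 - (1 - 1/30)^{30} \approx 0.638\) over ten thousand draws.

## The comparison pipelines

All classifiers satisfy one prepare/fit/predict contract and are therefore
interchangeable inside `cross_validate()` and `run_bootstrap_cv()`:

* **Naive Bayes** — mains notch, 100 Hz low-pass, 0.5 Hz high-pass,
  two-second epochs; features are per-electrode beta band power plus
  orthogonalized-envelope connectivity of the delta, theta and gamma bands;
  Gaussian Naive Bayes. The all-pairs connectivity set is quadratic in the
  montage, so it is summarised per electrode (mean connectivity with all
  others, per band), keeping the feature count at 4 per electrode.
* **AdaBoost** — 0.1–100 Hz band-pass; log10 mean PSD of delta, theta,
  alpha and gamma for the frontal bipolar derivations AF7–Fpz and AF8–Fpz
  (8 features); AdaBoost over decision stumps, 50 rounds by default (the
  weak-learner count of the original is unreported).
* **SVM + MRMR** — 0.5–30 Hz band-pass; per electrode the average power of
  theta, alpha, beta1, beta2, beta3 plus all 1 Hz bins from 1 to 30 Hz (34
  features per electrode, 2142 on the full montage); the top 10 features by
  greedy mutual-information MRMR, selected on the training fold only; SVM
  with radial kernel.
* **SVM on alpha power** — one alpha-band power feature per electrode;
  radial SVM.

Shared numerics: band edges follow conventional clinical definitions
(delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30 with beta1/2/3 sub-bands,
gamma 30–70 Hz, capped by the 70 Hz amplifier passband); band power is the
integrated Welch PSD (Hann window, 50% overlap) over `[low, high)`; the
notch defaults to 50 Hz mains; envelope connectivity band-filters both
channels, removes the zero-lag regression component of one from the other
(both directions, averaged), and correlates the log amplitude envelopes of
the FFT analytic signal, so shared instantaneous activity contributes
nothing; MRMR discretizes into equal-frequency quartile bins and breaks
ties toward the lower feature index; SVM features are standardized with
training-fold statistics only; SVM hyperparameters are the radial kernel
defaults with unit cost, since the originals report none.

## The synthetic cohort generator

The clinical recordings are not distributable, so `generate_cohort()`
produces seeded surrogate cohorts with the statistical structure the
detection problem assumes. Per channel, a subject is

\[ x(t) = a_{bg}\,\eta_\beta(t) + \sum_{b \in \{\delta,\theta,\alpha,\beta\}}
          a_b\, o_b(t), \]

where \(\eta_\beta\) is \(1/f^\beta\) noise (default \(\beta = 1\)) and
\(o_b\) is band-limited Gaussian noise with raised-cosine band edges,
both synthesized in the frequency domain. Default RMS amplitudes are 15 µV
background and 8/6/10/3 µV for delta/theta/alpha/beta — eyes-closed-like,
with total RMS near 21 µV, a plausible scalp EEG scale (the clinical
cohort's amplitude statistics are unpublished; these are config knobs, not
claims). Per-subject band amplitudes get lognormal factors with
coefficient of variation 0.2 (a realistic inter-subject spread), and
per-channel factors with CV 0.1. Spatial correlation comes from mixing
each channel with its cap-order neighbors (weight 0.4, RMS-preserving) —
enough to make connectivity features non-degenerate without a head model.
The TBI class multiplies the alpha amplitude by `alpha_attenuation` and the
theta amplitude by `theta_gain`; `alpha_attenuation = theta_gain = 1` is
the exact null. Everything derives deterministically from
`(seed, class, subject_index)`.

What the generator does *not* emulate: eye blinks, muscle and movement
artifacts (beyond optional injected spikes used to exercise the rejector),
volume-conduction topographies, non-stationarity, and any dependence of
the effect on electrode location. Passing tests therefore demonstrate that
the pipeline recovers a known band-power class structure under realistic
noise and inter-subject variability — not clinical performance.

Artifact handling follows the same philosophy: the clinical study removed
artifact segments by visual inspection, which is not automatable, so
`reject_artifacts()` substitutes a deterministic absolute-amplitude
threshold (default 100 µV, configurable, off for synthetic cohorts).

## Problem sizes used by the test suite

The package's statistical tests run cohorts at a reduced scale chosen so
the full bootstrap-of-cross-validation machinery is exercised end to end:
15 + 15 subjects, 16 channels (always including Fpz, AF7, AF8 and CPz),
32 Hz sampling with 14 one-second segments per subject for the CNN runs,
and 250 Hz with two-second epochs for the baseline feature chains (whose
filters need the mains/100 Hz region to exist). The CNN for this scale is
declared with the same topology algebra (three 3×3 convolutions and two
poolings on a 15×32 input) and trained at learning rate 0.02, batch 64, 25
epochs — at 32 Hz a 3-sample kernel spans ~94 ms, preserving the network's
ability to resolve theta from alpha, which is also why the reduced rate
rather than the reduced channel count carries the scale reduction. The
null-calibration check runs a 20-iteration bootstrap on an exact-null
cohort; the effect-recovery check uses `alpha_attenuation = 0.4`,
`theta_gain = 1.5` and requires threefold CV accuracy above 70% and above
the null mean by more than two null SDs. The full-geometry arithmetic
(64 × 130000 samples → 60 segments of 63 × 1000) is asserted at full size.

## Known limitations

* Reported accuracies are segment-level; subjects are never aggregated.
* The CNN engine is CPU-only and single-threaded beyond BLAS; the full
  63 × 1000 topology trains, but slowly — it is intended for the reduced
  scale and for forward passes, while the full scale is validated through
  its exact shape trace and parameter count.
* The EDF writer quantizes to 16 bits over each channel's physical range
  (as the format dictates); round trips are exact only to that step.
* The bootstrap CI is percentile-based; with 20-iteration runs the CI is
  itself noisy, which is why calibration bands in the tests are wide.
* Baseline hyperparameters left unreported by their sources (boosting
  rounds, SVM settings, connectivity aggregation) are fixed, documented
  defaults here, not inferences about the originals.
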