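---
title: "Patient-specific heartbeat classification: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific heartbeat classification: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatnet)
```

`beatnet` classifies single-lead ECG heartbeats into the four AAMI target
classes — N (normal-like), S (supraventricular ectopic), V (ventricular
ectopic) and F (fusion) — with a pipeline of four stages: median-filter
baseline removal with derivative-based QRS detection and fixed 700 ms beat
segmentation; a signal-adaptive frequency slice wavelet transform that turns
each beat into a normalized time-frequency image; a stacked denoising
auto-encoder (SDA) that learns a compact feature representation of those
images without labels; and a softmax deep neural network (DNN) classifier
initialized from the SDA and fine-tuned twice — first on an interpatient
training corpus, then on a small initial annotated portion of the target
patient's own record. This vignette explains the models, the parameters
that matter, and the design decisions taken where more than one reasonable
choice existed.

## The time-frequency transform

The transform operates in the frequency domain. Writing $\hat f(u)$ for the
Fourier transform of the beat $f(t)$, the spectrogram over observed time
$t$ and observed frequency $\omega$ is

$$W_f(t,\omega) \;=\; \frac{1}{2\pi}\int_{-\infty}^{\infty}
\hat f(u)\,\hat p^{*}\!\left(\frac{u-\omega}{q(u)}\right) e^{iut}\,du,$$

with the Gaussian frequency slice function $\hat p(x) = e^{-x^2/2}$ as the
window. Because $\hat p(0) = 1$, every input-frequency component survives
unattenuated on its own slice, which makes the transform exactly
invertible:

$$f(t) \;=\; \frac{1}{2\pi}\int\!\!\int
W_f(\tau,\omega)\,e^{i\omega(t-\tau)}\,d\tau\,d\omega.$$

The signal adaptivity sits in the scale function

$$q(u) \;=\; \delta + \operatorname{sign}\!\big(\nabla |\hat f(u)|\big),$$

where $\delta$ is the frequency of the spectral magnitude maximum and the
sign term nudges the slice width by $\pm 1$ Hz with the local spectral
slope. Narrow slices resolve weak components, wide slices reinforce strong
ones, and no wavelet or window length has to be hand-picked per signal.

Discretization choices:

* Both integrals are evaluated on the DFT grid of the 252-sample segment
  (700 ms at 360 Hz). The forward transform windows the FFT of the signal
  per observed frequency and carries it back with an inverse FFT; an $O(n^2)$
  direct-summation reference (`mfswt_direct()`, `mfswt_inverse_direct()`)
  is kept in the package as an independent cross-check and agrees with the
  FFT path to below $10^{-8}$ on short signals.
* $q(u)$ is evaluated per input-frequency bin on the nonnegative half-grid
  and mirrored to negative bins; the DC bin is excluded from the argmax
  defining $\delta$; the derivative is a forward difference whose last bin
  copies its neighbour. $q$ is clamped below at `q_min = 0.5` Hz so the
  slice width stays positive when $\delta$ is small.
* The literal sum of a frequency ($\delta$, Hz) and a dimensionless sign is
  implemented as written; treating the sign term as a 1 Hz nudge is the
  interpretation under which the units compose.
* Because $q$ adapts to the input spectrum, the transform is strictly
  linear only at a fixed $q$; `mfswt(q = ...)` exposes that. The adaptive
  transform is still positively homogeneous (scaling the signal scales the
  spectrogram), since $\delta$ and the sign pattern are scale-invariant.
* Reconstruction from the full signed DFT grid is exact to floating-point
  (percentage root-mean-square difference around $10^{-13}$ %). For even
  segment lengths the unpaired Nyquist bin breaks the exact conjugate
  symmetry of $\pm\omega$ rows at the $10^{-5}$ level; odd lengths pair
  exactly.

Classifier input images keep frequencies up to `f_max = 64` Hz — P/QRS/T
content lives below ~40 Hz and powerline interference at 50/60 Hz remains
visible — on a 45 x 64 grid (the 45 DFT bins of a 252-sample segment below
64 Hz, resampled along time by area averaging) and are min-max normalized
to $[0,1]$ per image, giving 2880 classifier inputs. Area averaging rather
than interpolation is used so that downsampling cannot alias narrow
spectral ridges; a numerically constant magnitude maps to an all-zero
image rather than amplifying resampling round-off.

## Preprocessing

Baseline wander is estimated by a 200 ms running median (removes QRS and
P) followed by a 600 ms running median of its output (removes T), and
subtracted. Window lengths are converted to the nearest odd sample count
(73 and 217 samples at 360 Hz); edges are padded by point reflection,
which preserves the local slope of a drifting baseline (plain mirroring
creases it and leaves an edge artifact). Two properties are worth knowing:
median filtering is nonlinear, so under a steep drift the P/T remnants
that survive the 200 ms stage can displace the 600 ms median rank — with a
0.5 mV, 0.3 Hz sinusoidal drift the recovered signal correlates with the
clean beats at about 0.97, not arbitrarily close to 1 — and a second
application changes the output by a few percent RMS (it re-estimates the
same small wave leakage), so the operation is only approximately
idempotent.

QRS detection emphasizes the steep QRS slope: a five-point derivative is
squared and integrated over a centred 150 ms window; plateau-aware local
maxima of this emphasis above an adaptive threshold (0.4 x an
exponentially updated running peak estimate, update weight 0.125) are
accepted subject to a 200 ms refractory period, and each accepted
candidate is refined to the local absolute extremum of the corrected
signal within +/- 50 ms. All constants are exposed as arguments. On
noise-free synthetic records the detector attains 100% sensitivity and
positive predictivity at exact sample positions.

Beats are cut as 700 ms windows, 300 ms before to 400 ms after the R
sample; windows crossing a record boundary are dropped (keeping the input
dimensionality fixed) and reported. Detections are paired to reference
annotations by greedy nearest matching within 75 ms, each annotation used
at most once; unmatched detections are labelled `"unknown"` and excluded
from training and evaluation.

## Feature learning and the classifier

Each denoising auto-encoder layer encodes $h = s(WV + b)$ and decodes
$\hat V = s(W^{\mathsf T} h + b')$ with tied weights and logistic
activations, and is trained to minimize the cross-entropy between the
clean input and the reconstruction of a corrupted input in which each
entry is independently zeroed with probability $P$ (per-element Bernoulli
masking, resampled every epoch). Gradients are exact backpropagation with
the encoder- and decoder-side contributions accumulated into the single
tied weight matrix; they are verified against central finite differences
in the tests. Stacking is greedy: layer $k+1$ trains on the clean
encodings of layer $k$; corruption applies only inside each layer's own
objective. Layer sizes must decrease strictly so the bottleneck
abstracts.

Defaults, all configurable and chosen as ordinary values for sigmoid
stacks since no canonical setting exists: corruption $P = 0.25$ (0.5 is
used in the corruption-calibration demonstrations), weight initialization
uniform in $\pm 4\sqrt{6/(d_V + d_h)}$, zero biases, learning rate 0.1 on
the batch-mean gradient, batch size 32, 30 epochs per layer. The
`dae_gradient()` convention itself sums over the batch (duplicating a
batch doubles it); the SGD step divides by the batch size so the learning
rate is independent of batch size.

The classifier copies the trained encoder layers by value and adds a
4-way softmax head (class order N, S, V, F; zero-initialized, so the
untrained head is uniform). Supervised fine-tuning minimizes mean
categorical cross-entropy by mini-batch SGD through all layers jointly;
ties at the argmax resolve toward the earlier class. Patient adaptation
fine-tunes an independent copy on the first `n_adapt = 300` beats of the
target record, early-stopping when adaptation-set accuracy has not
improved for 10 consecutive epochs (or at 200 epochs) and returning the
best-accuracy snapshot; `n_adapt = 0` degenerates to the interpatient
classifier. If a class is absent from the adaptation beats the rule
simply stops on the reachable accuracy; no rebalancing is applied, and
class imbalance is left to the evaluation metrics.

## Evaluation

From the 4 x 4 confusion matrix (true rows, predicted columns) the
package reports per-class sensitivity, specificity, positive predictive
value and accuracy, overall accuracy (trace over total), and the
geometric means of the per-class sensitivities and positive predictive
values — the two-class geometric mean generalized to $k$ values as the
$k$-th root of their product. Ratios with zero denominators are reported
as `NA` and excluded from geometric means with a warning, never silently
zeroed. Percentages print at one decimal with half-up rounding; under
these conventions every percentage in the bundled reference confusion
matrices (interpatient: 89.3% overall; patient-specific: 97.5% overall,
g-means 85.9/84.4) reproduces exactly, which the tests assert.

The package also bundles the standard MIT-BIH arrhythmia database
conventions: the 15-code (and WFDB symbol) mapping onto AAMI classes with
unknown codes rejected loudly, exclusion of the four paced records
(102, 104, 107, 217) and of Q-class beats, the conventional 22/22
train/test record split, and a low-signal-quality hook that drops
user-listed beats together with their immediate neighbours (the
literature gives no objective criterion, so the package deliberately
takes a list rather than guessing one).

## The synthetic cohort

Real ambulatory records cannot ship with the package, so every stage is
exercised on synthetic ECG built from five Gaussian deflections (P, Q, R,
S, T) per beat. Class morphologies follow clinical convention: N has a
dominant narrow R; S (APC-like) carries a flattened ectopic P and a
shortened preceding RR (factor 0.7, the premature-timing cue); V
(PVC-like) has no P, a wide tall QRS (span >= 120 ms) and a discordant T,
also premature; F is the parameter-wise midpoint of N and V. Wave widths
are textbook: T duration about 180 ms (Gaussian sd 45 ms), which also
respects the premise of the 200/600 ms baseline filter that individual
deflections fit well inside the shorter window. Records add baseline
wander (0.15 mV at 0.3 Hz), powerline interference (0.05 mV at 60 Hz,
the MIT-BIH mains frequency), white noise (0.02 mV), RR jitter around a
800 ms mean, and — for cohorts — per-patient multiplicative jitter of
wave amplitudes and widths with log-sd 0.3, emulating the large
across-subject amplitude variability of electrode placement and anatomy.

What this generator does *not* emulate: real QRS micro-structure and
notching, rhythm context beyond premature timing (bigeminy, runs),
electrode motion artefacts, and recording-quality dropouts. Passing tests
therefore demonstrate the correctness of the transforms, learners and
workflow under controlled morphology — not clinical-grade performance on
real records.

The adaptation experiment (`run_adaptation_experiment()`) is the
desk-scale surrogate for the patient-specific study: 10 patients with 400
beats each (class mix 70/10/15/5% for N/S/V/F), the first five forming
the interpatient training corpus; reduced 24 x 32 images and a single
64-unit feature layer keep a full run in the tens of seconds. Each test
patient's classifier is adapted on its first 0, 40, 80, 160 or 300 beats
and always evaluated on the beats after the first 300, so the evaluation
set is fixed across adaptation counts. Held-out accuracy rises from
roughly 78% without personal beats to about 99% with 300, and increases
essentially monotonically in between — the qualitative signature of
patient-specific adaptation that the acceptance tests assert. Problem
sizes here (beats, image resolution, layer widths, epochs) were chosen as
the smallest at which that signature is stable.

## Known limitations

* The forward transform costs one FFT per retained frequency row; imaging
  a full 30-minute record is seconds, not milliseconds.
* The baseline filter's median-rank displacement under steep drift (above)
  slightly distorts T waves; this is inherent to the two-median design,
  not to the implementation.
* Learners are plain SGD with logistic activations — deliberately so, to
  match the architecture being reproduced; no momentum, dropout or
  calibration.
* The WFDB binary format is not read directly; records travel as the
  package's plain-text format (signal CSV, annotation CSV, JSON header),
  and WFDB annotation *symbols* are mapped via `map_to_aami()`.
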