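---
title: "From pose trajectories to synthetic inertial signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pose trajectories to synthetic inertial signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrimu)
```

## The problem

Hand-held VR controllers stream 6-DoF pose: world-frame position and a
unit quaternion for orientation. Behavioral-biometric systems feed these
streams to convolutional classifiers to recognize *who* is moving. The
orientation channel is usually presented as Euler angles, and Euler angles
wrap: a smooth wrist rotation whose yaw passes ±180° appears as a ~2π jump
between consecutive samples. A convolution kernel sliding over that jump
extracts a large spurious feature that has nothing to do with the
underlying motion and is not stable across recordings.

`vrimu` implements the algebraic remedy: derive, from the same pose
stream, the signals a body-mounted inertial measurement unit would have
produced. Angular velocity and body-frame acceleration are smooth wherever
the motion is smooth, whatever the orientation parameterization does.

## The transform and its conventions

Quaternions are stored w-first, Hamilton convention, and interpreted as
**body-to-world** maps. Consequently the sandwich `o* ⊗ (0, u) ⊗ o`
expresses a world vector `u` in body coordinates, which is what an
attached sensor reads. With forward differences
`f'(t) = (f(t+1) − f(t)) / ΔT`:

* velocity `v = vec(o* ⊗ p' ⊗ o)` (m/s),
* acceleration `a = vec(o* ⊗ p'' ⊗ o)` (m/s²), `p''` by differencing twice,
* angular velocity `ω = 2 M(o) o'` (rad/s), with `M(o)` the standard 3×4
  body-frame quaternion-rate matrix.

Design notes, in decreasing order of consequence:

* **Rate-matrix form.** `M(o)` is pinned down by requiring exact agreement
  with the conjugate-product form `ω = 2 vec(o* ⊗ o')`; the test suite
  checks the two routes agree to 1e-12 elementwise on smooth random
  orientation sequences. The body-frame (not world-frame) sign convention
  is chosen so the output matches an attached gyroscope; combined with the
  sandwich above it makes every derived channel invariant to a rigid
  re-orientation of the world frame (verified to 1e-9 over 100 random
  recordings), which is the defining property of a body-frame reading.
* **Sign continuity.** `q` and `−q` encode the same rotation, and recorded
  streams may flip sign arbitrarily. Differencing across a flip corrupts
  `o'` catastrophically, so `enforce_quat_continuity()` re-signs the
  sequence to nonnegative consecutive dot products before any derivative.
  This plumbing is invisible when streams are already continuous.
* **Forward differences, not central.** Both derivatives use the one-sided
  forward difference, applied twice for `p''`. The truncation error is
  O(ΔT), which the suite verifies by halving the step; at the 45–75 Hz
  rates of interest the bias is far below the between-subject signal. The
  last sample (last two for `p''`) duplicates its predecessor so derived
  channels keep the input length; closed-form checks exclude that padding.
* **No gravity by default.** The transform models kinematic acceleration
  of the tracked body. An accelerometer additionally reacts to gravity;
  users who want specific-force semantics can opt in
  (`add_gravity = TRUE`), which subtracts world gravity (0, 0, −9.81) m/s²
  rotated into the body frame.
* **Euler convention.** Intrinsic Z-Y-X (yaw-pitch-roll), the common
  choice for yaw-dominant controller data. Within 1e-6 of the gimbal-lock
  pitch ±π/2 the yaw/roll split is resolved by setting roll = 0 (the full
  Z rotation goes to yaw). Euler outputs are deliberately left *wrapped*:
  unwrapping would erase the phenomenon under study.
* **Filtering.** Optional conditioning applies a 4th-order Butterworth
  low-pass (cutoff 3 or 6 Hz typical for hand gestures) forward and
  backward, so the phase response is zero and gesture features are not
  time-shifted; the cutoff gain of the two-pass filter is 0.5. The filter
  runs per channel with odd-reflection padding and steady-state initial
  conditions, so a constant channel passes through bit-nearly unchanged
  (DC error below 1e-9) even on short records. Filtering is applied
  *after* differentiation, to the acceleration and angular-velocity
  channels; differencing and a linear-phase filter commute up to edge
  effects, and filtering the outputs is what lets the unfiltered and
  filtered modality variants share one pose stream.
* **Uneven sampling is rejected, not repaired.** The pose CSV reader
  enforces uniform time steps (jitter tolerance 1e-6 s) and fails with a
  diagnostic otherwise; silently differencing unevenly sampled data would
  bias every derived channel.

## The synthetic gesture generator

The generator exists so the full pipeline — transform, feature assembly,
training, cross-day evaluation — is exercisable end-to-end with no
external corpus. It emulates a seated overhand throw with a right-hand
controller:

* **Reach**: one dominant displacement along world X with a min-jerk
  profile `s(u) = 10u³ − 15u⁴ + 6u⁵`, the standard smooth model of human
  point-to-point reaching (bell-shaped speed, high dynamics early, nearly
  stationary ending). A quadratic time warp places the velocity peak at a
  subject-specific fraction of the movement; the warp is smooth, so
  derived accelerations stay bounded. Small lateral and vertical arcs
  (`sin(πs)`-shaped) complete the path.
* **Wrist sweep**: a rotation of subject-specific amplitude
  (N(2.44, 0.26²) rad ≈ 140° ± 15°) about a subject-specific axis near +Y
  (tilt 12–25°), driven by the same profile.
* **Euler-wrap placement**: the base yaw is chosen per subject so the
  composed yaw trajectory crosses the ±π boundary *transversally*, at a
  point where yaw moves at a moderate rate. Centering the boundary on the
  longest moderate-rate segment of the sweep's yaw path maximizes the
  crossing margin; axes whose margin would be too small to survive trial
  noise are rejected and redrawn, exactly as the truncated normal
  parameters are. This makes the baseline POS+EULER representation degrade
  for a *documented, controllable* reason while every gyro channel stays
  smooth (consecutive-sample steps below 1 rad/s at default settings).
* **Subject parameters**: reach amplitude N(0.9, 0.1²) m (truncated above
  0.3), movement duration N(1.4, 0.15²) s (truncated to (0.5, 2.5)),
  velocity-peak fraction 0.3 + 0.4·Beta(2,2), lateral curvature
  N(0, 0.05²) m. Between-subject parameter variance dominates
  within-subject noise, the separability precondition for identification.
* **Trial noise**: white noise low-pass filtered at 2 Hz and rescaled to
  1 cm RMS per position axis and 0.02 rad RMS orientation perturbation.
  Controller tracking error and motor execution variability are
  temporally correlated, hence smoothed rather than white; the scales are
  typical of consumer VR tracking plus human repeat variability at this
  gesture scale.
* **Day drift**: per (subject, day), a multiplicative N(1, 0.05²) factor
  on reach amplitude, movement duration, peak fraction and curvature —
  people move a little differently on another day. The wrist sweep angle
  is kept fixed across days so the wrap calibration is not silently
  undone; the day effect is carried by timing and amplitude.
* **Defaults** mirror the motivating corpus layout: 41 subjects × 10
  trials × 2 days, 3-second recordings at 45 Hz (135 frames).

Everything derives deterministically from one master seed through
fixed-arithmetic sub-stream seeds, so a dataset regenerates bit-for-bit.

What the generator does **not** emulate: device-specific biomechanics
(device is a manifest label only), head or left-hand channels, sensor
error models (bias, scale factor, quantization — the transform produces
ideal signals), postural idiosyncrasies beyond the parameter family above,
and any long-term template aging beyond the two-day drift. Passing tests
on synthetic data therefore demonstrate the *mechanics* of the pipeline
and the direction of the modality effect, not field-grade biometric
accuracy.

## Features and classifiers

Four 3-channel modalities are assembled per trial: POS (raw positions),
EULER (wrapped Z-Y-X angles), ACC and GYRO (transform outputs at the
configured cutoff). Channels are linearly resampled to the model input
length — 128 samples stacked for single-input models, 100 per branch for
the two-branch model. Linear interpolation is used for all channels alike
(resampling happens after transformation, so spherical interpolation of
quaternions never arises); endpoints are preserved exactly and the error
for band-limited signals is bounded by `h²/8·max|f''|`. Per-channel
z-score normalization is fitted on the **training day only** and applied
everywhere; a leakage test verifies that perturbing held-out rows cannot
change the fitted statistics.

Three small 1-D CNN families are provided. Their layer dimensions are this
package's own choices, sized for CPU-scale experiments and recorded in the
model spec so they are overridable:

* *vanilla*: conv 64/128/128 (kernels 7/5/3, each ReLU + max-pool 2) →
  global average pool → softmax;
* *attention*: the same trunk with additive temporal attention pooling
  (scores from a 1-unit projection over time, softmax-weighted sum) — on
  time-constant input the weights are provably uniform, which the suite
  checks;
* *multi-input*: two branches of conv 32/64/64 with **equal kernel counts
  per branch** — so both modalities contribute equally sized feature sets
  at the fusion point — concatenated into a dense-128 ReLU head.

Training is Adam at learning rate 0.01 with categorical cross-entropy for
a fixed epoch budget, no early stopping, no scheduler, no weight decay;
batch size defaults to 32. The learning rate is aggressive for nets this
small but kept as the protocol default, with an override in
`train_config()`. All randomness (Glorot initialization, epoch shuffling)
derives from explicit seeds; training additionally canonicalizes the row
order first, so results are invariant to how the caller happened to order
the trials. A saturated wrong prediction produces an infinite loss, which
the loop reports as divergence rather than continuing silently.

## Evaluation protocol

Models train on all day-1 trials and are scored on day-2 trials of the
same subjects (cross-day validation controls for within-session priming
and muscle memory). Reported metrics:

* **macro F1** — unweighted mean of per-class F1. Macro averaging is the
  deliberate choice: classes are balanced by construction, and macro
  remains interpretable if a user evaluates on an unbalanced subset.
* **One-vs-rest AUC** — per class, the score column against binary
  membership, computed by the rank statistic (equal to the trapezoidal
  area with tied scores counting ½, verified against brute-force pair
  counting). Softmax columns are used as scores. Classes with no positive
  trials are excluded with a warning.
* **One-vs-rest FAR / FRR** — derived from argmax decisions, not a score
  threshold: `FAR_c = FP_c/(FP_c+TN_c)`, `FRR_c = FN_c/(FN_c+TP_c)`,
  averaged without weights. Argmax ties break toward the lowest class
  index. For balanced test sets this definition forces
  `mean FAR = mean FRR/(K−1)` *exactly* (total false positives equal total
  false negatives, and each class's negative pool is (K−1)·n); published
  reference values for multi-input classifiers at K = 41 satisfy this
  identity to their printed precision, which is strong evidence that
  argmax-based FAR/FRR is the right reading, and the suite verifies the
  identity on 1000 random balanced confusion matrices.

Experiment cells (model family × modality) run a configured number of
repetitions with per-repetition seeds derived from a master seed
(`seed + repetition`), and a failing cell records NA rows rather than
aborting the grid.

## Problem sizes

The test suite and the acceptance script run a deliberately scaled
experiment: 10 subjects × 10 trials × 2 days at 45 Hz, 60 training epochs,
3 repetitions for the headline cell. These sizes are the package's choice
for a fast, deterministic desk-scale experiment; chance macro F1 at
K = 10 is 0.1, so cross-day scores well above 0.5 demonstrate genuine
cross-day generalization, and a permuted-label control collapses to
chance. The full 41-subject, 300-epoch, 20-repetition protocol is a
configuration change (`synth_config()`, `train_config()`), not a code
change.

## Known limitations

* The forward difference is first-order; at very low sample rates the
  O(ΔT) bias becomes visible in the acceleration magnitude (the
  centripetal check at 60 Hz recovers 19.72 of 19.74 m/s²).
* Min-jerk templates are smoother than real throws; real data contain
  micro-corrections the generator only represents as band-limited noise.
* The multi-input architecture fuses exactly two branches; three-modality
  fusion would need a head change.
* FAR/FRR from argmax are identification-style metrics; verification-style
  thresholded ROC/EER analyses are out of scope.
* Euler discontinuity handling is diagnostic, not corrective: the package
  demonstrates the artifact and provides the alternative modality rather
  than attempting to unwrap or regularize Euler channels.
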