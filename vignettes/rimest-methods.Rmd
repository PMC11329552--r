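---
title: "Surrogate-based liver motion estimation: methods and design notes"
author: "rimest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-based liver motion estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimest)
```

## The estimation problem

Respiratory-induced motion (RIM) displaces the liver by a few
centimeters, mostly along the superior–inferior (SI) axis, and limits the
accuracy of percutaneous needle procedures. Direct imaging of the target
is impractical for continuous monitoring, so the standard approach is a
*surrogate signal*: an externally observable quantity highly correlated
with the internal motion, plus a *correspondence model* mapping surrogate
to displacement.

`rimest` implements this pipeline with an abdominal-surface surrogate.
The surface is observed as timestamped 3-D point clouds (the output of a
consumer depth camera at ~30 Hz). One frame — the maximum-inhalation
frame — is promoted to reference, and each frame is reduced to the mean
Euclidean distance from its points to their nearest neighbors in the
reference. Because the reference sits at an extreme of the breathing
cycle, every other phase lies on one side of it, so this unsigned
directed distance is a monotone encoding of the breathing phase; a signed
height-axis variant is available behind a flag for sensitivity analysis.
The nearest-neighbor search runs on a kd-tree built once per reference
(`src/`), and equals exhaustive search exactly (a tested invariant).

## Correspondence model

The mapping is a polynomial fitted by ordinary least squares,
$y(x) = \beta_0 + \beta_1 x + \dots + \beta_n x^n$, minimizing
$\sum_i (y_i - y(x_i))^2$. Fitting centers and scales $x$ before forming
powers and solves by QR; the returned $\beta$ is mapped back to the raw
scale exactly (binomial expansion), so coefficients are always reported
in mm per mm$^k$.

**Degree.** The surface–liver relationship is close to affine in the
simulator and in practice; the default degree is 3, enough to absorb mild
curvature without inviting extrapolation pathologies. `selectDegree()`
offers held-out selection over degrees 1–5 but is off by default so that
results stay comparable across sessions.

**Split.** The 70/30 train/test split is *chronologically contiguous* by
default: breathing data are strongly serially correlated, and a random
split would let the test set interleave with training samples,
optimistically biasing held-out errors. A seeded random split is
available (`mode = "random"`, seed mandatory).

**Regimes.** Three training regimes probe intra- vs inter-fraction
variation: *single* (fit on all of session 1, test on each later
session), *specific* (70/30 within one session), *combined* (pool the
70 % train parts of all sessions, fit once, test each session's held-out
30 %). Reports carry MAE (mm) and R² (%, as tables in this field print
it); R² may be negative for out-of-session tests and is reported as-is.

## Ground truth

*Phantom:* the simulated electromagnetic tracker trace is used directly
(40 Hz), resampled onto the surrogate timeline.

*Ultrasound sessions:* binary liver masks (any segmenter can produce
them; network training is out of scope) are post-processed — largest
8-connected component with ties broken toward the earliest row-major
pixel, hole filling, binary closing with a disc (default radius 2 px) —
then the boundary is extracted (foreground pixels with a 4-connected
background neighbor; the image border counts as background). The tracked
coordinate per frame is the mean boundary column inside a user-chosen
ROI that isolates the moving liver border; the median is available as a
robustness flag. Displacement is `(column - column_0) * 0.027 cm/px`
(reported in mm), optionally smoothed by a zero-phase forward–backward
Butterworth low-pass (order 2, cutoff 1 Hz — above the 0.1–0.5 Hz
breathing band, below pixel-quantization chatter). The ROI must exclude
the fixed borders of the structure (for a right-moving edge: the left
edge and the horizontal band boundaries), otherwise static edge pixels
dilute the tracked motion.

Segmentation quality is summarized on a seeded sample of 20 frames per
recording: Dice (%), symmetric Hausdorff distance, and Hausdorff
restricted to the ROI; Hausdorff is computed in pixels and converted with
the isotropic spacing, and both values are reported because published
tables in this area are ambiguous about the unit.

## Synchronization

Both streams move onto the surrogate timeline (the higher-utility
stream); ground truth is linearly interpolated inside the overlapping
support, never extrapolated. Two methods:

* `timestamps` — trust the clocks (phantom case).
* `breathholds` — estimate a constant clock offset from the recording
  protocol's leading breath-hold. Hold windows are found by a sliding
  variance test (window 2 s; threshold adaptive at 5 % of the signal's
  global variance, so it scales with amplitude); a candidate must persist
  at least 3 s, because breathing waveforms with long exhale plateaus
  otherwise register spurious ~2 s "holds" at every cycle trough. The
  hold *end* is then refined to sub-sample precision as the interpolated
  time the signal first departs from its hold level by 25 % of its range.
  Both streams are affine functions of the same breathing shape, so this
  fractional crossing marks the same physical instant in each stream
  regardless of units or sampling rate; without the refinement, the
  15 Hz vs 30 Hz quantization of the hold end (up to 1/15 s) shows up as
  a phase misalignment that depresses every regime's R².

Samples inside hold windows are flagged, not deleted. Fitting skips
flagged samples, and so does scoring: a hold contributes no motion, so
including it would deflate both MAE and the denominator of R² in
offsetting, hard-to-interpret ways.

## The simulator

The simulator provides the study conditions for every test; it emulates:

* **Waveform** — per-cycle shape `sin(pi*u)^4` (raised-cosine power), the
  default because real exhale plateaus are longer than a sinusoid's; a
  pure sinusoid is selectable. Phantom kinematics default to 30 mm SI and
  10 mm AP peak-to-trough at 0.25 Hz. The SI/AP phase relation is
  in-phase by construction; the phantom's true waveform and actuator
  phase are not publicly specified, so both are parameters rather than
  assertions.
* **Sessions** — duration 60 s with flat end-exhale breath-holds of 5 s
  at both ends (the hold phase is a modeling choice; end-exhale is the
  clinically common instruction), surrogate stream at 30 Hz, ground
  truth at 15 Hz (ultrasound) or 40 Hz (tracker). Inter-session drift:
  amplitude scale factors (defaults 1.0/0.9/1.1), baseline shifts drawn
  uniformly within ±3 mm, optional per-cycle period jitter. The baseline
  shift is applied to the internal SI channel only — it models
  inter-fraction drift of the organ relative to the surface, which is
  exactly what the single regime should be penalized by.
* **Surface** — a square grid patch (default 25×25 points over 24 cm)
  with a Gaussian rest bump, elevated 1 mm per mm of internal AP
  displacement, with per-point Gaussian depth noise (default 1 mm sd,
  consumer depth-camera scale).
* **Masks** — a filled band whose right edge column follows
  `rest + round(SI / spacing)`; single connected component, no holes.
* **Subjects** — SI amplitudes drawn uniformly in 20–50 mm (the range
  seen in published per-session liver displacement tables), AP = SI/3
  (the phantom's 30:10 ratio).

Seeding: every session derives its seed from `master seed + session
index`, every noise source from a documented offset of the master seed,
so a dataset regenerates bit-identically.

What the simulator does **not** emulate: hysteresis between surrogate and
internal motion (the correspondence is phase-free by construction, which
is also the published assumption for liver), heartbeat and lateral
motion, ultrasound speckle or B-mode appearance (only binary masks),
camera intrinsics, occlusion, or segmentation failure modes. Passing
tests therefore demonstrate the pipeline's correctness and its behavior
under drift and noise, not performance on real recordings.

## Numerical choices and degenerate inputs

* OLS rejects rank-deficient designs (fewer distinct surrogate values
  than degree + 1) with an error naming the degree; the minimum sample
  count is degree + 1 (exact interpolation is legitimate), while the
  regime runners require degree + 2 per split part.
* R² of a zero-variance ground truth is undefined: NA with a warning,
  MAE still returned.
* Reference-cloud ties break toward the earliest frame; largest-component
  ties toward the earliest row-major pixel; nearest-neighbor ties toward
  the smallest reference row index. All deterministic.
* A contrast stretch of a constant image maps to zeros instead of
  dividing by zero.
* Tracking gaps (no edge pixel inside the ROI) are errors naming the
  frame; interpolation over at most `maxGap` consecutive frames can be
  opted into.
* Filtering is skipped when the cutoff reaches the Nyquist rate or the
  trace is too short for stable forward–backward initialization.

## Problem sizes

The bundled experiments are sized for a desk run: phantom sessions of
60 s at 30 Hz (1800 frames, 625-point clouds), ten-seed phantom
repetitions, and a 6-subject × 3-session cohort (~32 000 synchronized
samples through the full cloud pipeline). The multi-seed regime-ordering
property is checked with the geometry-free surrogate mode (the cloud
stage is validated separately), and one full cloud-and-mask pipeline runs
at reduced scale in the test suite.

## Known limitations

* The surrogate collapses the whole surface to one scalar; it cannot
  separate superimposed motion sources (e.g., cardiac) or detect
  surrogate-internal phase shifts — inherited assumptions of the method.
* Breath-hold synchronization assumes the leading hold is detectable in
  both streams and that the clock offset is constant over a session.
* The mask tracker follows one moving border via the ROI; masks whose
  topology changes frame-to-frame (segmentation dropouts) surface as
  tracking-gap errors rather than being repaired.
* Hausdorff evaluation assumes isotropic pixel spacing.
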