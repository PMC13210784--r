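---
title: "Methods: speckle displacement tracking and apnea-like cessation detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speckle displacement tracking and apnea-like cessation detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `speckleapnea`, the tunable
parameters and why their defaults are what they are, what the synthetic
generator does and does not emulate, and the numerical choices made where
the underlying method leaves latitude.

## 1. Physical model

Coherent light reflected from an optically rough surface interferes into a
speckle pattern. In the far-field regime — observation distance
`Z2 > D²/(4λ)` for illuminated spot diameter `D` — the recorded field is
the Fourier transform of the aperture-limited surface field
`exp(iφ(x, y))`, where `φ` is the random surface phase. A small surface
tilt multiplies that field by a linear phase ramp, which by the shift
theorem translates the whole far-field pattern laterally without changing
its structure. Respiration tilts the chest surface periodically, so
breathing appears as a periodic lateral drift of the speckle pattern.

`optics_config()` enforces the far-field inequality at construction. The
tilt-to-shift conversion is a single calibrated constant, `pixel_gain`
(px/rad, default 4000): the optical proportionality between tilt and
pattern shift is linear in the small-angle regime, but its absolute scale
on the sensor depends on magnification and geometry that the method does
not otherwise need, so one constant absorbs all of it. With the default
breathing tilt amplitude of 1 mrad this yields 4 px of pattern motion —
large against the tracker's sub-pixel resolution, small against the frame.

### Simulator construction

* **Phase screen** (`generate_phase_screen()`): i.i.d. phases uniform on
  `[0, 2π)`, the standard fully-developed-speckle assumption. Deterministic
  per seed.
* **Rendering** (`render_farfield_frame()`): intensity is
  `|FFT(aperture · exp(iφ) · ramp)|²`, normalized to unit mean. The ramp
  route and a Fourier-domain translation of the base pattern are equivalent
  by the shift theorem; the ramp acts on the field, so intensities are
  non-negative by construction and integer shifts are exact circular
  translations.
* **Aperture support** (`aperture_fraction`, default 0.12 of the grid):
  sets the speckle grain size (≈ `1/aperture_fraction` px ≈ 8 px). Real
  hardware in this application often runs near 1 px grains, but a
  three-point parabolic interpolator needs the correlation peak to span
  several samples: at Nyquist-sized grains it under-reports fractional
  shifts by tens of percent, while at the default grain the tracker
  recovers sub-pixel shifts to ~0.003 px and end-to-end amplitudes within
  2%. Users wanting hardware-like grains can raise the fraction and accept
  the interpolation bias.
* **Tilt schedule** (`respiration_schedule()`):
  `α(t) = α₀ sin(2πf_b t + φ₀) · m(t) + drift + noise`. Breath holds
  multiply the envelope down to `residual_fraction` (default 0.02 — chest
  wall motion never stops perfectly) through a 1 s cosine taper at each
  edge; voluntary holds commanded verbally start and stop smoothly, and the
  taper midpoint (half-suppression instant) is the natural ground-truth
  boundary. Drift (default amplitude 10% of `α₀` at 0.02 Hz) models slow
  postural settling; tilt noise (default 1% of `α₀` in the benchmark plan)
  models residual body motion.
* **Camera** (`optics_config()`): additive Gaussian intensity noise with SD
  1% of the mean intensity, optional 8-bit quantization.

### What the generator does *not* emulate

Speckle decorrelation under large tilt (the model is pure translation,
valid in the small-angle regime), cardiac micro-motion, vocal or
blood-flow signals, multiple subjects in the scene, and inter-subject
variability of chest-wall mechanics beyond a posture-dependent amplitude
factor (supine 1.0, lateral 0.8, prone 0.65 — supine breathing presents
the largest chest excursion to the camera). Passing tests on this
generator therefore demonstrates the pipeline's correctness and its
behaviour under controlled SNR, not clinical performance on real chests.

## 2. Displacement tracking

`track()` subtracts a background reference — per-pixel mean of the first
`n_background` frames (default 50, i.e. 0.25 s at 200 Hz: long enough to
average sensor noise, short against a breath cycle) — and cross-correlates
consecutive frames through the frequency domain. An optional moving-average
background mode re-estimates the reference causally; `n_background = 0`
disables subtraction, which is the right setting when measuring the bare
tracker response on synthetic stacks that contain no static scene
component (on such stacks the reference itself is speckle correlated with
every frame and biases the peak).

Numerical conventions:

* The correlation map is re-centered so the grid center is zero shift;
  displacements live in `[-H/2, H/2) × [-W/2, W/2)`. Physiological
  frame-to-frame motion is far below the aliasing limit.
* The peak reports the displacement of the *second* frame relative to the
  *first*, so tracking in time order gives positive `dx` for motion toward
  increasing column indices.
* Ties between equal maxima resolve toward the smallest displacement
  magnitude (physiological prior of small inter-frame motion), then
  smallest row, then column. An all-flat map (e.g. a blank frame) reports
  zero displacement with a warning rather than failing a batch.
* Parabolic refinement is applied independently per axis with circular
  neighbour wrap; a flat three-point neighbourhood (zero curvature) leaves
  the integer location; the offset is clamped to `±0.5` px.

The frequency-domain route is validated in the test suite against an
`O(n⁴)` brute-force spatial correlation oracle to `1e-9` relative error,
and sub-pixel recovery against commanded Fourier-domain shifts.

## 3. Respiratory band isolation

The cumulative horizontal position is filtered with a Chebyshev Type I
bandpass, prototype order 2 (the bandpass transform doubles this to an
overall order of 4 — we read "second-order" as the prototype order, which
matches the sharp transition bands of the published response; the order is
configurable), 0.5 dB passband ripple, 0.2–0.33 Hz. That band corresponds
to 12–20 breaths/min, the typical sleep range; DC gain is exactly zero, so
baseline drift vanishes.

Zero-phase application: the signal is mirror-padded 20 samples per side
(reflection without repeating the boundary sample), filtered forward and
backward, and trimmed. Each pass starts from the filter's steady-state
(unit-step) initial conditions scaled by the first sample; without this the
short pad cannot absorb the startup transient of so narrow a band. The
effective magnitude response is the square of the single-pass response and
the net group delay is zero — event timing is preserved, which matters more
here than amplitude fidelity.

Breath peaks are local maxima with a 2 s minimum separation (larger
amplitude wins among close candidates, ties to the earlier sample); no
height threshold is applied at this stage — low-amplitude stretches are the
cessation detector's business. The breathing rate is
`60 / mean inter-peak interval` in seconds; the inverse orientation is the
only dimensionally consistent reading of the method's description, and it
reproduces commanded rates within 0.5 BPM in the suite. `axis_rms_ratio()`
reports RMS(x)/RMS(y) of the band-filtered axes as the diagnostic for
x-dominance; only x is analysed downstream.

## 4. Cessation detection

`Amax` is the largest breath-peak amplitude of the recording — the
published method uses the global maximum, and we follow it, although a
single exaggerated crest then raises the threshold for the whole recording
(the main false-positive mechanism; `amax_mode` variants such as a
percentile are left for future work). An apnea-like event is a maximal run
of samples with `|x(t)| ≤ THR · Amax` lasting at least `min_event = 10` s
(the clinical apnea minimum; the constructor refuses smaller values).
Equality is included in the comparison: it matters only at the crest that
defines `Amax`, and including it lets the saturated `THR = 1` case form a
single whole-window run rather than splitting at one sample.

Classification: events longer than `max_long = 30` s are whole-window
artefacts of permissive thresholds and are discarded — this one rule
reproduces both the perfect normal specificity and the collapsed
cessation sensitivity observed at high thresholds. Among the remaining
events the longest decides: under 20 s is `short`, 20 s and over is
`long`; the printed class ranges overlap at exactly 20 s and the tie goes
to the more severe class, as a screening context warrants. Run duration is
`(last − first + 1)/fs`. A recording with no detectable breath peaks is
classified `normal` with a warning so batch evaluation never aborts.

## 5. Evaluation

`metrics_from_matrix()` computes flat-count metrics on a 3 × 3
true-by-predicted matrix: per-cessation-class sensitivity counts only
duration-correct detections as true positives; normal specificity is the
normal-class recall (true negatives over all true normals); Macro F1 is
the unweighted mean of per-class F1. `collapse_binary()` folds short and
long into one apnea-like class, absorbing duration confusions into the
true positives.

Two nested five-fold procedures are provided. Subject-wise folds keep all
recordings of a participant together (the shipped default partition is the
published one, test sets of 3/3/3/3/2 subjects); class-stratified folds
shuffle each class independently (deterministic per seed) and deal
round-robin, so per-fold class counts differ by at most one — 23 per class
yields fold sizes 15/15/15/12/12. Threshold selection uses training data
only: each grid value (default {0.15, 0.235, 0.3625, 0.575, 0.7875, 1.0})
is scored on the training recordings and the highest short-cessation
sensitivity wins, long sensitivity breaking ties, the smaller threshold
breaking what remains (tighter thresholds preserve specificity). Because
the detector is deterministic given a threshold, scoring the grid on the
whole training fold is exactly equivalent to any inner resampling over the
same grid, so no inner fold count needs inventing.

Fold summaries report mean, sample SD and `mean ± z·SD/√k` with `z = 1.96`
by default; `z` is configurable because interval conventions differ across
reports and the multiplier is not always stated alongside published
intervals.

## 6. Event-boundary fidelity: a known, quantified limitation

Two mechanisms bound how precisely onset and offset can be recovered from
a threshold crossing of the band-filtered magnitude:

1. `|x(t)|` crests once per half breathing cycle (~2 s at 15 breaths/min),
   so "the last crest above threshold" quantizes crossing times at that
   granularity;
2. the order-4 Chebyshev band is ~0.13 Hz wide and rings for seconds, and
   zero-phase filtering smears that ring-down symmetrically across both
   edges of a hold.

Consequently detected events are systematically shorter than the
scheduled holds by roughly one second per side, with phase-dependent
scatter of a few seconds; the acceptance script measures the resulting
mean absolute boundary error on a zero-noise cohort, and the suite asserts
classification-level behaviour rather than relying on per-boundary
precision. The practical consequences are that holds drawn within a
second or two of the 10 s clinical minimum can fall under it after
shrinkage and be dismissed, and holds near the 20 s class boundary can
change duration class — the same near-boundary fragility the published
validation reports for real recordings. No attempt is made to sharpen
boundaries beyond the method's definition (e.g. by envelope fitting),
because the detector is specified on the thresholded magnitude.

## 7. Problem sizes in the shipped tests

The suite simulates at 64 × 64 px and 50 frames/s (one quarter of the
hardware rate) for end-to-end runs, 16–32 px frames for oracle
equivalences, and signal-level cohorts at 25 Hz for cross-validation
bookkeeping; the benchmark cohort is 30 recordings (10 per class, 60 s).
These sizes keep the full suite within a few minutes while leaving every
quantitative invariant (sub-pixel accuracy, linearity, filter template,
fold structure) at full strength: none of the checked properties depends
on the frame count or frame size beyond the quarter-frame shift bound.
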