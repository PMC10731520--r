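---
title: "Methods: dual-brain mesoscale imaging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-brain mesoscale imaging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(duobrain)
```

This vignette documents the models, parameters and numerical choices behind
`duobrain`, in the spirit of a methods section: what each stage assumes,
which knobs matter, and what the synthetic-session tests do and do not
establish about real recordings.

## The measurement model

Each mouse's camera records two channels from the same optical path. The
green channel measures GCaMP6s epifluorescence: a slow calcium indicator
whose impulse response we model as a difference of exponentials with 0.2 s
rise and 1.5 s decay (`calcium_kernel()`), values taken from the GCaMP6s
kinetics literature and exposed as parameters because the source recordings
do not constrain them directly. The blue channel measures 440 nm
reflectance, close to a hemoglobin isosbestic point: it sees blood-volume
changes but almost no calcium signal. Both channels are converted to
fractional change ΔF/F₀ with F₀ the per-pixel temporal mean of the whole
recording — deliberately including the interaction phase, so a phase with
elevated activity is expressed relative to the same baseline as the rest of
the trial, and no rolling-baseline artifacts are introduced.

Hemodynamic absorption is, to first order, a multiplicative modulation
common to both channels, so in ΔF/F₀ units it is additive and identical in
green and blue; elementwise subtraction of the reflectance ΔF/F₀ removes
it. This subtractive correction assumes equal artifact gain in the two
channels. The rolling-shutter cameras preclude strobed-illumination or
model-based (Beer–Lambert) corrections, which are out of scope here.

## Preprocessing order and filters

The pipeline order is fixed and recorded in each stack's provenance:
ΔF/F₀ → clipping → subtraction → spatial smoothing → temporal band-pass.
Clipping precedes the filters so that rare extreme values (window-edge
pixels, tiny F₀ denominators) cannot smear into their spatiotemporal
neighborhood: GCaMP values are clamped at each pixel's mean ± 3.5 SD,
reflectance at ±15 % ΔF/F₀ — far above physiological reflectance changes,
so it only removes artifacts. The reflectance clip is applied symmetrically
about zero; the text this follows states only the 15 % level, and since
reflectance ΔF/F₀ is zero-mean by construction the symmetric-about-zero and
symmetric-about-the-mean readings are equivalent up to a negligible offset.

Spatial smoothing is a σ = 1 px Gaussian (separable convolution, kernel
truncated at 4σ, reflect padding). The temporal filter is a 4th-order
Butterworth band-pass, 0.01–12 Hz at 28.9 frames/s, applied zero-phase
(forward–backward): correlation and lag analyses downstream must not see
phase distortion, so one-pass causal filtering is not an option. Each
pixel's temporal mean is removed before filtering; DC is outside the
passband anyway, and removing it first eliminates the large edge transients
an 0.01 Hz high-pass pole otherwise produces on non-zero-mean input. The
filter is applied to all pixels at once by a small compiled kernel whose
output matches `signal::filtfilt` to ~1e-7 (asserted in the tests).

Dropped camera frames (~0.1 % of frames, identified from timestamp gaps
larger than 1.5 nominal frame periods) are reconstructed by per-pixel
linear interpolation between flanking frames onto the nominal grid —
adequate because the indicator kinetics are far slower than one frame
period. Cameras are synchronized by the illumination-LED onset: the first
frame whose mean intensity crosses the midpoint between the dark and lit
plateau means.

## Behavior segmentation

Motion energy is the absolute temporal gradient of an ROI's mean pixel
value, smoothed by a σ = 25-frame Gaussian (0.28 s at 90 frames/s, reflect
padding) and thresholded at the mean + 1 SD of the smoothed trace.
Threshold statistics are computed on the smoothed trace; because the
threshold is an affine function of the trace's own statistics, detection is
invariant to rescaling of the energy. Events are maximal supra-threshold
runs, minimum length one sample, no merging. The moving mouse is only in
the behavior frame during the together phase, so its event series carry a
validity mask and all statistics (percent time, cross-correlation, Jaccard)
use pairwise-complete samples; windows with more than 5 % incomplete
samples trigger a warning. Cross-correlations are computed on the 90
frames/s behavior clock with overlap-only normalization per lag; the
default ±30 s lag range covers the slow envelope of interactive
coordination.

An inherent detectability limit: bouts shorter than the smoothing kernel
are attenuated below threshold. With exponential bout durations a
corresponding fraction of ground-truth bouts is unrecoverable by *any*
mean+SD detector at this smoothing width, so the recovery test compares
detected counts against ground-truth bouts at least one kernel sigma long.

## Registration

Three key-points (bregma, a point on the superior sagittal sinus 4 mm
posterior, and the olfactory-bulb/frontal boundary ~3.2 mm anterior) sit
on or near the midline, so a general affine fit is ill-posed. We fit a
similarity transform (rotation + isotropic scale + translation, no shear)
by complex least squares on `z_px = α·(ML − i·AP) + β`, which flips the AP
axis into the image row direction and remains well-posed for collinear
points; the bregma→sinus axis maps onto the atlas midline by construction.
The ten region coordinates shipped in `default_regions()` are editable
defaults at standard Common Coordinate Framework positions — configuration,
not measured values, since no coordinate table is available. Region traces
are the per-frame median of the 5×5-pixel block at each placed location;
seed-pixel correlation maps (same 5×5 median seed) verify placement on
synthetic sessions by peaking at the generator's blob centers.

## Interbrain statistics

The global signal is the per-frame spatial *median* over masked pixels —
robust to residual hot pixels. Phase correlations use a 60 s analysis
window *centered* in each phase (the window position within the phase is
not otherwise constrained; centering avoids translation-edge effects).
Correlations are Fisher z-transformed (atanh) wherever averaged or
compared. The trial-shuffle null pairs mouse A of trial i with mouse B of
trial j over all unordered pairs i < j, giving n(n−1)/2 values — 595 at
n = 35, the combinatorial reading consistent with that printed count
(ordered pairs would give 1190). Trials entering the null must be
independent draws; the test fixtures assign distinct seeds to every
simulated trial for exactly this reason.

Time-varying coherence uses 45 s windows with 22.5 s overlap and DPSS
multitapers, time-bandwidth 5 with 9 tapers, computed by the standard
symmetric tridiagonal eigenproblem (solved tapers are cached per window
length). Within a window the estimate is |Σₖ S_ab|² / (Σₖ S_aa · Σₖ S_bb),
summing cross- and auto-spectra over tapers, which is bounded in [0, 1]
and has a bias floor of ~1/K for independent signals — the tests check
independent noise lands near that floor, well below 0.5.

## Encoding model

Event variables expand into time-lagged indicator columns on the neural
clock: behavior and stage-translation events cover lag 0 up to 2 s
(`ceiling(2·fs)` columns), approach covers the 5 s before its event, leave
the 5 s after. Kernels are zeroed across trial boundaries. The stationary
mouse's whisker bouts are split into "alone" and "together" context
variables by the phase at bout onset. Neural data are mean-centered per
pixel and reduced to the top 200 singular triplets via the Gram-matrix
eigendecomposition; ridge coefficients have the closed form
(XᵀX + λI)⁻¹XᵀY with an unpenalized intercept.

Cross-validation uses contiguous time blocks, not random samples, because
the 0.01–12 Hz signals are strongly autocorrelated and random folds would
leak. Per-pixel R² pools the squared error over the 10 folds (the mean of
per-fold R² is also reported; the pooled version is the headline map).
Pixel-level error sums are obtained through the spatial components as
k×k quadratic forms, so no time×pixels prediction matrix is materialized.
λ defaults to a grid search over {0.1, 1, 10, 100, 1000} on a contiguous
validation split (the final 10 % of samples), and can be fixed.

Unique contributions permute a variable by circularly shifting its event
train by a seeded random offset and re-expanding the lags, preserving the
kernel structure (independent per-column shuffles would break it). Two
properties of permutation ΔR² worth knowing: where the total variance is
negligible, cross-validated R² is ill-conditioned and ΔR² with it; and the
permuted block can overfit, pushing the reduced model below the mean
predictor so that ΔR² exceeds the full R² by roughly p/n (block columns
over training samples). Both effects shrink with recording length and
larger λ and are bounded explicitly in the tests.

## The synthetic session generator

The generator emulates the statistical structure the analysis assumes, with
defaults set to the standard acquisition conditions: 28.9 frames/s brain
cameras, 90 frames/s behavior camera, the 2 min / 27.5 s / 2 min / 27.5 s /
2 min phase schedule (415 s total), 0.1 % dropped frames. Where the
conditions are not documented we chose once, on field-typical grounds:
bout onsets as a 0.1 Hz Poisson process per channel (a few whisking or
forelimb bouts per minute) with exponential 2 s mean durations (~20 %
activity duty cycle); peak bout response 5 % ΔF/F₀ on Gaussian region
footprints (σ = 3 px at 64×64, scaled with image size) placed bilaterally
through the package's own registration; a diffuse cortex-wide response at
30 % of the regional gain, because movement engages broad dorsal cortex and
the *median* global signal would otherwise barely see a small somatotopic
blob; a shared slow hemodynamic artifact (low-pass filtered noise,
< 0.1 Hz, 1 % ΔF/F₀) injected identically into both channels *and both
mice* — the worst case for interbrain analysis if correction fails; and
2 % per-pixel sensor noise.

Social structure enters through one pathway by default: during the
together phase only, each stationary-mouse bout triggers a moving-mouse
bout with probability `coupling` at a uniform 0–1 s lag. The lag model is a
stand-in for seconds-scale behavioral coordination, not an estimate of its
distribution. A second, optional pathway (`partner_gain`) drives a mouse's
own barrel cortex directly from the partner's together-phase bouts —
touch-evoked activity — and is what the encoding analyses switch off to
emulate mesh-barrier sessions. It defaults to 0 so that
uncoupled sessions show chance-level interbrain correlation.

Because bout responses are rendered by convolving bout *onsets* with the
unit-peak calcium kernel, a single noiseless bout reproduces the analytic
kernel exactly (a test fixture), and bout duration does not scale the
transient. Behavior ROI traces fluctuate frame-to-frame for the duration of
a bout so that gradient-based motion energy is sustained across it. In GFP
mode the response gains are forced to zero while the artifact remains: the
control in which any surviving interbrain correlation is artifactual.

What the generator does *not* emulate: photon physics and optics,
vocalizations, freely moving behavior, spatially structured hemodynamics,
breathing/heartbeat rhythms, slow drift, or motion artifacts. Passing tests
therefore demonstrate that the pipeline recovers the intended statistical
structure under its own assumptions — not that those assumptions exhaust
real recordings.

## Problem sizes and numerical notes

Simulation-heavy checks run full-length 415 s sessions at reduced spatial
resolution: 16×16 pixels for global-signal statistics (the global median is
a spatial aggregate, so resolution is immaterial to it) and 32×32 for the
encoding localization checks, where the driven-region footprint must be
resolvable; registration checks run at the full 256-px geometry. Cohort
sizes are 20 GFP sessions and 10–15 sessions per coupling level, with every
simulated trial seeded independently. Single-trial phase correlations of
slow band-limited signals are wide (null sd ~0.15, matching real
recordings), so coupled-vs-null contrasts are distribution-level tests;
the strict single-trial 97.5th-percentile exceedance is reached at full
coupling.

Numerical details worth recording: ΔF/F₀ of the whole recording makes every
pixel exactly zero-mean, so the band-pass sees no DC step; the Butterworth
poles at 0.01 Hz have radius ~0.9992 and the direct-form filter stays
stable in double precision; eigen-decomposition Gram matrices are clamped
at zero before taking square roots; correlations return NA (not an error)
for constant windows; the Jaccard index is defined as 0 for an empty union;
and all permutations, simulations and fold splits are reproducible
bit-exactly from integer seeds.

## Known limitations

- Subtractive hemodynamic correction assumes equal artifact gain in both
  channels; wavelength-dependent gain differences would leave a residual.
- Key-point similarity registration cannot capture shear or nonlinear
  window distortion; functional mapping would align better.
- The default region coordinate table is a placeholder at standard atlas
  positions, meant to be replaced per preparation.
- The 60 s phase windows and the centered placement are conventions; very
  slow coupling (< 1/60 Hz) is invisible to them.
- Permutation ΔR² is biased where total variance is negligible (see above);
  interpret maps jointly with the full-model R².
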