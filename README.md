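# duobrain

Analysis of simultaneous widefield ("mesoscale") GCaMP calcium imaging from
two interacting head-fixed mice, from raw dual-channel image stacks to
interbrain synchrony statistics and a behavioral encoding model.

## The problem

Pairs of head-fixed mice are imaged through transcranial windows while a
motorized stage brings them whisker-to-whisker: a trial runs *separate →
translate → together → translate → separate* (2 min / ~27.5 s / 2 min /
~27.5 s / 2 min). Each brain camera records RGB frames at 28.9 frames/s in
which the green channel carries GCaMP6s epifluorescence and the blue channel
near-isosbestic (440 nm) reflectance; a 90 frames/s camera films whiskers
and forelimbs. The scientific questions: do the two cortices synchronize
when the mice interact, in which frequency band, and which behavioral events
(own movements, partner movements, trial events) explain the cortical maps?

`duobrain` implements the full pipeline:

1. **Preprocessing** — LED-onset synchronization across cameras,
   dropped-frame interpolation, per-pixel ΔF/F₀ = (F − F₀)/F₀ with F₀ the
   whole-recording temporal mean, extreme-value clipping (mean ± 3.5 SD per
   pixel for GCaMP, ±15 % ΔF/F₀ for reflectance), hemodynamic correction by
   elementwise subtraction of the reflectance ΔF/F₀ from the fluorescence
   ΔF/F₀, Gaussian spatial smoothing (σ = 1 px) and a zero-phase 4th-order
   Butterworth band-pass (0.01–12 Hz).
2. **Behavior** — ROI motion energy |x(t+1) − x(t)|, Gaussian smoothing
   (σ = 25 video frames), thresholding at mean + 1 SD into binary event
   series; percent time behaving, lagged cross-correlation, Jaccard index.
3. **Registration** — least-squares similarity transform from three
   anatomical key-points (bregma, superior sagittal sinus, olfactory-bulb/
   frontal boundary) to atlas coordinates; placement of ten named cortical
   regions (ALM, M2, wM1, aBC, pBC, HL, FL, lPTA, RS, V1).
4. **Interbrain statistics** — global signal (spatial median ΔF/F₀ over the
   masked cortex), per-phase Pearson correlations over 1-min windows with
   Fisher z = atanh(r), the trial-shuffle null (all n(n−1)/2 cross-trial
   pairings), 10×10 inter/intrabrain region correlation matrices from 5×5-
   pixel median traces, seed-pixel maps, and sliding-window multitaper
   coherence (45 s windows, 22.5 s overlap, time-bandwidth 5, 9 DPSS
   tapers).
5. **Encoding model** — event-kernel design matrix (2 s post-event lags for
   behavior/translation, 5 s pre/post for approach/leave), SVD reduction of
   the masked stack to 200 components, ridge regression
   B̂ = (XᵀX + λI)⁻¹XᵀY, per-pixel explained variance R² under contiguous
   10-fold cross-validation, and each variable's unique contribution
   ΔR² = R²(full) − R²(variable permuted).
6. **Synthetic sessions** — a generator with known ground truth (Poisson
   behavior bouts, probabilistic cross-mouse triggering active only in the
   together phase, GCaMP6s-like double-exponential transients on region
   footprints, a shared slow hemodynamic artifact in both channels, sensor
   noise, dropped frames, an activity-independent "GFP" control mode), so
   every stage is testable without data downloads.

## Worked example

```r
library(duobrain)
params <- session_params(image_size = 32L, seed = 42L, coupling = 0.6)
sim    <- simulate_session(params)          # two mice, known ground truth
pre    <- preprocess_session(sim$session)   # corrected dF/F0 stacks
events <- session_behavior_events(pre)      # binary whisker/forelimb bouts
ib     <- interbrain_analysis(pre)          # correlations + coherence
ib
```

```
Interbrain synchrony results
     phase      signal    pcc fisher_z
 separate1   corrected -0.191  -0.1932
 separate1 uncorrected  0.550   0.6187
  together   corrected  0.169   0.1701
  together uncorrected  0.683   0.8349
 separate2   corrected  0.063   0.0631
 separate2 uncorrected  0.715   0.8970
```

Reading this: the *uncorrected* green-channel signals correlate in every
phase (~0.55–0.72) because both mice carry the same slow hemodynamic
artifact — exactly the confound reflectance subtraction exists to remove.
After correction, the correlation survives only in the together phase
(0.17 here; single-trial phase correlations are noisy, which is why the
cohort statistics below average many sessions and compare against a
trial-shuffle null). The per-region change in interbrain correlation
(together − before), averaged against all partner regions:

```r
round(ib$matrices$delta_row_mean, 3)
#   ALM    M2   wM1   aBC   pBC    HL    FL  lPTA    RS    V1
# 0.235 0.269 0.301 0.295 0.185 0.286 0.314 0.242 0.276 0.227
```

The encoding model is fitted the usual way for an R model object:

```r
fit <- encoding_model(pre, events, k = 200, folds = 10)
summary(fit)          # per-variable unique contributions (delta R^2)
plot(fit)             # cross-validated R^2 map
plot(fit, "partner_whisk_together")
```

A thin CLI wraps the same functions:
`Rscript inst/scripts/duobrain.R run-all --seed 1 --out out/`.

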