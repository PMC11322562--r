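---
title: "Respiratory surrogate extraction from dynamic PET: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory surrogate extraction from dynamic PET: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgate)
```

## The signal model

A dynamic PET acquisition is unlisted into a time series of low-resolution
sinograms `S_t` (radial × angle × plane × TOF bins) at 500 ms frames,
rebinned to 2 Hz — fast enough for respiration (0.1–0.4 Hz in most
patients) while averaging out cardiac motion near 1 Hz. Respiratory motion
displaces structures and modulates the counts in bins that see their edges;
tracer kinetics rescale whole regions; Poisson noise sits on everything.

All extractors in this package share one readout: a *component* `PC` — a
weight map over sinogram bins — applied frame-wise,

$$W_t = \sum_{\text{bins}} PC \cdot S_t,$$

and they differ only in how the component is obtained. The modelling
assumptions are: respiration is quasi-periodic with a stable spatial
signature over the time span used to estimate the component; kinetics are
spectrally slow (mostly below 0.1 Hz) over the scoring span; and the
transformed counts are near-Gaussian so that PCA's variance objective is
meaningful.

## Pre-processing

Raw counts are Poisson, so variance tracks the mean and PCA would weight
bright bins by brightness rather than by motion. Two element-wise
transforms Gaussianise the data:

1. Freeman–Tukey, `FT(X) = √(X+1) + √X`, stabilises Poisson variance to ≈ 1
   over means from a few counts upwards.
2. Yeo–Johnson with a single global power `λ`, fitted by minimising the KL
   divergence from the histogram of transformed values to the matched
   Gaussian over `λ ∈ [−2, 2]` in steps of 0.05.

Numerical choices in the fit: values are standardised before histogramming
(KL divergence is affine-invariant, and a common scale keeps the bin count
comparable across `λ`); the Freedman–Diaconis bin width is floored at 2.5×
the median spacing of distinct values, because transformed *counts* are
discrete and narrower bins produce a comb histogram with a flat, noisy
objective; the Miller–Madow correction removes the occupied-bin bias. With
these choices the fitter recovers `λ ∈ {0, 0.5, 1}` exactly (to the grid
step) on data constructed through the inverse transform, and gives `λ ≈ 1`
for Freeman–Tukey-transformed Poisson(50) data, which is already
near-Gaussian. Note one subtlety of the four-branch transform: `λ = 0` is
the log branch only for non-negative values — data spanning zero is *not*
Gaussianised by `λ = 0` even when `log(1 + x)` of its positive part is.

A mask then removes the bottom 5 % of the time-mean sinogram (mostly
background); the threshold is computed on the time-mean so one mask serves
every frame, and bins strictly above the threshold are kept (`percentile =
0` keeps everything; a degenerate all-equal sinogram falls back to keeping
everything with a warning). Finally a separable Gaussian (defaults
σ = 1.0, 0.5, 2.0 bins over radial, angle, plane for the PCA methods;
1.0, 3.0, 1.0 for signed-mask methods) with reflect boundaries smooths each
frame, and linear interpolation halves the radial and plane axes — after
smoothing the dropped resolution carries no extra information, and the
smaller matrices make the SVDs cheap. The order is transforms → mask →
smoothing; the mask is carried through the downsampling by
nearest-neighbour resampling.

## The extractors

**Conventional.** SVD of the centred (time × masked-bins) matrix of the
whole record; each of the top 10 right-singular vectors is applied via the
readout above and scored by the mean spectral magnitude inside the fixed
respiratory band (0.1–0.4 Hz); the best signal wins. Ten candidates is a
pragmatic default: enough to look past kinetic components, few enough that
pure-noise components rarely win the band score.

**Moving window.** The record is cut into windows that overlap their
predecessor by half; each window is extracted independently (the
conventional method within the window, or a spectral-analysis signed mask),
NaN-padded to full length, sign-matched to the previous window by the
correlation over their overlap (each window's sign is arbitrary), and
averaged ignoring NaNs. Two design points deserve justification:

- *Per-window score selection.* The window extraction scores the window's
  top components and keeps the best, exactly as the whole-record method
  does; taking the first component blindly fails mid-record, where residual
  kinetic drift still out-varies breathing.
- *z-normalised averaging.* Window signals are z-scored before the
  NaN-mean. A component signal's amplitude scales with the window's data
  variance, so raw averaging lets early, kinetics-dominated windows swamp
  their quieter neighbours in the overlap regions — on realistic phantoms
  the raw-averaged trace is unusable (mean early correlation ≈ 0.08 vs
  ≈ 0.5 z-scored). `normalize = FALSE` restores raw averaging.

The default schedule uses 60 s windows up to 62 % of the record, growing
linearly to 120 s at the end — small early windows limit how much kinetic
variance a window sees, long late windows reduce noise. The final window is
re-anchored to end exactly at the last frame.

**Late-time interval.** PCA on the frames after a cutoff (default 62 % of
the record, ≈ 520 s into a 14 min acquisition), where kinetics have largely
settled; the best-scoring late component is applied to *all* frames.
Breathing is semi-consistent over an acquisition, so a component that
captures it late captures it early too — while early kinetic leakage
through the fixed weights is spectrally slow and removed by the bandpass.

**Score–Select–Combine.** The late-time signal initialises an adaptive
respiratory band: the band centre is the spectral centroid of the initial
signal's magnitude spectrum and each bound sits half a power-weighted
standard deviation away (a full standard deviation between the bounds).
Two robustness choices matter at low counts:

- The centroid is computed on the *late segment* of the initial signal (the
  segment its component was fitted on); the early part still carries
  kinetic leakage that drags the centroid below the breathing peak.
- The spectrum is noise-floor-subtracted before taking moments. White-noise
  spectral magnitudes are Rayleigh distributed, so the floor is the
  Rayleigh 95 % quantile with σ estimated from the spectrum median;
  without it the broadband floor of a sparse-count signal pulls the
  centroid toward mid-band and the estimated window can miss the breathing
  peak entirely. The subtraction is frequency-symmetric, so the moments of
  a genuinely flat spectrum are unchanged in expectation.

Every whole-record component is then scored by the ratio product
(respiratory/kinetic) × (respiratory/noise) of mean band magnitudes —
scale-invariant, so bright components enjoy no advantage — thresholded
(strictly above 0 for the frequency scorer; 0.5 for a pluggable `[0, 1]`
scorer), sorted descending with ties kept in component order, and combined
greedily: each further component is added *and* subtracted (both sides
weighted by their scores; the two signs absorb the arbitrary component
orientation), the candidates are rescored, and the better one replaces the
running best only if it improves the score strictly — "strictly" enforced
up to a 10⁻⁹ relative tolerance so a proportional signal cannot be accepted
on floating-point jitter. A `+Inf` score sentinel (empty kinetic or noise
band) falls back to equal combination weights. The pluggable scorer slot
takes any function mapping a signal to `[0, 1]`; the shipped stand-in is a
logistic squash of the log frequency-ratio score, transparent and
dependency-free.

## Post-processing

Applied in fixed order to every extracted trace: parallel compression →
quartile outlier repair → bandpass → Savitzky–Golay.

*Parallel compression* splits the trace into an untouched channel and a
compressed channel divided by `(envelope/reference)^(1−1/ratio)` — the
envelope is a smoothed running maximum of the absolute trace, the reference
its median — then mixes the two (default mix 0.5, ratio 4). Amplitude
excursions from residual kinetics shrink; breath-to-breath shape survives
in the uncompressed channel.

*Outlier repair* replaces samples outside `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`
with linear interpolation between the nearest inliers (boundary outliers
take the nearest inlier value). Quartile fences always contain the central
half of the data, so the documented refuse-if-majority-outliers guard is
defensive only. Repair is idempotent in practice: interpolated values lie
inside the inlier range, so re-computed fences contain them.

*Bandpass*: the ideal kernel `h(t) = 2B_H sinc(2B_H t) − 2B_L sinc(2B_L t)`
(defaults 0.1–0.4 Hz) sampled at the trace rate, truncated at ±8/B_L
seconds and tapered with a Hann window — unity at the centre so
`h(0) = 2B_H − 2B_L` exactly; convolution uses edge reflection and the
symmetric kernel makes the filter zero-phase. At the defaults the measured
in-band gain at 0.25 Hz is 1.00 and attenuation at 0.02 Hz exceeds 90 dB.

*Savitzky–Golay* (order 3, window 5) promotes local smoothness while
reproducing cubic segments — and hence respiratory peaks — exactly.

The whole chain is phase-preserving: interpolated zero-crossing times of a
clean sinusoid move by less than one sample end to end.

## Evaluation

Traces are compared by Pearson correlation after linear resampling to a
common 2 Hz grid: over the usable record (20–840 s by default; the first
20 s of a dynamic scan hold essentially no counts), over the first usable
120 s (20–140 s), and in 20 s intervals. Because a data-driven trace's sign
is arbitrary, the extracted trace is globally flipped when the full-record
correlation is negative, and the flip is reported. Correlations are
computed on raw values (Pearson r is affine-invariant); z-normalisation is
used for plotting only.

## The phantom: what it emulates, and what it does not

The simulator provides ground truth for every stage: ellipsoidal regions
with soft (≈ 1.5 voxel) edges standing in for scanner resolution; a
first-pass redistribution chain of time-activity curves (right heart →
lung field → arterial pool, sharp bolus-washout forms with transit delays,
plus slow tissue uptake) entering 20 s after scan start; rigid axial
displacement of all regions by a quasi-periodic trace with per-cycle
frequency and amplitude jitter, optional drift and breath holds; a
nearest-neighbour ray-summation projector into (radial × angle × plane)
bins, with optional TOF bins filled by a fixed Gaussian along-ray profile;
and Poisson counts. Sub-voxel displacement is handled by linear
interpolation, implemented exactly as a convex combination of
integer-shifted projections, which makes the simulator fast and the
expected-count model analytic (mass conservation and Poisson-mean checks in
the test suite exploit this).

Default conditions are a scaled-down version of a dynamic thoracic FDG
study: 1680 frames of 500 ms (14 min), injection at 20 s, breathing at
0.2–0.3 Hz with ~8 % cycle jitter and a 0.8 voxel (~7.5 mm, shallow
breathing) amplitude, and ~250 expected counts per frame over ~3000 bins.
That count density (≈ 0.1–1 counts per bin) matches real low-resolution
gating sinograms; a miniature phantom cannot match both per-bin density and
total counts, and the per-bin density is what sets the operating point —
early respiratory information near the detection threshold. In this regime
the phantom reproduces the qualitative phenomenon the extractors exist for:
whole-record PCA loses the early signal (mean early-window |r| ≈ 0.1–0.45
across seeds), the moving window partially recovers it (≈ 0.4–0.55), and
the late-time and score–select–combine methods recover it almost fully
(≈ 0.85–0.93).

What the phantom does *not* emulate: attenuation, scatter, randoms,
realistic scanner geometry; cardiac motion; non-rigid deformation and
hysteresis; bulk patient motion; spatially continuous kinetic
heterogeneity. Passing the phantom bank therefore demonstrates correct
mechanics and the expected failure mode of whole-record PCA under kinetics
and sparse counts — not clinical performance on patient data, where
irregular breathing and the confounds above make all methods worse.

## Problem sizes and runtime

The test suite runs the full bank comparison on five 14-minute phantoms
(4 methods each, ≈ 45 s total) plus module tests on small constructed
series; the acceptance script repeats the bank (five methods) and the
transform/filter diagnostics in ≈ 35 s. SVDs after downsampling are
1680 × 768 at most, so no compiled code is needed.

## Known limitations

- The moving-window sign chain can still break across a stretch of windows
  with no extractable signal (e.g. during the bolus); signs downstream of
  such a stretch are effectively re-randomised. The method's averaging
  limits the damage but cannot undo it.
- The adaptive respiratory window assumes the late-time initial estimate is
  usable; if breathing is absent or far outside 0.02 Hz–Nyquist the
  estimate falls back to the fixed bands with a warning.
- The signed-mask (SAM) engine needs a per-bin spectral peak to clear its
  inclusion threshold and can legitimately find no qualifying bin in very
  sparse windows; the moving-window driver skips such windows with a
  warning.
- A single global Yeo–Johnson λ is fitted; per-bin powers are possible in
  principle but not implemented.
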