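---
title: "Methods: super-resolution ultrasound localization microscopy at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-resolution ultrasound localization microscopy at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulmr)
```

## The processing model

Ultrasound localization microscopy (ULM) reconstructs microvascular maps far
below the diffraction limit by localizing individual circulating microbubble
contrast agents across many ultrafast frames and linking their positions into
trajectories. `ulmr` implements the full chain on complex beamformed
in-phase/quadrature (IQ) frame stacks:

1. **Clutter filtering.** The stack `[depth, lateral, frames]` is reshaped
   into a Casorati matrix (space x time) and decomposed by SVD. Tissue echo is
   30-60 dB stronger than bubbles but spatiotemporally coherent, so it
   concentrates in the lowest-order singular components; zeroing components
   `1..k` and inverting the SVD leaves the flowing-bubble signal. The cutoff
   `k` is chosen adaptively at the elbow (maximum convex curvature) of the
   log10 singular-value decay, clamped to `[5, 30]` by default — on realistic
   scenes this removes on the order of the first 10-20 components. A
   depth-dependent noise profile — by default a low (10th-percentile)
   per-row amplitude quantile of the clutter-filtered stack, which stays on
   the noise floor even when a vessel's point-spread tails cover most of a
   row, smoothed over 5% of the depth rows; a trailing-singular-component
   surrogate is available but under-represents high-noise rows for strongly
   depth-colored noise —
   equalizes bubble intensity over depth (amplitude equalization; the profile
   is returned so a power profile can be reconstructed).

2. **Separation filtering.** At practical bubble concentrations detections
   overlap, so the filtered stack is split in the temporal-frequency domain
   into sparser subsets: by Doppler sign (axial flow direction) and optionally
   by speed band. The transfer functions form a partition of unity, so the
   subsets sum back to the input exactly and no energy is invented or lost.

3. **Localization.** Each subset frame is spline-interpolated (separable
   cubic, exact for cubic polynomials) onto an isotropic 4.928 um grid whose
   samples are registered so native pixel centers land exactly on
   super-resolved pixel centers. A zero-normalized 2D cross-correlation with
   an empirical Gaussian PSF model yields a correlation map; detections are
   regional maxima above a correlation threshold (default 0.5) that also pass
   an amplitude gate (normalized correlation is amplitude-blind; see below),
   optionally refined to subpixel positions by a least-squares quadratic fit
   of the log-correlation peak over a 5x5 neighbourhood.

4. **Tracking.** Detections are paired frame to frame by maximum-weight
   bipartite matching under a speed gate (default 50 mm/s): the pairing
   maximizes the number of links within the gate and, among those, minimizes
   the summed displacement. Tracks shorter than 20 frames (20 ms at 1000 Hz)
   are discarded. Per-track speed is the mean frame-to-frame displacement
   times the frame rate; tortuosity is the sum-of-angles metric (SOAM): the
   summed unsigned turning angle divided by path length, in deg/mm, together
   with the distance metric (path length over end-to-end distance).

5. **Mapping and quantification.** Tracks rasterize into density / mean-speed
   / direction channels on the super-resolved grid (line deposition between
   consecutive centroids, so slow vessels fill in); acquisitions are
   registered to the first by integer-pixel normalized cross-correlation of
   the density maps before merging. Regional metrics per ROI: blood volume
   (mean distinct tracks entering the ROI per acquisition), vascularity
   (percent of ROI pixels with density above a 1-traversal binarization
   threshold), track-averaged velocity and SOAM, K-means stratification of
   the log-density into 6 clusters (top 2 = large vessels), intervessel
   distance (twice the mean distance-transform value over non-vessel ROI
   pixels), and the adjusted Fisher-Pearson skewness G1 of the per-track
   speed distribution. Diffraction-limited comparators (power Doppler,
   ROI contrast power, Loupas autocorrelation color flow) are included.

6. **Statistics.** Cohort tables (subject x region x metric) are tested by
   two-way ANOVA (age group x region; Type II sums of squares, appropriate
   for unbalanced cohorts) with Tukey HSD post-tests on the age contrast
   within each region, by OLS regression of each metric on age (weeks) and
   sex, and by a Welch t-test on per-subject velocity skewness. An optional
   per-subject `qc_pass` flag in the metrics table (for acquisitions excluded
   by quality control, e.g. an animal lost during imaging) is honored by the
   aggregation: flagged rows never enter a model.

## The synthetic scene simulator

Matched in vivo acquisitions — ultrafast contrast-enhanced imaging of young
and aged mouse brains — are not publicly available, so `ulmr` ships a
simulator that emulates their statistical structure with full ground truth;
every pipeline stage is validated against it.

A scene is a set of vessels (straight, sinusoidal, or polyline centerlines;
radius; plug-flow speed — a parabolic profile is available; axial flow sign;
Poisson bubble arrival rate) on a native grid. A simulated acquisition
contains:

* **Bubbles**: Poisson arrivals per vessel, advected along the centerline,
  rendered as an anisotropic Gaussian PSF (defaults sigma_ax = 60 um,
  sigma_lat = 100 um, typical of a 20 MHz linear array) times the carrier
  `exp(-1i * 4 * pi * f0 * (z - zb) / c)`. The phase advances with axial
  position at the round-trip wavenumber and rotates in slow time as the
  bubble moves, so autocorrelation (color-flow) estimators see the correct
  Doppler shift; motion away from the transducer gives positive Doppler
  frequency and positive Loupas velocity.
* **Tissue**: a spatially correlated static complex field (default +30 dB
  above bubble amplitude), optionally drifting sinusoidally in-plane
  (respiration-like, ~1.5 Hz) by a configurable amplitude.
* **Noise**: circular white noise whose amplitude grows with depth at a
  configurable dB/mm slope (default 30 dB below the bubbles at the surface),
  emulating depth-dependent SNR loss; this is what the noise-equalization
  profile corrects.

The acquisition constants default to a typical ultrafast mouse-brain
protocol: 20 MHz center frequency, 1000 Hz compounded frame rate, 1600 frames
per acquisition, 80 acquisitions per imaging plane, 4.928 um super-resolved
pitch. The native (pre-interpolation) pitch defaults to 49.28 um so the
super-resolved grid is an exact x10 upsampling.

**Cohort presets.** `preset_cohort()` builds a "young" scene — a band of
near-columnar cortical vessels over a band of deep horizontal vessels, with
per-vessel lognormal speeds (mean 9 mm/s, sdlog 0.35) and sinusoidal
tortuosity (amplitude 20 um, wavelength 600 um) — and an "aged" scene that
differs by documented multiplicative contrasts: cortical vessel count x0.7,
all speeds x0.8, tortuosity amplitude x1.5, and a heavier-tailed speed
assignment (sdlog 0.55). Speeds are drawn mean-preservingly
(`S0 * exp(sigma * z - sigma^2 / 2)`) from the same per-vessel normal draw in
both groups, so the aged/young expected-speed ratio is exactly the speed
factor and the heavier tail raises skewness without moving the mean.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: nonlinear bubble oscillation and size dispersion,
out-of-plane motion and elevational beam thickness, aberration and
reverberation clutter, non-rigid tissue motion, hematocrit-dependent bubble
clustering, and real vascular topology (trees, anastomoses). Contrasts
recovered on synthetic cohorts demonstrate that the *pipeline* preserves
them, not that mice show them.

## Numerical choices and caveats

* **Slow-flow suppression.** An SVD clutter filter removes whatever is
  temporally coherent over the acquisition window. A bubble moving much less
  than a PSF width within the window is partially removed with the tissue;
  at 2 mm/s a useful window is >= 1 s (a full 1600-frame acquisition).
  The velocity-recovery checks therefore isolate localization + tracking:
  clutter-free plug-flow scenes over up to 1600 frames, with the
  clutter-coupled behaviour validated separately (suppression checks and the
  end-to-end cohort).
* **Localization guards.** Normalized correlation is amplitude-blind, so
  detections must also exceed an amplitude gate (default 5x the median frame
  amplitude) — otherwise low-amplitude smooth clutter residue shaped like
  the PSF produces jittery ghost tracks that dominate slow-flow statistics.
  Detections whose correlation window is clipped by the frame edge are
  dropped: the zero-padded normalization biases those positions inward,
  which compresses apparent speeds near the boundary. The matching window is
  2.5 sigma (tighter than the rendered 3.5 sigma support) to limit
  normalization interference between bubbles a few sigma apart.
* **Quantization and step speeds.** Centroids quantized to the 4.928 um grid
  make the summed step length of an oblique track exceed its true length
  (staircase effect), biasing speeds upward; subpixel parabolic refinement
  reduces this to the localization-noise floor. The residual noise-induced
  bias on the mean step speed is about `sigma_loc^2 / displacement` per
  frame, which is why velocity tests at 2 mm/s are run in the high-contrast
  regime (50 dB bubble SNR) where `sigma_loc` is ~0.1 um.
* **Tortuosity conditioning.** SOAM on raw quantized centroids is dominated
  by turning-angle noise for slow tracks. The pipeline smooths track
  geometry with a 5-frame moving average and resamples it at 15 um arc
  length before computing SOAM (both configurable; `track_soam()` itself is
  the pure geometric metric and is used untouched by the analytic tests).
  Recovered SOAM values are therefore comparable within a processing
  configuration, not absolute curvatures.
* **Adaptive cutoff.** The elbow is the maximum positive (convex) discrete
  curvature of `log10(sigma_i)`; the cutoff is one less than that index (the
  size of the tissue cliff). An exactly geometric decay has no convex elbow
  and falls back to the lower clamp with a warning.
* **Registration** searches integer super-resolved shifts only (subpixel
  registration is out of scope); recovery is exact for shifts up to a
  quarter of the image extent.
* **Hobby ROIs.** Closed-boundary interpolation solves the cyclic
  mock-curvature system; tension >= 0.75, default 1. Tension applies to the
  control-point distances (the common simplified scheme). Degenerate
  (collinear) vertex sets and self-intersecting boundaries are rejected.
* **Loupas color flow.** At a 49.28 um native pitch the 20 MHz carrier
  advances more than one cycle per axial sample, so the mean-RF-frequency
  estimate is computed as the baseband deviation from the nominal carrier
  added to f0 (the standard demodulated-IQ form). Velocities wrap beyond
  the Nyquist velocity c*PRF/(4*f0) (~19.3 mm/s at the defaults).
* **Sign conventions.** Axial depth z grows away from the transducer;
  positive track direction sign and positive color-flow velocity mean motion
  away from the transducer ("red" in directional maps; "blue" is toward).

## Problem sizes

The package validates at desk scale: test scenes use 16-64 native pixels per
side (0.8-3.2 mm fields of view), 64-400 frames for most stages, full
1600-frame acquisitions for slow-flow velocity recovery, and synthetic
cohorts of 8 young + 8 aged subjects at 192 frames x 1-2 acquisitions per
subject with two separation subsets. These sizes were chosen so the full
suite exercises every stage at realistic bubble densities; the same code runs
the full-scale configuration (1600 frames x 80 acquisitions x 2 planes per
subject) unchanged via `pipeline_config()`.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- pipeline_config(n_young = 8, n_aged = 8, n_frames = 192,
                       n_acquisitions = 1, grid_shape = c(32, 32),
                       seed = 1, out_dir = "ulm_out")
res <- run_pipeline(cfg)
subset(res$anova, effect == "age_group")
res$skewness_test
```

The output directory contains the tidy metrics table, ANOVA / Tukey /
regression tables, the per-subject skewness comparison, per-stage counts and
a manifest with MD5 checksums; rerunning with the same seed reproduces every
artifact bit-identically.
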