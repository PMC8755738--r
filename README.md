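# ulmr — super-resolution ultrasound localization microscopy in R

`ulmr` is a desk-scale, fully tested implementation of an ultrasound
localization microscopy (ULM) processing chain for cerebral microvascular
imaging, together with the statistical layer used to compare vascular
phenotypes between cohorts (e.g. young vs. aged brains). ULM breaks the
diffraction limit of ultrasound by localizing individual circulating
microbubble contrast agents over thousands of ultrafast frames and linking
them into trajectories, producing vascular maps at micrometre scale without
sacrificing imaging depth.

The package takes complex beamformed in-phase/quadrature (IQ) frame stacks
`[depth × lateral × frames]` and provides:

* **SVD clutter filtering** of the Casorati (space × time) matrix with an
  adaptive low-order cutoff `k` at the elbow of the log singular-value decay
  (tissue is 30–60 dB above bubbles but spatiotemporally coherent), plus
  depth-dependent **noise equalization**;
* a Fourier-domain **microbubble separation filter** (partition-of-unity bank
  over Doppler sign × speed band) that splits dense bubble data into sparser
  subsets;
* **2D spline upsampling** to an isotropic 4.928 µm grid and **normalized
  cross-correlation localization** against an empirical Gaussian PSF, with
  subpixel parabolic refinement;
* gated optimal-assignment **tracking** (max-weight bipartite matching), the
  20-frame minimum-trajectory filter, per-track velocity
  `v = |Δx| · framerate` and **sum-of-angles tortuosity**
  `SOAM = Σ unsigned turning angles / path length` (deg/mm);
* super-resolved **density / velocity / direction mapping** with
  inter-acquisition registration, plus diffraction-limited comparators
  (power Doppler, ROI contrast power, Loupas autocorrelation color flow);
* **regional quantification**: Hobby-spline ROIs from control vertices, blood
  volume (mean microbubble tracks entering an ROI per acquisition),
  vascularity (% perfused pixels), K-means (k = 6) large/small-vessel
  stratification, intervessel distance, velocity-distribution skewness (G1);
* **cohort statistics**: two-way ANOVA (age group × region, Type II SS) with
  Tukey HSD post-tests, OLS regression on age and sex, Welch test on
  skewness.

Because suitable in vivo acquisitions are not publicly deposited, `ulmr`
ships a **synthetic-scene simulator** (`make_scene()`, `simulate_iq()`,
`preset_cohort()`) that emulates ultrafast contrast-enhanced acquisitions —
coherent tissue clutter, depth-growing noise, microbubbles advected along
parametric vessel centerlines — with full ground truth, so every stage is
verifiable. The `"young"`/`"aged"` presets differ by documented contrasts
(cortical vessel count ×0.7, speeds ×0.8, tortuosity amplitude ×1.5,
heavier-tailed speed distribution).

See the methods vignette (`vignettes/ulm-methods.Rmd`) for the model,
parameter defaults, numerical choices and limitations.

## Worked example

Simulate two vessels (5 mm/s flowing away from the transducer, 8 mm/s
toward it) under +30 dB tissue clutter, reconstruct, and read off the track
metrics:

```r
library(ulmr)

params <- acquisition_params()        # 20 MHz, 1000 Hz, 4.928 um grid
fov <- 32 * params$native_pixel_um    # 1577 um field of view
v1 <- vessel_spec(p0 = c(500, 90), p1 = c(500, fov - 90), radius_um = 12,
                  peak_speed_mm_s = 5, bubble_rate_hz = 3)
v2 <- vessel_spec(p0 = c(1100, 90), p1 = c(1100, fov - 90), radius_um = 12,
                  peak_speed_mm_s = 8, flow_sign = -1, bubble_rate_hz = 3)
scene <- make_scene(scene_config(grid_shape = c(32, 32),
                                 vessels = list(v1, v2), seed = 1), params)
sim <- simulate_iq(scene, n_frames = 400, seed = 1)

flt  <- svd_filter(sim$stack, cutoff = "adaptive", clamp = c(1, 30))
eq   <- noise_equalization(flt)
locs <- localize_stack(eq$stack, psf_model(), corr_threshold = 0.5,
                       refine = TRUE)
trks <- filter_tracks(link_frames(locs, params$frame_rate_hz), 20)
head(track_summary(trks, soam_smooth_window = 5, soam_resample_um = 15), 4)
```

```
  track_id n_points mean_speed_mm_s path_um soam_deg_mm    dm
1        1       44           5.382   210.2       165.2 1.001
2        2      124           5.468   617.3       251.6 1.001
3        3      129           8.144  1010.0       100.9 1.000
4        4      199           5.471   994.4       202.5 1.001
```

Each row is one microbubble trajectory reconstructed from the clutter-filtered
IQ frames: the 5 mm/s and 8 mm/s plug flows are recovered from frame-to-frame
displacements on the 4.928 µm grid (slow tracks read slightly high — a
documented localization-jitter bias at 30 dB SNR, see the methods vignette),
with near-unity distance metric (path/end-to-end) as expected for straight
vessels.

A full synthetic cohort comparison:

```r
cfg <- pipeline_config(n_young = 8, n_aged = 8, n_frames = 192,
                       n_acquisitions = 1, seed = 1, out_dir = "ulm_out")
res <- run_pipeline(cfg)
subset(res$anova, effect == "age_group")   # age effect per metric
res$skewness_test                          # Welch test on velocity skewness
```

writes the tidy metrics table, ANOVA/Tukey/regression tables and a manifest
with MD5 checksums under `ulm_out/`; reruns with the same seed are
bit-identical.

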