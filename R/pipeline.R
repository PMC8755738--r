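#' Configuration of the end-to-end reconstruction pipeline
#'
#' One declarative object holding every stage's parameters exactly once:
#' acquisition constants, scene/cohort preset, clutter-filter settings,
#' separation bank, localization, linking, track filtering, tortuosity
#' conditioning, K-means stratification, ROI source and the master seed. The
#' configuration round-trips through YAML ([save_config()] / [load_config()]).
#'
#' @param n_young,n_aged synthetic subjects per group (a "subject" is one
#'   simulated imaging plane).
#' @param n_frames frames per acquisition (desk-scale default 256; full-scale
#'   acquisitions are 1600 frames).
#' @param n_acquisitions acquisitions accumulated per subject (full scale: 80).
#' @param grid_shape native grid.
#' @param cohort_factors aged-vs-young contrast factors, see [preset_cohort()].
#' @param svd_cutoff `"adaptive"` or integer.
#' @param svd_clamp adaptive-cutoff clamp.
#' @param noise_eq apply depth noise equalization.
#' @param separation_bands 0 (no separation), 1 (direction split, 2 subsets)
#'   or 2 (direction x speed, 4 subsets).
#' @param corr_threshold localization correlation threshold.
#' @param refine subpixel refinement of the correlation peak.
#' @param psf_sigma_ax_um,psf_sigma_lat_um PSF model widths.
#' @param max_speed_mm_s linker speed gate.
#' @param gap_close linker gap closing (frames).
#' @param min_track_length minimum trajectory length (frames).
#' @param soam_smooth_window,soam_resample_um track-geometry conditioning for
#'   tortuosity (see [track_summary()]).
#' @param kmeans_k,kmeans_n_large vessel stratification settings.
#' @param vascularity_threshold traversal count defining perfusion.
#' @param seed master seed; all per-subject/per-stage seeds derive from it.
#' @param out_dir output directory for [run_pipeline()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_young = 8L, n_aged = 8L,
                            n_frames = 256L, n_acquisitions = 2L,
                            grid_shape = c(32L, 32L),
                            cohort_factors = list(),
                            svd_cutoff = "adaptive", svd_clamp = c(5L, 30L),
                            noise_eq = TRUE,
                            separation_bands = 1L,
                            corr_threshold = 0.5, refine = TRUE,
                            psf_sigma_ax_um = 60, psf_sigma_lat_um = 100,
                            max_speed_mm_s = 50, gap_close = 0L,
                            min_track_length = 20L,
                            soam_smooth_window = 5L, soam_resample_um = 15,
                            kmeans_k = 6L, kmeans_n_large = 2L,
                            vascularity_threshold = 1,
                            seed = 1L, out_dir = tempfile("ulm_run_")) {
  if (n_acquisitions < 1) stop("stage simulate: need at least 1 acquisition")
  cfg <- list(n_young = as.integer(n_young), n_aged = as.integer(n_aged),
              n_frames = as.integer(n_frames),
              n_acquisitions = as.integer(n_acquisitions),
              grid_shape = as.integer(grid_shape),
              cohort_factors = cohort_factors,
              svd_cutoff = svd_cutoff, svd_clamp = as.integer(svd_clamp),
              noise_eq = noise_eq,
              separation_bands = as.integer(separation_bands),
              corr_threshold = corr_threshold, refine = refine,
              psf_sigma_ax_um = psf_sigma_ax_um,
              psf_sigma_lat_um = psf_sigma_lat_um,
              max_speed_mm_s = max_speed_mm_s, gap_close = as.integer(gap_close),
              min_track_length = as.integer(min_track_length),
              soam_smooth_window = as.integer(soam_smooth_window),
              soam_resample_um = soam_resample_um,
              kmeans_k = as.integer(kmeans_k),
              kmeans_n_large = as.integer(kmeans_n_large),
              vascularity_threshold = vascularity_threshold,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Reconstruct one acquisition: filter, separate, localize, track
#'
#' Applies the SVD clutter filter (adaptive cutoff), optional noise
#' equalization, the optional microbubble separation filter, per-subset
#' spline upsampling + normalized cross-correlation localization, gated
#' frame-to-frame linking, and the minimum-track-length filter.
#'
#' @param stack an [iq_stack()].
#' @param config a [pipeline_config()].
#' @return list `tracks` (a `track_set`, all subsets pooled), `counts`
#'   (detections, tracks before/after length filter), `spectrum`.
#' @export
reconstruct_acquisition <- function(stack, config) {
  params <- stack$params
  flt <- svd_filter(stack, cutoff = config$svd_cutoff,
                    clamp = config$svd_clamp, keep_factors = config$noise_eq)
  spectrum <- flt$spectrum
  work <- if (config$noise_eq) noise_equalization(flt)$stack else flt$stack
  subsets <- if (config$separation_bands > 0L) {
    bank <- separation_bank(dim(work$iq)[3], params$frame_rate_hz,
                            n_bands = config$separation_bands)
    separation_filter(work, bank)
  } else list(all = work)
  psf <- psf_model(config$psf_sigma_ax_um, config$psf_sigma_lat_um)
  all_tracks <- list()
  n_det <- 0L
  for (sub in subsets) {
    locs <- localize_stack(sub, psf, config$corr_threshold, config$refine)
    n_det <- n_det + nrow(locs)
    ts <- link_frames(locs, params$frame_rate_hz, config$max_speed_mm_s,
                      config$gap_close)
    all_tracks <- c(all_tracks, unclass(ts))
  }
  tracks <- structure(all_tracks, class = "track_set",
                      frame_rate_hz = params$frame_rate_hz,
                      max_speed_mm_s = config$max_speed_mm_s,
                      gap_close = config$gap_close)
  n_before <- length(tracks)
  tracks <- filter_tracks(tracks, config$min_track_length)
  list(tracks = tracks,
       counts = c(frames = dim(stack$iq)[3], detections = n_det,
                  tracks = n_before, tracks_filtered = length(tracks)),
       spectrum = spectrum)
}

# Simulator-defined analysis bands: a "cortical" band over the upper part of
# the field of view and a "deep" (thalamic) band below, matching the preset
# vessel layout.
cohort_band_rois <- function(geom) {
  zc <- sr_to_um(geom, seq_len(geom$nz_sr))
  fov_z <- geom$fov_um[1]
  cort <- matrix(zc >= 0.04 * fov_z & zc <= 0.45 * fov_z, geom$nz_sr, geom$nx_sr)
  deep <- matrix(zc > 0.45 * fov_z & zc <= 0.95 * fov_z, geom$nz_sr, geom$nx_sr)
  list(cortex = roi_from_mask(cort, geom, "cortex"),
       deep = roi_from_mask(deep, geom, "deep"))
}

#' Simulate and reconstruct one synthetic subject
#'
#' Generates `n_acquisitions` acquisitions of the subject's scene,
#' reconstructs each, registers the per-acquisition accumulations to the
#' first, and computes the regional metrics (blood volume, vascularity, mean
#' velocity, mean SOAM) plus the whole-field velocity skewness.
#'
#' @param config a [pipeline_config()].
#' @param group `"young"` or `"aged"`.
#' @param subject_index index within the cohort (drives the subject seed).
#' @return list `metrics` (data.frame region x metric), `skewness`, `image`
#'   (merged `ulm_image`), `tracksets`, `counts`, `scene`.
#' @export
process_subject <- function(config, group, subject_index) {
  sseed <- child_seed(config$seed, subject_index + 1000L * (group == "aged"))
  scene_cfg <- preset_cohort(group, seed = sseed,
                             factors = config$cohort_factors,
                             grid_shape = config$grid_shape)
  scene <- make_scene(scene_cfg)
  geom <- scene$geom
  psf <- psf_model(config$psf_sigma_ax_um, config$psf_sigma_lat_um)
  tracksets <- list(); images <- list(); counts <- list()
  for (a in seq_len(config$n_acquisitions)) {
    sim <- simulate_iq(scene, config$n_frames, seed = child_seed(sseed, a),
                       psf = psf)
    rec <- reconstruct_acquisition(sim$stack, config)
    tracksets[[a]] <- rec$tracks
    images[[a]] <- ulm_accumulate(rec$tracks, geom)
    counts[[a]] <- rec$counts
  }
  reg <- register_accumulations(images)
  merged <- reg$merged
  rois <- cohort_band_rois(geom)
  all_tracks <- structure(do.call(c, lapply(tracksets, unclass)),
                          class = "track_set",
                          frame_rate_hz = scene$params$frame_rate_hz)
  rows <- list()
  for (nm in names(rois)) {
    rv <- suppressWarnings(region_velocity_and_soam(
      all_tracks, rois[[nm]], soam_smooth_window = config$soam_smooth_window,
      soam_resample_um = config$soam_resample_um))
    rows[[nm]] <- data.frame(
      region = nm,
      blood_volume = blood_volume(tracksets, rois[[nm]]),
      vascularity = vascularity(merged, rois[[nm]], config$vascularity_threshold),
      velocity = rv$mean_speed_mm_s,
      soam = rv$mean_soam_deg_mm,
      n_tracks = rv$n_tracks)
  }
  summ <- track_summary(all_tracks)
  skew <- if (nrow(summ) >= 3) velocity_skewness(summ$mean_speed_mm_s) else NA_real_
  list(metrics = do.call(rbind, rows), skewness = skew, image = merged,
       tracksets = tracksets, counts = do.call(rbind, counts), scene = scene)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates and reconstructs `n_young + n_aged` synthetic subjects, builds
#' the tidy metrics table, runs the group statistics (two-way ANOVA + Tukey
#' HSD per metric, per-region multivariate regression on age and sex, Welch
#' test on velocity skewness) and writes all artifacts plus a manifest (config
#' snapshot, per-stage counts, file checksums) under `config$out_dir`.
#' Rerunning with the same config and seed reproduces all numeric outputs
#' bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param write_maps also write each subject's merged ULM image as TIFF.
#' @return list `metrics` (tidy table), `anova` (per metric), `tukey`,
#'   `regression`, `skewness_test`, `subjects` (per-subject results),
#'   `manifest`, invisibly also written to disk.
#' @export
run_pipeline <- function(config, write_maps = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- c(rep("young", config$n_young), rep("aged", config$n_aged))
  if (!length(groups)) stop("stage 'simulate' failed: zero subjects configured")
  idx <- c(seq_len(config$n_young), seq_len(config$n_aged))
  subjects <- list(); metrics <- list(); counts <- list()
  for (s in seq_along(groups)) {
    res <- stage("simulate/reconstruct",
                 process_subject(config, groups[s], idx[s]))
    subject_id <- sprintf("%s_%02d", groups[s], idx[s])
    m <- res$metrics
    # deterministic synthetic demographics: age in weeks and sex
    age_weeks <- if (groups[s] == "young") 20 + 2 * idx[s] else 95 + 3 * idx[s]
    sex <- if (idx[s] %% 2L == 0L) "F" else "M"
    long <- do.call(rbind, lapply(c("blood_volume", "vascularity",
                                    "velocity", "soam"), function(mn) {
      data.frame(subject = subject_id, age_group = groups[s], sex = sex,
                 age_weeks = age_weeks, region = m$region, metric_name = mn,
                 value = m[[mn]])
    }))
    metrics[[s]] <- long
    counts[[s]] <- cbind(subject = subject_id, as.data.frame(res$counts))
    subjects[[subject_id]] <- list(skewness = res$skewness,
                                   metrics = res$metrics, image = res$image)
    if (write_maps) {
      write_ulm_tiff(res$image, file.path(config$out_dir,
                                          paste0(subject_id, "_ulm.tif")))
    }
  }
  metrics <- do.call(rbind, metrics)
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, counts),
                   file.path(config$out_dir, "stage_counts.csv"),
                   row.names = FALSE)

  # a metric too sparse for a model (e.g. a region with no tracks in a tiny
  # run) is reported and skipped rather than aborting the stats stage
  anova_res <- list(); tukey_res <- list(); regr <- list()
  for (mn in unique(metrics$metric_name)) {
    st <- tryCatch(two_way_anova_tukey(metrics, mn), error = function(e) {
      message("stats: skipping ANOVA for '", mn, "': ", conditionMessage(e))
      NULL
    })
    if (!is.null(st)) {
      anova_res[[mn]] <- cbind(metric = mn, st$anova)
      if (!is.null(st$tukey)) tukey_res[[mn]] <- cbind(metric = mn, st$tukey)
    }
    for (rg in unique(metrics$region)) {
      fit <- tryCatch(multivariate_regression(metrics, mn, rg),
                      error = function(e) {
                        message("stats: skipping regression for '", mn, "'/",
                                rg, ": ", conditionMessage(e))
                        NULL
                      })
      if (!is.null(fit)) {
        regr[[paste(mn, rg)]] <- cbind(metric = mn, region = rg, fit)
      }
    }
  }
  skew_y <- stats::na.omit(vapply(subjects[groups == "young"], `[[`, 1, "skewness"))
  skew_a <- stats::na.omit(vapply(subjects[groups == "aged"], `[[`, 1, "skewness"))
  skew_test <- tryCatch(compare_skewness(skew_y, skew_a), error = function(e) {
    message("stats: skipping skewness comparison: ", conditionMessage(e))
    NULL
  })

  anova_tab <- do.call(rbind, anova_res)
  tukey_tab <- do.call(rbind, tukey_res)
  regr_tab <- do.call(rbind, regr)
  if (!is.null(anova_tab)) {
    utils::write.csv(anova_tab, file.path(config$out_dir, "stats_anova.csv"),
                     row.names = FALSE)
  }
  if (!is.null(tukey_tab)) {
    utils::write.csv(tukey_tab, file.path(config$out_dir, "stats_tukey.csv"),
                     row.names = FALSE)
  }
  if (!is.null(regr_tab)) {
    utils::write.csv(regr_tab, file.path(config$out_dir, "stats_regression.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(skewness = list(young = unname(skew_y), aged = unname(skew_a),
                         test = skew_test)),
    file.path(config$out_dir, "skewness.json"), auto_unbox = TRUE, digits = NA)

  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    config = unclass(config),
    stage_counts = do.call(rbind, counts),
    files = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(config$out_dir, files)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(metrics = metrics, anova = anova_tab, tukey = tukey_tab,
                 regression = regr_tab, skewness_test = skew_test,
                 skewness = list(young = skew_y, aged = skew_a),
                 subjects = subjects, manifest = manifest))
}
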