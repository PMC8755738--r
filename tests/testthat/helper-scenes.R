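# Shared fixture builders (all synthetic, generated at test time).

default_params <- function(...) acquisition_params(...)

# Stack of parallel lateral plug-flow vessels used for velocity recovery:
# axis-aligned flow keeps grid quantization of centroids unbiased.
velocity_scene <- function(speed_mm_s, seed = 11L, grid_shape = c(64L, 32L),
                           spacing_um = 250) {
  fov <- grid_shape * 49.28
  depths <- seq(300, fov[1] - 300, by = 200)
  vessels <- lapply(depths, function(d) {
    vessel_spec(c(d, 90), c(d, fov[2] - 90), radius_um = 12,
                peak_speed_mm_s = speed_mm_s,
                bubble_rate_hz = speed_mm_s * 1000 / spacing_um)
  })
  scene_config(grid_shape = grid_shape, vessels = vessels,
               tissue_amplitude = 0, noise_floor = 0.003,
               seed = seed)
}

# Frame counts per speed: enough arrivals for >= 100 tracks of >= 20 frames.
velocity_frames <- function(speed_mm_s) {
  if (speed_mm_s <= 2) 1600L else if (speed_mm_s <= 5) 800L else 500L
}

# One static-tissue + bubbles scene for clutter-filter tests.
tissue_bubble_scene <- function(seed = 5L, tissue_db = 30,
                                grid_shape = c(32L, 32L),
                                motion_um = 0) {
  fov <- grid_shape * 49.28
  v <- vessel_spec(c(fov[1] * 0.55, 90), c(fov[1] * 0.55, fov[2] - 90),
                   radius_um = 12, peak_speed_mm_s = 6, bubble_rate_hz = 8)
  scene_config(grid_shape = grid_shape, vessels = list(v),
               tissue_amplitude = 10^(tissue_db / 20),
               tissue_motion_amplitude_um = motion_um,
               noise_floor = 10^(-30 / 20), seed = seed)
}

# Single-bubble native frame with complex white noise at a given amplitude SNR.
single_bubble_frame <- function(pos_um, snr_db = 30, grid_shape = c(32L, 32L),
                                params = acquisition_params(),
                                psf = psf_model()) {
  fr <- render_iq_frame(matrix(pos_um, 1), grid_shape, params, psf)
  sd <- 10^(-snr_db / 20) / sqrt(2)
  n <- prod(grid_shape)
  fr + matrix(complex(real = rnorm(n, sd = sd), imaginary = rnorm(n, sd = sd)),
              grid_shape[1], grid_shape[2])
}

# Brute-force optimal gated assignment for <= 4 x 4 problems (oracle for the
# linker): maximizes link count, then minimizes summed distance.
brute_force_assignment <- function(dist, gate) {
  nt <- nrow(dist); nd <- ncol(dist)
  best <- list(links = -1, cost = Inf, pairs = NULL)
  dets <- seq_len(nd)
  # enumerate all injective partial assignments track -> detection/none
  opts <- c(0L, dets)
  grid <- expand.grid(rep(list(opts), nt))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    used <- a[a > 0]
    if (anyDuplicated(used)) next
    ok <- all(vapply(seq_len(nt), function(i) {
      a[i] == 0L || dist[i, a[i]] <= gate
    }, TRUE))
    if (!ok) next
    links <- sum(a > 0)
    cost <- sum(vapply(seq_len(nt), function(i) {
      if (a[i] > 0) dist[i, a[i]] else 0
    }, 1))
    if (links > best$links || (links == best$links && cost < best$cost - 1e-12)) {
      best <- list(links = links, cost = cost, pairs = a)
    }
  }
  best
}

# Tidy synthetic metrics table for the statistics module.
make_metrics_table <- function(values, groups, regions, metric = "velocity",
                               sexes = NULL, age_weeks = NULL) {
  n <- length(values)
  if (is.null(sexes)) sexes <- rep(c("F", "M"), length.out = n)
  if (is.null(age_weeks)) age_weeks <- ifelse(groups == "young", 25, 105)
  data.frame(subject = paste0("s", seq_len(n)), age_group = groups, sex = sexes,
             age_weeks = age_weeks, region = regions, metric_name = metric,
             value = values)
}
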