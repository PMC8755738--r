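#' Render one native-grid IQ frame from point scatterers
#'
#' Each microbubble contributes its Gaussian point-spread function times a
#' complex carrier `exp(-1i * 4 * pi * f0 * (z - zb) / c)`: the phase advances
#' with axial position as `-4*pi*f0*z/c`, and the `zb`-dependent term makes
#' the slow-time phase at a fixed pixel rotate as the bubble moves, so
#' autocorrelation velocity estimators see the correct Doppler shift (motion
#' away from the transducer gives a positive Doppler frequency).
#'
#' @param positions_um matrix `(n x 2)` of bubble `(z, x)` positions, um.
#' @param grid_shape native `(depth, lateral)` shape.
#' @param params an [acquisition_params()].
#' @param psf a [psf_model()].
#' @param amplitudes per-bubble linear amplitudes (default 1).
#' @return complex matrix `depth x lateral`.
#' @export
render_iq_frame <- function(positions_um, grid_shape, params = acquisition_params(),
                            psf = psf_model(), amplitudes = NULL) {
  nz <- grid_shape[1]; nx <- grid_shape[2]
  frame <- matrix(complex(real = 0), nz, nx)
  if (is.null(positions_um) || NROW(positions_um) == 0L) return(frame)
  positions_um <- matrix(positions_um, ncol = 2L)
  if (is.null(amplitudes)) amplitudes <- rep(1, nrow(positions_um))
  p <- params$native_pixel_um
  k4 <- 4 * pi * params$center_frequency_hz / (params$sound_speed_m_s * 1e6) # rad/um
  hz <- ceiling(psf$support_sigmas * psf$sigma_ax_um / p)
  hx <- ceiling(psf$support_sigmas * psf$sigma_lat_um / p)
  for (b in seq_len(nrow(positions_um))) {
    zb <- positions_um[b, 1]; xb <- positions_um[b, 2]
    iz0 <- round(zb / p + 0.5)
    ix0 <- round(xb / p + 0.5)
    iz <- max(1L, iz0 - hz):min(nz, iz0 + hz)
    ix <- max(1L, ix0 - hx):min(nx, ix0 + hx)
    if (!length(iz) || !length(ix) || iz0 + hz < 1L || iz0 - hz > nz ||
        ix0 + hx < 1L || ix0 - hx > nx) next
    zc <- (iz - 0.5) * p; xc <- (ix - 0.5) * p
    env <- outer(exp(-(zc - zb)^2 / (2 * psf$sigma_ax_um^2)),
                 exp(-(xc - xb)^2 / (2 * psf$sigma_lat_um^2)))
    carrier <- exp(complex(imaginary = -k4 * (zc - zb)))
    frame[iz, ix] <- frame[iz, ix] + amplitudes[b] * psf$amplitude * env * carrier
  }
  frame
}

# Smooth static complex tissue field, RMS-normalized, plus its FFT for
# subpixel Fourier drift shifts.
make_tissue_field <- function(nz, nx, amplitude, corr_px = 2) {
  w <- matrix(complex(real = rnorm(nz * nx), imaginary = rnorm(nz * nx)), nz, nx)
  fz <- c(0:(nz %/% 2), -((nz - nz %/% 2 - 1):1)) / nz
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  filt <- outer(exp(-2 * (pi * corr_px * fz)^2), exp(-2 * (pi * corr_px * fx)^2))
  t0 <- stats::fft(stats::fft(w) * filt, inverse = TRUE) / (nz * nx)
  rms <- sqrt(mean(Mod(t0)^2))
  if (rms > 0) t0 <- t0 * (amplitude / rms)
  t0
}

fourier_shift <- function(field_fft, dz_px, dx_px) {
  d <- dim(field_fft)
  fz <- c(0:(d[1] %/% 2), -((d[1] - d[1] %/% 2 - 1):1)) / d[1]
  fx <- c(0:(d[2] %/% 2), -((d[2] - d[2] %/% 2 - 1):1)) / d[2]
  ramp <- outer(exp(complex(imaginary = -2 * pi * fz * dz_px)),
                exp(complex(imaginary = -2 * pi * fx * dx_px)))
  stats::fft(field_fft * ramp, inverse = TRUE) / prod(d)
}

#' Simulate an ultrafast contrast-enhanced IQ acquisition with ground truth
#'
#' Microbubbles arrive in each vessel as a Poisson process (rate
#' `bubble_rate_hz`, arrival window widened by one transit time so the vessel
#' is populated from frame 1) and are advected along the centerline at the
#' vessel's plug-flow speed (or a parabolic profile across the lumen).
#' Rendered frames are the sum of the bubble field (see [render_iq_frame()]),
#' a spatially correlated tissue field that is static or drifts slowly
#' in-plane (respiration-like sinusoidal drift), and circular white noise
#' whose amplitude grows with depth at `noise_depth_slope_db_mm`. True
#' bubble positions are recorded at frame resolution.
#'
#' @param scene a [make_scene()] result.
#' @param n_frames number of frames to simulate (>= 2).
#' @param seed integer; fixes arrivals, tissue and noise.
#' @param psf a [psf_model()].
#' @param flow_profile `"plug"` (default, one speed per vessel) or
#'   `"parabolic"`.
#' @param bubbles optional data.frame(`vessel`, `t0_s`, `offset_um`) of
#'   deterministic bubble injections replacing the Poisson draws.
#' @return list with `stack` (an [iq_stack()]), `truth` (data.frame
#'   `track_id, frame, z_um, x_um, vessel, speed_mm_s`), and the scene's
#'   `masks`.
#' @export
simulate_iq <- function(scene, n_frames, seed = scene$config$seed,
                        psf = psf_model(), flow_profile = c("plug", "parabolic"),
                        bubbles = NULL) {
  stopifnot(inherits(scene, "ulm_scene"), n_frames >= 2)
  flow_profile <- match.arg(flow_profile)
  params <- scene$params
  cfg <- scene$config
  nz <- cfg$grid_shape[1]; nx <- cfg$grid_shape[2]
  fr <- params$frame_rate_hz
  duration <- n_frames / fr
  p <- params$native_pixel_um

  slow <- vapply(cfg$vessels, function(v) v$peak_speed_mm_s, 1) / fr * 1e3 # um/frame
  if (length(slow) && any(slow > min(psf$sigma_ax_um, psf$sigma_lat_um))) {
    warning("bubble displacement exceeds one PSF width per frame; the tracking gate may fail by design")
  }

  # --- bubble itineraries ------------------------------------------------
  if (is.null(bubbles)) {
    bubbles <- with_seed(child_seed(seed, 1L), {
      out <- list()
      for (vi in seq_along(cfg$vessels)) {
        v <- cfg$vessels[[vi]]
        len <- scene$arc_lengths_um[vi]
        v_um_s <- v$peak_speed_mm_s * 1e3
        transit <- if (v_um_s > 0) len / v_um_s else 0
        n <- rpois(1, v$bubble_rate_hz * (duration + transit))
        if (n > 0) {
          out[[vi]] <- data.frame(
            vessel = vi,
            t0_s = runif(n, -transit, duration),
            offset_um = runif(n, -0.8, 0.8) * v$radius_um)
        }
      }
      do.call(rbind, out)
    })
  }

  truth <- list()
  frame_bubbles <- vector("list", n_frames)  # per frame: matrix (z, x, amp)
  if (!is.null(bubbles) && nrow(bubbles)) {
    tt <- (seq_len(n_frames) - 1) / fr
    for (b in seq_len(nrow(bubbles))) {
      vi <- bubbles$vessel[b]
      v <- cfg$vessels[[vi]]
      pts <- scene$centerlines[[vi]]
      if (v$flow_sign < 0) {  # traverse toward the transducer / reversed
        pts2 <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
        arc <- max(attr(pts, "arc")) - rev(attr(pts, "arc"))
        pts <- pts2; attr(pts, "arc") <- arc
      }
      arc <- attr(pts, "arc"); len <- max(arc)
      rho <- bubbles$offset_um[b]
      speed <- v$peak_speed_mm_s *
        if (flow_profile == "parabolic") (1 - (rho / v$radius_um)^2) else 1
      v_um_s <- speed * 1e3
      s <- v_um_s * (tt - bubbles$t0_s[b])
      live <- which(s >= 0 & s <= len & v_um_s > 0)
      if (!length(live)) next
      zc <- approx(arc, pts[, 1], xout = s[live])$y
      xc <- approx(arc, pts[, 2], xout = s[live])$y
      # local tangent -> perpendicular offset within the lumen
      s2 <- pmin(s[live] + 1, len)
      tz <- approx(arc, pts[, 1], xout = s2)$y - zc
      tx <- approx(arc, pts[, 2], xout = s2)$y - xc
      tn <- sqrt(tz^2 + tx^2); tn[tn == 0] <- 1
      zb <- zc + rho * (-tx / tn)
      xb <- xc + rho * (tz / tn)
      inside <- zb > 0 & zb < nz * p & xb > 0 & xb < nx * p
      live <- live[inside]; zb <- zb[inside]; xb <- xb[inside]
      if (!length(live)) next
      truth[[length(truth) + 1L]] <- data.frame(
        track_id = b, frame = live, z_um = zb, x_um = xb,
        vessel = vi, speed_mm_s = speed)
      for (k in seq_along(live)) {
        frame_bubbles[[live[k]]] <- rbind(frame_bubbles[[live[k]]],
                                          c(zb[k], xb[k]))
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(track_id = integer(), frame = integer(), z_um = numeric(),
               x_um = numeric(), vessel = integer(), speed_mm_s = numeric())

  # --- tissue ------------------------------------------------------------
  tissue <- NULL; tissue_fft <- NULL
  if (cfg$tissue_amplitude > 0) {
    tissue <- with_seed(child_seed(seed, 2L),
                        make_tissue_field(nz, nx, cfg$tissue_amplitude))
    if (cfg$tissue_motion_amplitude_um > 0) tissue_fft <- stats::fft(tissue)
  }

  # --- assemble frames ---------------------------------------------------
  iq <- array(complex(real = 0), dim = c(nz, nx, n_frames))
  depth_mm <- ((seq_len(nz) - 0.5) * p) / 1e3
  noise_amp <- cfg$noise_floor * 10^(cfg$noise_depth_slope_db_mm * depth_mm / 20)
  resp_hz <- 1.5  # anesthetized-mouse respiration-like drift frequency
  noise <- if (cfg$noise_floor > 0) {
    with_seed(child_seed(seed, 3L), complex_noise(c(nz, nx, n_frames), noise_amp))
  } else NULL
  for (t in seq_len(n_frames)) {
    fb <- frame_bubbles[[t]]
    fm <- render_iq_frame(fb, c(nz, nx), params, psf)
    if (!is.null(tissue)) {
      if (!is.null(tissue_fft)) {
        d_um <- cfg$tissue_motion_amplitude_um * sin(2 * pi * resp_hz * (t - 1) / fr)
        fm <- fm + fourier_shift(tissue_fft, d_um / p * 0.7, d_um / p * 0.7)
      } else {
        fm <- fm + tissue
      }
    }
    iq[, , t] <- fm
  }
  if (!is.null(noise)) iq <- iq + noise

  list(stack = iq_stack(iq, params), truth = truth, masks = scene$masks)
}
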