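#' Accumulate tracks into a super-resolved ULM image
#'
#' Every track deposits along the rasterized line between consecutive
#' centroids, so vessel lumens fill in even for slow flow. Per super-resolved
#' pixel the image keeps a traversal count (density, +1 per depositing track),
#' the running mean of the depositing tracks' mean speeds, and the running
#' mean of their axial direction signs (in [-1, 1]).
#'
#' @param tracks a `track_set` (see [link_frames()]).
#' @param geom the [grid_geometry()] of the reconstruction.
#' @param frame_rate_hz frame rate, Hz (default: track-set attribute).
#' @return a `ulm_image`: list with `density` (integer matrix), `speed`
#'   (mm/s, `NA` where density is 0), `direction` (`NA` where density is 0),
#'   `geom` and `n_acq = 1`.
#' @export
ulm_accumulate <- function(tracks, geom,
                           frame_rate_hz = attr(tracks, "frame_rate_hz")) {
  dens <- matrix(0L, geom$nz_sr, geom$nx_sr)
  spd <- matrix(0, geom$nz_sr, geom$nx_sr)
  dir <- matrix(0, geom$nz_sr, geom$nx_sr)
  for (tr in tracks) {
    if (nrow(tr) < 2) next
    v <- track_velocity(tr, frame_rate_hz)
    iz <- pmin(pmax(um_to_sr(geom, tr$z_um), 1L), geom$nz_sr)
    ix <- pmin(pmax(um_to_sr(geom, tr$x_um), 1L), geom$nx_sr)
    px <- do.call(rbind, lapply(seq_len(nrow(tr) - 1L), function(i) {
      raster_segment(c(iz[i], ix[i]), c(iz[i + 1L], ix[i + 1L]))
    }))
    px <- unique(px)
    idx <- cbind(px[, 1], px[, 2])
    n0 <- dens[idx]
    dens[idx] <- n0 + 1L
    spd[idx] <- (spd[idx] * n0 + v$mean_speed_mm_s) / (n0 + 1)
    dir[idx] <- (dir[idx] * n0 + v$direction_sign) / (n0 + 1)
  }
  spd[dens == 0L] <- NA_real_
  dir[dens == 0L] <- NA_real_
  structure(list(density = dens, speed = spd, direction = dir, geom = geom,
                 n_acq = 1L), class = "ulm_image")
}

#' @export
print.ulm_image <- function(x, ...) {
  cat(sprintf("ulm_image: %d x %d at %.4g um, %d acquisition(s), %.1f%% perfused\n",
              nrow(x$density), ncol(x$density), x$geom$sr_pitch, x$n_acq,
              100 * mean(x$density > 0)))
  invisible(x)
}

#' Merge ULM accumulation images
#'
#' Densities add exactly; speed and direction channels merge as
#' density-weighted means.
#'
#' @param images list of `ulm_image`s on a common grid.
#' @return merged `ulm_image`.
#' @export
merge_ulm <- function(images) {
  stopifnot(length(images) >= 1)
  dens <- Reduce(`+`, lapply(images, `[[`, "density"))
  wsum <- function(ch) {
    acc <- matrix(0, nrow(dens), ncol(dens))
    for (im in images) {
      v <- im[[ch]]; v[is.na(v)] <- 0
      acc <- acc + v * im$density
    }
    out <- acc / dens
    out[dens == 0] <- NA_real_
    out
  }
  structure(list(density = dens, speed = wsum("speed"),
                 direction = wsum("direction"), geom = images[[1]]$geom,
                 n_acq = sum(vapply(images, `[[`, 1L, "n_acq"))),
            class = "ulm_image")
}

#' Register ULM accumulations to a reference acquisition
#'
#' Finds, for every accumulation, the integer super-resolved-pixel shift that
#' maximizes the zero-mean 2D normalized cross-correlation of its density
#' channel against the reference (first image by default), and returns the
#' shifts together with the shift-corrected merged image. The search is
#' limited to `max_shift` pixels (default a quarter of the image extent).
#'
#' @param images list of `ulm_image`s (>= 1).
#' @param reference index of the reference image (default 1).
#' @param max_shift maximum absolute shift searched, super-resolved pixels.
#' @return list `shifts` (n x 2 integer matrix: the detected (dz, dx)
#'   displacement of each image relative to the reference; the merged image
#'   is corrected by its negative), `peak_corr` (per image), `merged`
#'   (`ulm_image`).
#' @export
register_accumulations <- function(images, reference = 1L, max_shift = NULL) {
  stopifnot(length(images) >= 1)
  ref <- images[[reference]]$density
  if (is.null(max_shift)) max_shift <- floor(min(dim(ref)) / 4)
  shifts <- matrix(0L, length(images), 2L)
  peak <- numeric(length(images))
  for (i in seq_along(images)) {
    if (i == reference) { peak[i] <- 1; next }
    mov <- images[[i]]$density
    if (all(mov == 0) || all(ref == 0)) {
      warning("all-zero density image; using shift (0,0)")
      peak[i] <- 0
      next
    }
    cc <- xcorr_shift(ref, mov, max_shift)
    shifts[i, ] <- -cc$shift          # displacement of image i vs reference
    peak[i] <- cc$peak
  }
  shifted <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    if (all(shifts[i, ] == 0L)) return(im)
    # correct by the negative of the detected displacement
    im$density <- shift_matrix(im$density, -shifts[i, 1], -shifts[i, 2], fill = 0L)
    im$speed <- shift_matrix(im$speed, -shifts[i, 1], -shifts[i, 2], fill = NA_real_)
    im$direction <- shift_matrix(im$direction, -shifts[i, 1], -shifts[i, 2], fill = NA_real_)
    im
  })
  list(shifts = shifts, peak_corr = peak, merged = merge_ulm(shifted))
}

# Integer shift (dz, dx) maximizing the normalized cross-correlation between
# ref and mov (shift applied to mov), searched over |shift| <= max_shift via
# zero-padded FFT correlation of zero-mean images.
xcorr_shift <- function(ref, mov, max_shift) {
  d <- dim(ref)
  nz <- 2L * d[1]; nx <- 2L * d[2]
  pr <- matrix(0, nz, nx); pr[seq_len(d[1]), seq_len(d[2])] <- ref - mean(ref)
  pm <- matrix(0, nz, nx); pm[seq_len(d[1]), seq_len(d[2])] <- mov - mean(mov)
  cc <- Re(stats::fft(stats::fft(pr) * Conj(stats::fft(pm)), inverse = TRUE)) / (nz * nx)
  sh <- c(0:max_shift, -(max_shift:1))
  sub <- cc[sh %% nz + 1L, sh %% nx + 1L]
  ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  norm <- sqrt(sum((ref - mean(ref))^2) * sum((mov - mean(mov))^2))
  list(shift = c(sh[ij[1]], sh[ij[2]]),
       peak = max(sub) / max(norm, .Machine$double.eps))
}

shift_matrix <- function(m, dz, dx, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_z <- seq_len(nrow(m)) - dz
  src_x <- seq_len(ncol(m)) - dx
  okz <- src_z >= 1 & src_z <= nrow(m)
  okx <- src_x >= 1 & src_x <= ncol(m)
  out[which(okz), which(okx)] <- m[src_z[okz], src_x[okx]]
  out
}

#' Power Doppler image of a clutter-filtered stack
#'
#' Per-pixel mean power of the signal over frames; the diffraction-limited
#' vascular comparator. Returns linear power with a log-compressed (dB)
#' display copy.
#'
#' @param stack an SVD-filtered [iq_stack()].
#' @return list `power` (linear), `db` (log-compressed, floor -80 dB re max).
#' @export
power_doppler <- function(stack) {
  pw <- apply(Mod(stack$iq)^2, c(1, 2), mean)
  mx <- max(pw)
  db <- if (mx > 0) pmax(10 * log10(pw / mx), -80) else matrix(-80, nrow(pw), ncol(pw))
  list(power = pw, db = db)
}

#' Contrast signal power within an ROI
#'
#' Accumulates the clutter-filtered microbubble signal power over the ROI
#' pixels and the temporal dimension of the diffraction-limited contrast
#' images.
#'
#' @param stack an SVD-filtered [iq_stack()].
#' @param roi_mask logical matrix on the native grid.
#' @return scalar total power.
#' @export
contrast_power <- function(stack, roi_mask) {
  d3 <- dim(stack$iq)
  stopifnot(identical(dim(roi_mask), d3[1:2]))
  if (!any(roi_mask)) stop("empty ROI")
  idx <- which(roi_mask)
  sum(vapply(seq_len(d3[3]),
             function(t) sum(Mod(stack$iq[, , t][idx])^2), 1))
}

#' Color-flow axial velocity map (2D autocorrelation estimator)
#'
#' Per pixel, the phase of the lag-1 slow-time autocorrelation is mapped to
#' axial velocity `v = c * PRF * phi / (4 * pi * f_hat)`, where the mean RF
#' frequency `f_hat` is estimated from the phase of the lag-1 axial
#' (fast-time) autocorrelation and falls back to the nominal center frequency
#' when that estimate is degenerate. Autocorrelations are ensemble-averaged
#' over a spatial window and over slow time. Positive velocities indicate
#' motion away from the transducer; |v| is bounded by the Nyquist velocity
#' `c * PRF / (4 * f_hat)` and faster motion wraps (aliases) in phase.
#'
#' @param stack a clutter-filtered [iq_stack()] with >= 2 frames.
#' @param ensemble number of frames averaged (default min(64, all)).
#' @param window spatial averaging half-width in native pixels (default 1,
#'   i.e. a 3x3 window).
#' @return list `velocity_mm_s` (matrix), `f_hat_hz`, `nyquist_mm_s`.
#' @export
color_flow <- function(stack, ensemble = NULL, window = 1L) {
  d3 <- dim(stack$iq)
  if (d3[3] < 2) stop("color flow needs at least 2 frames")
  params <- stack$params
  nt <- if (is.null(ensemble)) min(64L, d3[3]) else min(ensemble, d3[3])
  iq <- stack$iq[, , seq_len(nt), drop = FALSE]
  # lag-1 slow-time autocorrelation, averaged over the ensemble
  r1 <- apply(Conj(iq[, , -nt, drop = FALSE]) * iq[, , -1, drop = FALSE],
              c(1, 2), sum)
  # lag-1 fast-time (axial) autocorrelation for the mean RF frequency. The
  # nominal carrier advances several cycles per native pixel, so the raw
  # axial phase is wrapped; estimate the deviation from the nominal carrier
  # (standard baseband correction) and add it to f0.
  rax <- sum(Conj(iq[-d3[1], , , drop = FALSE]) * iq[-1, , , drop = FALSE])
  dz_um <- params$native_pixel_um
  c_um_s <- params$sound_speed_m_s * 1e6
  f0 <- params$center_frequency_hz
  k4dz <- 4 * pi * f0 * dz_um / c_um_s        # nominal carrier phase per pixel
  f_hat <- if (Mod(rax) > 0) {
    delta <- Arg(rax * exp(complex(imaginary = k4dz)))
    f0 - delta * c_um_s / (4 * pi * dz_um)
  } else f0
  if (!is.finite(f_hat) || f_hat <= 0) f_hat <- f0
  # spatial ensemble averaging of the complex autocorrelation
  if (window > 0) {
    k <- matrix(1, 2L * window + 1L, 2L * window + 1L)
    r1 <- xcorr2_same(Re(r1), k) + 1i * xcorr2_same(Im(r1), k)
  }
  phi <- Arg(r1)
  v <- params$sound_speed_m_s * params$frame_rate_hz * phi / (4 * pi * f_hat) * 1e3
  v[Mod(r1) == 0] <- 0
  list(velocity_mm_s = v, f_hat_hz = f_hat,
       nyquist_mm_s = 1e3 * params$sound_speed_m_s * params$frame_rate_hz /
         (4 * f_hat))
}

#' Write ULM image channels as multi-page TIFF
#'
#' Density, speed and direction channels as float32 pages (NA encoded as -1).
#'
#' @param image a `ulm_image`.
#' @param path output TIFF path.
#' @export
write_ulm_tiff <- function(image, path) {
  norm <- function(m) { m[is.na(m)] <- -1; m }
  tiff::writeTIFF(list(norm(image$density) / max(1, max(image$density)),
                       norm(image$speed) / max(1, max(image$speed, na.rm = TRUE)),
                       (norm(image$direction) + 1) / 2),
                  path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
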