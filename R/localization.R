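#' Anisotropic Gaussian point-spread-function model
#'
#' The system response to an isolated microbubble, modeled as a separable
#' Gaussian with distinct axial and lateral widths. Defaults are typical of a
#' high-frequency (20 MHz) linear array: a tighter axial than lateral lobe.
#'
#' @param sigma_ax_um axial standard deviation, um.
#' @param sigma_lat_um lateral standard deviation, um.
#' @param amplitude peak linear amplitude.
#' @param support_sigmas half-width of the rendered/matched support in units
#'   of sigma (>= 3).
#' @return a `psf_model` object.
#' @export
psf_model <- function(sigma_ax_um = 60, sigma_lat_um = 100, amplitude = 1,
                      support_sigmas = 3.5) {
  stopifnot(sigma_ax_um > 0, sigma_lat_um > 0, support_sigmas >= 3)
  structure(list(sigma_ax_um = sigma_ax_um, sigma_lat_um = sigma_lat_um,
                 amplitude = amplitude, support_sigmas = support_sigmas),
            class = "psf_model")
}

#' Fit the empirical PSF to an isolated microbubble patch
#'
#' Least-squares fit of a separable Gaussian (amplitude, center, axial and
#' lateral sigma) to the magnitude of an image crop containing a single
#' dominant peak, initialized from image moments.
#'
#' @param patch numeric or complex matrix crop around an isolated bubble.
#' @param pitch_um pixel pitch of the patch, um.
#' @return a [psf_model()] with the fitted sigmas and amplitude; the fitted
#'   center (um, patch coordinates) is attached as attribute `center_um`.
#' @export
fit_psf <- function(patch, pitch_um) {
  a <- Mod(patch)
  if (all(a == 0)) stop("patch is identically zero; not a bubble-like patch")
  nz <- nrow(a); nx <- ncol(a)
  zc <- (seq_len(nz) - 0.5) * pitch_um
  xc <- (seq_len(nx) - 0.5) * pitch_um
  # moment initialization on the baseline-subtracted patch (a noise floor
  # would otherwise inflate the width estimates towards the patch size)
  w <- pmax(a - stats::median(a), 0)
  if (all(w == 0)) w <- a
  w <- w / sum(w)
  mz <- sum(rowSums(w) * zc); mx <- sum(colSums(w) * xc)
  sz <- sqrt(max(sum(rowSums(w) * (zc - mz)^2), pitch_um^2 / 12))
  sx <- sqrt(max(sum(colSums(w) * (xc - mx)^2), pitch_um^2 / 12))
  obj <- function(th) {
    mu <- exp(th[1]) *
      outer(exp(-(zc - th[2])^2 / (2 * exp(2 * th[4]))),
            exp(-(xc - th[3])^2 / (2 * exp(2 * th[5]))))
    sum((a - mu)^2)
  }
  fit <- stats::optim(c(log(max(a)), mz, mx, log(sz), log(sx)), obj,
                      method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  if (fit$value > 0.5 * sum(a^2)) {
    stop("fit residual exceeds 50% of patch energy; not a bubble-like patch")
  }
  out <- psf_model(sigma_ax_um = exp(fit$par[4]), sigma_lat_um = exp(fit$par[5]),
                   amplitude = exp(fit$par[1]))
  attr(out, "center_um") <- c(z = fit$par[2], x = fit$par[3])
  out
}

#' Microbubble separation filter bank
#'
#' Fourier-domain transfer functions over temporal frequency that partition
#' the clutter-filtered data into subsets with sparser bubble distributions.
#' The default bank splits the temporal-frequency axis by Doppler sign (axial
#' flow direction: positive frequency = motion away from the transducer) and,
#' optionally, into a slow and a fast band per direction, giving 2 or 4
#' subsets. The transfer functions are a partition of unity: they sum to 1 at
#' every frequency bin (the DC bin is shared equally by the two slow bands),
#' so the subsets sum back to the input exactly.
#'
#' @param n_frames number of frames (temporal FFT length).
#' @param frame_rate_hz frame rate, Hz.
#' @param band_edge_hz Doppler frequency separating the slow from the fast
#'   band; `NULL` (default `frame_rate_hz / 8`) — set `n_bands = 1` for a pure
#'   direction split.
#' @param n_bands 1 (direction split only) or 2 (direction x speed band).
#' @return a `separation_bank`: list of length-`n_frames` weight vectors in
#'   `[0, 1]`, in FFT bin order.
#' @export
separation_bank <- function(n_frames, frame_rate_hz, band_edge_hz = NULL,
                            n_bands = 2L) {
  stopifnot(n_frames >= 2, n_bands %in% c(1L, 2L))
  if (is.null(band_edge_hz)) band_edge_hz <- frame_rate_hz / 8
  f <- c(0:(n_frames %/% 2), -((n_frames - n_frames %/% 2 - 1):1)) / n_frames *
    frame_rate_hz
  pos <- as.numeric(f > 0) + 0.5 * (f == 0)
  neg <- 1 - pos
  if (n_bands == 1L) {
    bank <- list(pos = pos, neg = neg)
  } else {
    slow <- abs(f) <= band_edge_hz
    bank <- list(pos_slow = pos * slow, pos_fast = pos * !slow,
                 neg_slow = neg * slow, neg_fast = neg * !slow)
  }
  structure(bank, class = "separation_bank", freq_hz = f)
}

#' Apply a separation filter bank to an IQ stack
#'
#' Each subset is the inverse temporal FFT of the stack's spectrum multiplied
#' by one transfer function. Because the bank is a partition of unity the
#' subsets sum to the input within floating-point error.
#'
#' @param stack an [iq_stack()] (normally SVD-filtered).
#' @param bank a [separation_bank()]; must match the frame count.
#' @return named list of [iq_stack()] subsets.
#' @export
separation_filter <- function(stack, bank) {
  stopifnot(inherits(stack, "iq_stack"))
  d3 <- dim(stack$iq)
  wsum <- Reduce(`+`, bank)
  if (length(wsum) != d3[3] || max(abs(wsum - 1)) > 1e-6) {
    stop("bank is not a partition of unity over ", d3[3], " frequency bins")
  }
  x <- casorati(stack)
  xf <- t(stats::mvfft(t(x)))                 # FFT along time (rows of t(x))
  lapply(bank, function(w) {
    sub <- t(stats::mvfft(t(xf * rep(w, each = nrow(x))), inverse = TRUE)) / d3[3]
    uncasorati(sub, stack)
  })
}

# Cubic-spline (FMM) interpolation matrix mapping n native samples to
# (n - 1) * factor + 1 super-resolved samples with native centers preserved.
# Interpolation is linear in the data, so the matrix is built once per size.
spline_upsample_matrix <- function(n, factor) {
  m <- (n - 1L) * factor + 1L
  xout <- (seq_len(m) - 1) / factor + 1
  w <- matrix(0, m, n)
  if (n == 1L) { w[1, 1] <- 1; return(w) }
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    w[, j] <- if (n >= 4) {
      stats::spline(seq_len(n), e, xout = xout, method = "fmm")$y
    } else {
      stats::approx(seq_len(n), e, xout = xout)$y
    }
  }
  w
}

#' Upsample a frame to the super-resolved grid
#'
#' 2D cubic-spline interpolation (separable, Forsythe-Malcolm-Moler end
#' conditions, exact for cubic polynomials) of the magnitude image by an
#' integer factor. The super-resolved grid is registered so that native pixel
#' centers map exactly onto super-resolved pixel centers (see
#' [grid_geometry()]); a frame of `n` rows maps to `(n - 1) * factor + 1`
#' rows.
#'
#' @param frame numeric or complex matrix (complex input is converted to
#'   magnitude).
#' @param factor integer upsampling factor >= 1.
#' @return numeric matrix on the super-resolved grid.
#' @export
upsample_frame <- function(frame, factor) {
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop("upsampling factor must be a positive integer")
  }
  factor <- as.integer(factor)
  a <- Mod(frame)
  if (factor == 1L) return(a)
  wz <- spline_upsample_matrix(nrow(a), factor)
  wx <- spline_upsample_matrix(ncol(a), factor)
  wz %*% a %*% t(wx)
}

# Gaussian matched template on the super-resolved grid. The matching window
# may be tighter than the PSF model support: a narrower window reduces the
# normalization interference between nearby bubbles.
psf_template <- function(psf, sr_pitch, match_sigmas = 2.5) {
  hz <- max(2L, ceiling(match_sigmas * psf$sigma_ax_um / sr_pitch))
  hx <- max(2L, ceiling(match_sigmas * psf$sigma_lat_um / sr_pitch))
  z <- (-hz:hz) * sr_pitch; x <- (-hx:hx) * sr_pitch
  outer(exp(-z^2 / (2 * psf$sigma_ax_um^2)), exp(-x^2 / (2 * psf$sigma_lat_um^2)))
}

# Reusable engine for zero-normalized cross-correlation maps of fixed-size
# frames against a fixed template: the template FFTs are computed once.
ncc_engine <- function(di, template) {
  t0 <- template - mean(template)
  ones <- matrix(1, nrow(template), ncol(template))
  list(plan_t = xcorr2_plan(di, t0), plan_1 = xcorr2_plan(di, ones),
       tnorm = sqrt(sum(t0^2)), npx = length(template))
}

ncc_map_engine <- function(engine, img) {
  pi_ <- matrix(0, engine$plan_t$nz, engine$plan_t$nx)
  idx_z <- seq_len(nrow(img)); idx_x <- seq_len(ncol(img))
  pi_[idx_z, idx_x] <- img
  f1 <- fftwtools::fftw2d(pi_)
  pi_[idx_z, idx_x] <- img^2
  f2 <- fftwtools::fftw2d(pi_)
  s1 <- xcorr2_exec(engine$plan_1, img_fft = f1)
  s2 <- xcorr2_exec(engine$plan_1, img_fft = f2)
  num <- xcorr2_exec(engine$plan_t, img_fft = f1)
  tnorm <- engine$tnorm; npx <- engine$npx
  denom_img <- s2 - s1^2 / npx
  denom_img[denom_img < 0] <- 0
  den <- sqrt(denom_img) * tnorm
  # windows with (near-)zero signal variance carry no correlation evidence
  valid <- den > 1e-6 * max(den, .Machine$double.xmin)
  out <- num / pmax(den, 1e-12 * max(den, 1e-300))
  out[!valid] <- 0
  pmin(pmax(out, -1), 1)
}

# Zero-normalized cross-correlation map (same size as img); values in [-1, 1].
ncc_map <- function(img, template) {
  ncc_map_engine(ncc_engine(dim(img), template), img)
}

# Regional maxima restricted to pixels >= threshold. The regional-maximum
# property is local, so thresholding the candidate set first gives the same
# result as thresholding the full maxima set (and keeps the monotonicity of
# detection counts in the threshold), at a fraction of the cost.
thresholded_maxima <- function(m, threshold) {
  nz <- nrow(m); nx <- ncol(m)
  idx <- which(m >= threshold)
  if (!length(idx)) return(matrix(integer(), 0, 2))
  r <- ((idx - 1L) %% nz) + 1L
  c <- ((idx - 1L) %/% nz) + 1L
  val <- m[idx]
  ok <- rep(TRUE, length(idx))
  for (dz in -1:1) for (dx in -1:1) {
    if (dz == 0 && dx == 0) next
    rr <- r + dz; cc <- c + dx
    inb <- rr >= 1L & rr <= nz & cc >= 1L & cc <= nx
    nv <- rep(-Inf, length(idx))
    nidx <- (cc[inb] - 1L) * nz + rr[inb]
    nv[inb] <- m[nidx]
    bad <- nv > val
    # flat plateau: defer to the lowest linear index
    eq <- inb & nv == val
    eq[eq] <- nidx[eq[inb]] < idx[eq]
    ok <- ok & !bad & !eq
  }
  cbind(r[ok], c[ok])
}

# Subpixel peak offsets (dz, dx) for each (iz, ix) via least-squares quadratic
# fit of log(map) over a 5x5 window. The design pseudo-inverse is fixed.
quad_peak_offsets <- function(map, iz, ix, hw = 2L) {
  g <- as.matrix(expand.grid(z = -hw:hw, x = -hw:hw))
  design <- cbind(1, g[, 1], g[, 2], g[, 1]^2, g[, 2]^2, g[, 1] * g[, 2])
  pinv <- solve(crossprod(design), t(design))
  out <- matrix(0, length(iz), 2L)
  nz <- nrow(map); nx <- ncol(map)
  for (k in seq_along(iz)) {
    zi <- max(hw + 1L, min(nz - hw, iz[k]))
    xi <- max(hw + 1L, min(nx - hw, ix[k]))
    w <- map[(zi - hw):(zi + hw), (xi - hw):(xi + hw)]
    if (any(w <= 0)) next                       # fall back to the pixel center
    b <- pinv %*% log(as.vector(w))
    h <- matrix(c(2 * b[4], b[6], b[6], 2 * b[5]), 2)
    if (!all(is.finite(h)) || det(h) <= 0 || h[1, 1] >= 0) next
    d <- -solve(h, b[2:3])
    if (max(abs(d)) > 1.5) next
    out[k, ] <- d + c(zi - iz[k], xi - ix[k])
  }
  out
}

# Regional maxima of a matrix: pixels >= all 8 neighbours, with flat plateaus
# deduplicated by keeping the lowest linear index.
regional_maxima <- function(m) {
  nz <- nrow(m); nx <- ncol(m)
  pad <- matrix(-Inf, nz + 2L, nx + 2L)
  pad[2:(nz + 1L), 2:(nx + 1L)] <- m
  nbr_max <- matrix(-Inf, nz, nx)
  nbr_eq_lower <- matrix(FALSE, nz, nx)   # equal-valued neighbour w/ smaller index
  lin <- matrix(seq_len(nz * nx), nz, nx)
  lin_pad <- matrix(NA_integer_, nz + 2L, nx + 2L)
  lin_pad[2:(nz + 1L), 2:(nx + 1L)] <- lin
  for (dz in -1:1) for (dx in -1:1) {
    if (dz == 0 && dx == 0) next
    sh <- pad[(2:(nz + 1L)) + dz, (2:(nx + 1L)) + dx]
    nbr_max <- pmax(nbr_max, sh)
    shl <- lin_pad[(2:(nz + 1L)) + dz, (2:(nx + 1L)) + dx]
    nbr_eq_lower <- nbr_eq_lower | (!is.na(shl) & sh == m & shl < lin)
  }
  which(m >= nbr_max & !nbr_eq_lower, arr.ind = TRUE)
}

#' Localize microbubble centroids on a super-resolved frame
#'
#' Computes the normalized 2D cross-correlation of the frame with the
#' empirical PSF template, finds regional maxima of the correlation map, and
#' keeps maxima whose correlation coefficient reaches `corr_threshold`. One
#' centroid is reported per surviving maximum, at the maximum's super-resolved
#' pixel center (optionally refined to a subpixel position by a quadratic
#' fit of the log-correlation peak).
#' Maxima are found before thresholding, so raising the threshold can only
#' remove detections.
#'
#' @param frame super-resolved magnitude frame (see [upsample_frame()]).
#' @param psf a [psf_model()].
#' @param geom the scene [grid_geometry()] (pitch and micron origin).
#' @param corr_threshold minimum normalized correlation (default 0.5).
#' @param refine logical; subpixel refinement by a least-squares quadratic
#'   fit of the log-correlation over a 5x5 neighbourhood (off by default).
#' @param match_sigmas half-width of the correlation window in units of the
#'   PSF sigma (default 2.5; tighter than the PSF support to limit
#'   normalization interference between nearby bubbles).
#' @param exclude_margin drop detections closer to the frame edge than half
#'   the correlation window (where the clipped normalization biases positions
#'   inward); on by default.
#' @param min_peak_snr amplitude gate: detections must have a frame amplitude
#'   at the peak of at least this multiple of the frame's background scale,
#'   estimated as the 10th percentile of positive frame values (a low
#'   quantile stays robust even when bubbles cover much of the frame).
#'   Normalized correlation is amplitude-blind, so without the gate
#'   low-amplitude smooth clutter residue whose spatial scale resembles the
#'   PSF would be detected; 0 disables.
#' @param engine internal: a precomputed correlation engine for this frame
#'   size and template (used by [localize_stack()]).
#' @return data.frame `z_um, x_um, corr, iz, ix` (super-resolved indices).
#' @export
localize_frame <- function(frame, psf, geom, corr_threshold = 0.5,
                           refine = FALSE, match_sigmas = 2.5,
                           exclude_margin = TRUE, min_peak_snr = 10,
                           engine = NULL) {
  tmpl <- psf_template(psf, geom$sr_pitch, match_sigmas)
  if (nrow(tmpl) >= nrow(frame) || ncol(tmpl) >= ncol(frame)) {
    stop("PSF support must be smaller than the frame")
  }
  if (all(frame == 0)) {
    return(data.frame(z_um = numeric(), x_um = numeric(), corr = numeric(),
                      iz = integer(), ix = integer()))
  }
  cmap <- if (!is.null(engine)) ncc_map_engine(engine, frame) else
    ncc_map(frame, tmpl)
  mx <- thresholded_maxima(cmap, corr_threshold)
  if (exclude_margin && nrow(mx)) {
    # drop detections whose correlation window is clipped by the frame edge:
    # the zero-padded normalization biases those positions inward
    hz <- nrow(tmpl) %/% 2L; hx <- ncol(tmpl) %/% 2L
    ok <- mx[, 1] > hz & mx[, 1] <= nrow(frame) - hz &
      mx[, 2] > hx & mx[, 2] <= ncol(frame) - hx
    mx <- mx[ok, , drop = FALSE]
  }
  if (min_peak_snr > 0 && nrow(mx)) {
    bg <- stats::quantile(frame[frame > 0], 0.1, names = FALSE)
    if (is.finite(bg) && bg > 0) {
      mx <- mx[frame[mx] >= min_peak_snr * bg, , drop = FALSE]
    }
  }
  iz <- mx[, 1]; ix <- mx[, 2]
  z_um <- sr_to_um(geom, iz); x_um <- sr_to_um(geom, ix)
  if (refine && nrow(mx)) {
    # subpixel refinement: least-squares quadratic fit to the log-correlation
    # over a 5x5 neighbourhood (a Gaussian-Gaussian correlation peak is
    # exactly quadratic in the log domain); offsets clamped to 1.5 pixels
    off <- quad_peak_offsets(cmap, iz, ix)
    z_um <- z_um + off[, 1] * geom$sr_pitch
    x_um <- x_um + off[, 2] * geom$sr_pitch
  }
  data.frame(z_um = z_um, x_um = x_um, corr = cmap[mx],
             iz = as.integer(iz), ix = as.integer(ix))
}

#' Localize every frame of an IQ stack
#'
#' Convenience wrapper: upsamples each frame of (each subset of) a stack to
#' the super-resolved grid and localizes bubbles, returning one tidy table.
#'
#' @param stack an [iq_stack()] (typically clutter-filtered / one separation
#'   subset).
#' @param psf a [psf_model()].
#' @param corr_threshold minimum normalized correlation.
#' @param refine subpixel refinement flag, see [localize_frame()].
#' @param match_sigmas correlation window half-width, see [localize_frame()].
#' @return data.frame `frame, z_um, x_um, corr`.
#' @export
localize_stack <- function(stack, psf, corr_threshold = 0.5, refine = FALSE,
                           match_sigmas = 2.5, exclude_margin = TRUE,
                           min_peak_snr = 10) {
  d3 <- dim(stack$iq)
  geom <- grid_geometry(stack$params, d3[1:2])
  out <- vector("list", d3[3])
  tmpl <- psf_template(psf, geom$sr_pitch, match_sigmas)
  engine <- ncc_engine(c(geom$nz_sr, geom$nx_sr), tmpl)
  for (t in seq_len(d3[3])) {
    fr <- upsample_frame(stack$iq[, , t], geom$factor)
    loc <- localize_frame(fr, psf, geom, corr_threshold, refine, match_sigmas,
                          exclude_margin, min_peak_snr, engine = engine)
    if (nrow(loc)) out[[t]] <- cbind(frame = t, loc[, c("z_um", "x_um", "corr")])
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(frame = integer(), z_um = numeric(), x_um = numeric(),
                      corr = numeric()))
  }
  do.call(rbind, out)
}
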