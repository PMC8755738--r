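#' Acquisition parameters for ultrafast contrast-enhanced imaging
#'
#' Bundles the constants of the ultrafast acquisition: a 20 MHz center
#' frequency, 1000 Hz compounded frame rate, 1600 frames per acquisition and
#' 80 acquisitions per imaging plane, with super-resolved reconstruction at an
#' isotropic 4.928 um pitch. The native (pre-interpolation) IQ pixel pitch
#' defaults to 49.28 um so that the super-resolved grid is an exact x10
#' upsampling; `superres_pixel_um` must divide `native_pixel_um` by an integer
#' factor.
#'
#' @param center_frequency_hz transmit center frequency f0, Hz.
#' @param frame_rate_hz compounded frame rate (PRF after compounding), Hz.
#' @param sound_speed_m_s speed of sound c, m/s.
#' @param native_pixel_um native IQ pixel pitch (isotropic axial/lateral), um.
#' @param superres_pixel_um super-resolved reconstruction pitch, um.
#' @param frames_per_acquisition frames in one acquisition.
#' @param n_acquisitions number of acquisitions accumulated per imaging plane.
#' @return an object of class `acquisition_params`.
#' @examples
#' p <- acquisition_params()
#' p$upsampling_factor  # 10
#' @export
acquisition_params <- function(center_frequency_hz = 2.0e7,
                               frame_rate_hz = 1000,
                               sound_speed_m_s = 1540,
                               native_pixel_um = 49.28,
                               superres_pixel_um = 4.928,
                               frames_per_acquisition = 1600,
                               n_acquisitions = 80) {
  vals <- c(center_frequency_hz, frame_rate_hz, sound_speed_m_s,
            native_pixel_um, superres_pixel_um, frames_per_acquisition,
            n_acquisitions)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all acquisition parameters must be finite and strictly positive")
  }
  factor <- native_pixel_um / superres_pixel_um
  if (abs(factor - round(factor)) > 1e-9) {
    stop("superres_pixel_um must divide native_pixel_um by an integer factor, got ",
         fmt_num(factor))
  }
  structure(list(
    center_frequency_hz = center_frequency_hz,
    frame_rate_hz = frame_rate_hz,
    sound_speed_m_s = sound_speed_m_s,
    native_pixel_um = native_pixel_um,
    superres_pixel_um = superres_pixel_um,
    frames_per_acquisition = as.integer(frames_per_acquisition),
    n_acquisitions = as.integer(n_acquisitions),
    upsampling_factor = as.integer(round(factor))
  ), class = "acquisition_params")
}

#' Nyquist axial velocity of the acquisition
#'
#' The largest unambiguous axial velocity of a slow-time phase estimator,
#' `c * PRF / (4 * f0)`, in mm/s.
#'
#' @param params an [acquisition_params()] object.
#' @return Nyquist velocity, mm/s.
#' @export
nyquist_velocity <- function(params) {
  1e3 * params$sound_speed_m_s * params$frame_rate_hz /
    (4 * params$center_frequency_hz)
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "acquisition_params: f0 = %.3g MHz, PRF = %g Hz, c = %g m/s\n  native %g um -> superres %g um (x%d), %d frames x %d acquisitions\n",
    x$center_frequency_hz / 1e6, x$frame_rate_hz, x$sound_speed_m_s,
    x$native_pixel_um, x$superres_pixel_um, x$upsampling_factor,
    x$frames_per_acquisition, x$n_acquisitions))
  invisible(x)
}
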