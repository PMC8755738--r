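#' Super-resolved grid geometry
#'
#' With an integer upsampling factor F, the super-resolved samples run from
#' the first to the last native pixel center in steps of `native_pitch / F`,
#' so native pixel centers land exactly on super-resolved pixel centers. A
#' native grid of n pixels maps to `(n - 1) * F + 1` super-resolved pixels;
#' super-resolved pixel k (1-based) sits at
#' `0.5 * native_pitch + (k - 1) * sr_pitch` micrometres.
#'
#' @param params an [acquisition_params()] object.
#' @param grid_shape integer `(depth, lateral)` native grid shape.
#' @return a `grid_geometry` list with native/super-resolved shapes, pitches
#'   and the micron origin of both grids.
#' @export
grid_geometry <- function(params, grid_shape) {
  nz <- as.integer(grid_shape[1]); nx <- as.integer(grid_shape[2])
  f <- params$upsampling_factor
  structure(list(
    nz = nz, nx = nx,
    nz_sr = (nz - 1L) * f + 1L, nx_sr = (nx - 1L) * f + 1L,
    native_pitch = params$native_pixel_um,
    sr_pitch = params$native_pixel_um / f,
    origin_um = 0.5 * params$native_pixel_um,
    factor = f,
    fov_um = c(nz, nx) * params$native_pixel_um
  ), class = "grid_geometry")
}

#' Convert micron positions to super-resolved pixel indices and back
#'
#' @param geom a [grid_geometry()].
#' @param um positions in micrometres.
#' @return `um_to_sr`: nearest 1-based super-resolved index (not clipped);
#'   `sr_to_um`: micron position of a super-resolved pixel center.
#' @export
um_to_sr <- function(geom, um) as.integer(round((um - geom$origin_um) / geom$sr_pitch)) + 1L

#' @rdname um_to_sr
#' @param idx 1-based super-resolved indices.
#' @export
sr_to_um <- function(geom, idx) geom$origin_um + (idx - 1) * geom$sr_pitch

#' Specify one vessel of a synthetic vascular scene
#'
#' A vessel is a planar centerline (straight segment, sinusoid about a chord,
#' or piecewise-linear control points), a lumen radius, a plug-flow speed and
#' an axial flow sign (+1 flowing away from the transducer, -1 toward it, the
#' blue/red convention of directional ULM maps), plus a Poisson microbubble
#' arrival rate.
#'
#' @param p0,p1 chord endpoints, micrometres `(z, x)`.
#' @param radius_um lumen radius, um.
#' @param peak_speed_mm_s plug-flow speed, mm/s.
#' @param flow_sign +1 away from the transducer, -1 toward it. The sign only
#'   labels the vessel; the actual axial velocity follows the centerline
#'   direction, which is traversed from `p0` to `p1`.
#' @param bubble_rate_hz Poisson arrival rate of microbubbles, 1/s.
#' @param type `"straight"`, `"sinusoid"` or `"points"`.
#' @param amplitude_um,wavelength_um,phase sinusoid perpendicular offset
#'   parameters (ignored for other types).
#' @param points for `type = "points"`: matrix of `(z, x)` control points, um.
#' @return a `vessel_spec` object.
#' @export
vessel_spec <- function(p0, p1, radius_um, peak_speed_mm_s,
                        flow_sign = 1, bubble_rate_hz = 5,
                        type = c("straight", "sinusoid", "points"),
                        amplitude_um = 0, wavelength_um = 500, phase = 0,
                        points = NULL) {
  type <- match.arg(type)
  stopifnot(radius_um > 0, peak_speed_mm_s >= 0, bubble_rate_hz >= 0,
            flow_sign %in% c(-1, 1), wavelength_um > 0)
  structure(list(p0 = as.numeric(p0), p1 = as.numeric(p1),
                 radius_um = radius_um, peak_speed_mm_s = peak_speed_mm_s,
                 flow_sign = flow_sign, bubble_rate_hz = bubble_rate_hz,
                 type = type, amplitude_um = amplitude_um,
                 wavelength_um = wavelength_um, phase = phase,
                 points = points),
            class = "vessel_spec")
}

# Densely sampled centerline polyline (n x 2 matrix of (z, x) um) with
# cumulative arc length attribute.
centerline_points <- function(vessel, step_um = 1) {
  if (vessel$type == "points") {
    pts <- vessel$points
    # resample piecewise-linear curve at ~step_um spacing
    seg <- sqrt(rowSums(diff(pts)^2))
    out <- list(pts[1, , drop = FALSE])
    for (i in seq_along(seg)) {
      n <- max(1L, ceiling(seg[i] / step_um))
      t <- seq_len(n) / n
      out[[i + 1L]] <- cbind(pts[i, 1] + t * (pts[i + 1, 1] - pts[i, 1]),
                             pts[i, 2] + t * (pts[i + 1, 2] - pts[i, 2]))
    }
    pts <- do.call(rbind, out)
  } else {
    chord <- vessel$p1 - vessel$p0
    len <- sqrt(sum(chord^2))
    u <- chord / len                      # along-chord unit vector
    v <- c(-u[2], u[1])                   # perpendicular
    s <- seq(0, len, by = step_um)
    if (s[length(s)] < len) s <- c(s, len)
    off <- if (vessel$type == "sinusoid") {
      vessel$amplitude_um * sin(2 * pi * s / vessel$wavelength_um + vessel$phase)
    } else rep(0, length(s))
    pts <- cbind(vessel$p0[1] + s * u[1] + off * v[1],
                 vessel$p0[2] + s * u[2] + off * v[2])
  }
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  attr(pts, "arc") <- arc
  pts
}

#' Configure a synthetic vascular scene
#'
#' Scene-level knobs of the simulator: the native grid shape, the vessel list,
#' the tissue clutter level relative to the (unit) microbubble amplitude, a
#' slow in-plane tissue drift, and a depth-growing noise floor. The defaults
#' put static tissue 30 dB above the bubbles and the noise floor 30 dB below
#' them, so clutter filtering, localization and tracking are each exercised.
#'
#' @param grid_shape native `(depth, lateral)` shape.
#' @param vessels list of [vessel_spec()] objects.
#' @param tissue_amplitude tissue RMS amplitude, linear, relative to unit
#'   bubble amplitude (default `10^(30/20)`, i.e. +30 dB).
#' @param tissue_motion_amplitude_um amplitude of the slow sinusoidal in-plane
#'   tissue drift (respiration-like), um; 0 = static tissue.
#' @param noise_floor noise RMS amplitude at zero depth, linear (default
#'   `10^(-30/20)`, i.e. 30 dB below the bubbles).
#' @param noise_depth_slope_db_mm growth of the noise amplitude with depth,
#'   dB/mm.
#' @param seed integer; fixes all randomness of the scene and the simulation.
#' @return a `scene_config` object.
#' @export
scene_config <- function(grid_shape = c(32L, 32L), vessels = list(),
                         tissue_amplitude = 10^(30 / 20),
                         tissue_motion_amplitude_um = 0,
                         noise_floor = 10^(-30 / 20),
                         noise_depth_slope_db_mm = 2,
                         seed = 1L) {
  stopifnot(tissue_amplitude >= 0, noise_floor >= 0,
            tissue_motion_amplitude_um >= 0, length(grid_shape) == 2L)
  structure(list(grid_shape = as.integer(grid_shape), vessels = vessels,
                 tissue_amplitude = tissue_amplitude,
                 tissue_motion_amplitude_um = tissue_motion_amplitude_um,
                 noise_floor = noise_floor,
                 noise_depth_slope_db_mm = noise_depth_slope_db_mm,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Build a synthetic scene: geometry plus ground-truth masks
#'
#' Rasterizes every vessel lumen on the super-resolved grid and computes the
#' analytic centerline tortuosity (sum-of-angles of the densely sampled
#' centerline, deg/mm) where the centerline admits one. Deterministic for a
#' fixed config.
#'
#' @param config a [scene_config()].
#' @param params an [acquisition_params()].
#' @return a `ulm_scene` with elements `config`, `params`, `geom`, per-vessel
#'   `masks` (logical super-resolved matrices), combined `mask`, per-vessel
#'   `centerlines`, `arc_lengths_um` and `analytic_soam_deg_mm`.
#' @export
make_scene <- function(config, params = acquisition_params()) {
  geom <- grid_geometry(params, config$grid_shape)
  fov <- geom$fov_um
  masks <- list(); cls <- list()
  arc_len <- numeric(0); soam <- numeric(0)
  for (i in seq_along(config$vessels)) {
    v <- config$vessels[[i]]
    pts <- centerline_points(v, step_um = geom$sr_pitch / 2)
    pad <- v$radius_um
    if (any(pts[, 1] < pad) || any(pts[, 1] > fov[1] - pad) ||
        any(pts[, 2] < pad) || any(pts[, 2] > fov[2] - pad)) {
      stop(sprintf("vessel %d lies outside the field of view (%g x %g um)",
                   i, fov[1], fov[2]))
    }
    masks[[i]] <- rasterize_lumen(pts, v$radius_um, geom)
    cls[[i]] <- pts
    arc_len[i] <- max(attr(pts, "arc"))
    soam[i] <- if (nrow(pts) >= 3) soam_polyline(pts)["soam_deg_mm"] else 0
  }
  combined <- matrix(FALSE, geom$nz_sr, geom$nx_sr)
  for (m in masks) combined <- combined | m
  structure(list(config = config, params = params, geom = geom,
                 masks = masks, mask = combined, centerlines = cls,
                 arc_lengths_um = arc_len, analytic_soam_deg_mm = soam),
            class = "ulm_scene")
}

# Mark super-resolved pixels whose centers are within radius_um of the
# sampled centerline.
rasterize_lumen <- function(pts, radius_um, geom) {
  m <- matrix(FALSE, geom$nz_sr, geom$nx_sr)
  r_px <- radius_um / geom$sr_pitch
  h <- ceiling(r_px)
  dzo <- rep(-h:h, times = 2 * h + 1)
  dxo <- rep(-h:h, each = 2 * h + 1)
  keep <- dzo^2 + dxo^2 <= r_px^2
  dzo <- dzo[keep]; dxo <- dxo[keep]
  iz <- um_to_sr(geom, pts[, 1]); ix <- um_to_sr(geom, pts[, 2])
  ctr <- unique(cbind(iz, ix))
  for (k in seq_len(nrow(ctr))) {
    z <- ctr[k, 1] + dzo; x <- ctr[k, 2] + dxo
    ok <- z >= 1L & z <= geom$nz_sr & x >= 1L & x <= geom$nx_sr
    m[cbind(z[ok], x[ok])] <- TRUE
  }
  m
}

#' @export
print.ulm_scene <- function(x, ...) {
  cat(sprintf("ulm_scene: %d vessels on %d x %d native grid (superres %d x %d)\n",
              length(x$config$vessels), x$geom$nz, x$geom$nx,
              x$geom$nz_sr, x$geom$nx_sr))
  invisible(x)
}

#' Cohort scene presets emulating young and aged cerebral vasculature
#'
#' Builds a scene with a densely vascularized "cortical" band of roughly
#' columnar vessels in the upper part of the field of view and a band of deep
#' ("thalamic") vessels below, mimicking the organization seen in coronal
#' brain sections. The aged preset differs from the young one by documented
#' multiplicative contrasts: fewer cortical vessels (x0.7), globally slower
#' flow (x0.8), larger sinusoid tortuosity amplitude (x1.5) and a
#' heavier-tailed per-vessel speed assignment. Per-vessel random draws use a
#' per-index seed, so a vessel shared by both presets at the same `seed` gets
#' exactly the same base speed (aged = 0.8 x young) and geometry apart from
#' the documented contrasts.
#'
#' @param group `"young"` or `"aged"`.
#' @param seed integer seed.
#' @param factors named list of aged-vs-young contrasts:
#'   `cortical_count` (default 0.7), `speed` (0.8), `tortuosity_amplitude`
#'   (1.5), `speed_sdlog_aged` (0.55 vs the young 0.35).
#' @param n_cortical,n_deep young-group vessel counts per band.
#' @param grid_shape native grid shape.
#' @return a [scene_config()].
#' @export
preset_cohort <- function(group = c("young", "aged"), seed = 1L,
                          factors = list(), n_cortical = 10L, n_deep = 8L,
                          grid_shape = c(32L, 32L)) {
  group <- match.arg(group)
  f <- utils::modifyList(list(cortical_count = 0.7, speed = 0.8,
                              tortuosity_amplitude = 1.5,
                              speed_sdlog_young = 0.35,
                              speed_sdlog_aged = 0.55), factors)
  params <- acquisition_params()
  fov <- grid_shape * params$native_pixel_um
  aged <- group == "aged"
  n_c <- if (aged) as.integer(round(n_cortical * f$cortical_count)) else as.integer(n_cortical)
  amp_scale <- if (aged) f$tortuosity_amplitude else 1
  spd_scale <- if (aged) f$speed else 1
  sdlog <- if (aged) f$speed_sdlog_aged else f$speed_sdlog_young
  base_amp <- 20                 # um, young sinusoid amplitude
  mean_speed <- 9                # mm/s, cohort mean assigned speed (young)
  # Lognormal speed with E[speed] = mean_speed * spd_scale regardless of the
  # tail weight: speed = S0 * exp(sigma * z - sigma^2 / 2) * scale. The same
  # standard-normal draw z is used for a vessel index in both presets, so the
  # aged/young expected-speed ratio is the speed factor exactly.
  draw_speed <- function(idx) {
    z <- with_seed(child_seed(seed, 100L + idx), qnorm(runif(1)))
    mean_speed * exp(sdlog * z - sdlog^2 / 2) * spd_scale
  }
  vessels <- list()
  # cortical band: near-vertical columnar vessels, depth 6% .. 42% of FOV
  for (i in seq_len(n_c)) {
    vals <- with_seed(child_seed(seed, i), {
      list(x = runif(1, 0.12, 0.88),
           ph = runif(1, 0, 2 * pi), sgn = sample(c(-1, 1), 1))
    })
    x0 <- vals$x * fov[2]
    vessels[[length(vessels) + 1L]] <- vessel_spec(
      p0 = c(0.06 * fov[1], x0), p1 = c(0.42 * fov[1], x0),
      radius_um = 10, peak_speed_mm_s = draw_speed(i),
      flow_sign = vals$sgn, bubble_rate_hz = 7,
      type = "sinusoid", amplitude_um = base_amp * amp_scale,
      wavelength_um = 600, phase = vals$ph)
  }
  # deep band: near-horizontal vessels, depth 50% .. 92% of FOV
  for (i in seq_len(n_deep)) {
    vals <- with_seed(child_seed(seed, 200L + i),
                      list(zf = runif(1, 0.50, 0.92), ph = runif(1, 0, 2 * pi),
                           sgn = sample(c(-1, 1), 1)))
    vessels[[length(vessels) + 1L]] <- vessel_spec(
      p0 = c(vals$zf * fov[1], 0.06 * fov[2]),
      p1 = c(vals$zf * fov[1], 0.94 * fov[2]),
      radius_um = 12, peak_speed_mm_s = draw_speed(500L + i),
      flow_sign = vals$sgn, bubble_rate_hz = 7,
      type = "sinusoid", amplitude_um = base_amp * amp_scale,
      wavelength_um = 600, phase = vals$ph)
  }
  scene_config(grid_shape = grid_shape, vessels = vessels,
               tissue_amplitude = 10^(30 / 20),
               tissue_motion_amplitude_um = 2,
               noise_floor = 10^(-30 / 20),
               noise_depth_slope_db_mm = 2, seed = seed)
}
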