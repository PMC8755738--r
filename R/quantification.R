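# --- ROI construction ----------------------------------------------------

# Solve the closed-path Hobby spline through knots (n x 2, um): returns per
# segment the two cubic Bezier control points. Departure/arrival angles theta,
# phi (relative to each chord) solve the cyclic mock-curvature system; for a
# circle the solution reproduces the inscribed-arc tangents. `tension` >= 1
# shortens the control distances (tenser, more polygonal curve).
hobby_closed <- function(knots, tension = 1) {
  n <- nrow(knots)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  chord <- knots[nxt, ] - knots
  d <- sqrt(rowSums(chord^2))
  if (any(d == 0)) stop("coincident consecutive vertices")
  ang <- atan2(chord[, 2], chord[, 1])
  psi <- ang - ang[prv]
  psi <- (psi + pi) %% (2 * pi) - pi     # wrap to (-pi, pi]
  m <- matrix(0, n, n); rhs <- numeric(n)
  for (i in seq_len(n)) {
    dp <- d[prv[i]]; di <- d[i]
    m[i, prv[i]] <- m[i, prv[i]] + 1 / dp
    m[i, i] <- m[i, i] + 2 * (1 / dp + 1 / di)
    m[i, nxt[i]] <- m[i, nxt[i]] + 1 / di
    rhs[i] <- -(2 * psi[i] / dp + psi[nxt[i]] / di)
  }
  theta <- solve(m, rhs)
  phi <- -psi[nxt] - theta[nxt]
  rho <- function(th, ph) {
    (2 + sqrt(2) * (sin(th) - sin(ph) / 16) * (sin(ph) - sin(th) / 16) *
       (cos(th) - cos(ph))) /
      (3 * (1 + (sqrt(5) - 1) / 2 * cos(th) + (3 - sqrt(5)) / 2 * cos(ph)))
  }
  c1 <- knots + (rho(theta, phi) * d / tension) *
    cbind(cos(ang + theta), sin(ang + theta))
  c2 <- knots[nxt, ] - (rho(phi, theta) * d / tension) *
    cbind(cos(ang - phi), sin(ang - phi))
  list(p0 = knots, c1 = c1, c2 = c2, p3 = knots[nxt, , drop = FALSE])
}

# Sample every Bezier segment of a hobby_closed() result at `per_seg` points,
# returning the closed boundary polyline (without repeating the start) and a
# map from sampled subsegments to spline segment index.
sample_hobby <- function(h, per_seg = 32L) {
  t <- seq(0, 1, length.out = per_seg + 1L)[-(per_seg + 1L)]
  b0 <- (1 - t)^3; b1 <- 3 * t * (1 - t)^2; b2 <- 3 * t^2 * (1 - t); b3 <- t^3
  n <- nrow(h$p0)
  pts <- matrix(0, n * per_seg, 2L)
  seg <- integer(n * per_seg)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * per_seg + 1L):(i * per_seg)
    pts[rows, ] <- b0 %o% h$p0[i, ] + b1 %o% h$c1[i, ] +
      b2 %o% h$c2[i, ] + b3 %o% h$p3[i, ]
    seg[rows] <- i
  }
  list(pts = pts, seg = seg)
}

polygon_area <- function(p) {
  n <- nrow(p); nxt <- c(2:n, 1L)
  abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])) / 2
}

#' Build a region of interest from control vertices (Hobby interpolation)
#'
#' Interpolates a closed smooth boundary through ordered control vertices
#' using Hobby's algorithm (the scheme behind METAFONT's "smooth, easy to
#' compute" splines; the boundary passes through every vertex with continuous
#' tangents). The raster mask contains the super-resolved pixels whose centers
#' fall inside the boundary (even-odd rule). The boundary is checked for
#' self-intersection.
#'
#' @param vertices matrix (>= 3 x 2) of `(z, x)` control vertices, um,
#'   ordered along the boundary.
#' @param geom a [grid_geometry()] defining the raster grid.
#' @param tension Hobby tension >= 0.75 (1 = standard roundness; larger values
#'   pull the boundary toward the control polygon).
#' @param name region name.
#' @return a `roi_polygon`: `vertices`, `boundary` (sampled closed polyline,
#'   um), `mask` (logical super-resolved matrix), `area_um2` (of the sampled
#'   boundary polygon), `name`.
#' @export
roi_from_vertices <- function(vertices, geom, tension = 1, name = "roi") {
  vertices <- as.matrix(vertices)
  stopifnot(nrow(vertices) >= 3, ncol(vertices) == 2, tension >= 0.75)
  if (polygon_area(vertices) < 1e-9) {
    stop("control vertices are collinear/degenerate: zero-area region")
  }
  h <- hobby_closed(vertices, tension)
  s <- sample_hobby(h)
  b <- s$pts
  nb <- nrow(b)
  # self-intersection check on the sampled boundary, skipping neighbours
  for (i in seq_len(nb)) {
    a1 <- b[i, ]; a2 <- b[i %% nb + 1L, ]
    jmax <- nb - (i == 1L)   # skip the closing segment's adjacency to i = 1
    if (i + 2L > jmax) next
    for (j in (i + 2L):jmax) {
      if (segments_intersect(a1, a2, b[j, ], b[j %% nb + 1L, ])) {
        stop(sprintf("self-intersecting boundary: spline segments %d and %d cross",
                     s$seg[i], s$seg[j]))
      }
    }
  }
  mask <- roi_rasterize(b, geom)
  structure(list(vertices = vertices, boundary = b, mask = mask,
                 area_um2 = polygon_area(b), geom = geom, name = name,
                 tension = tension),
            class = "roi_polygon")
}

roi_rasterize <- function(boundary, geom) {
  zc <- sr_to_um(geom, seq_len(geom$nz_sr))
  xc <- sr_to_um(geom, seq_len(geom$nx_sr))
  # restrict the point-in-polygon test to the bounding box
  zr <- range(boundary[, 1]); xr <- range(boundary[, 2])
  iz <- which(zc >= zr[1] & zc <= zr[2])
  ix <- which(xc >= xr[1] & xc <= xr[2])
  mask <- matrix(FALSE, geom$nz_sr, geom$nx_sr)
  if (length(iz) && length(ix)) {
    pz <- rep(zc[iz], times = length(ix))
    px <- rep(xc[ix], each = length(iz))
    inside <- points_in_polygon(pz, px, boundary)
    mask[iz, ix] <- matrix(inside, length(iz), length(ix))
  }
  mask
}

#' Build an ROI directly from a raster mask
#'
#' For simulator-defined regions (e.g. the cortical / deep bands of the
#' synthetic cohort) where no hand-placed boundary exists.
#'
#' @param mask logical super-resolved matrix.
#' @param geom matching [grid_geometry()].
#' @param name region name.
#' @return a `roi_polygon` (with `vertices`/`boundary` set to `NULL`).
#' @export
roi_from_mask <- function(mask, geom, name = "roi") {
  stopifnot(is.logical(mask), any(mask))
  structure(list(vertices = NULL, boundary = NULL, mask = mask,
                 area_um2 = sum(mask) * geom$sr_pitch^2, geom = geom,
                 name = name, tension = NA_real_),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("roi_polygon '%s': %d px (%.3g mm^2)\n", x$name, sum(x$mask),
              sum(x$mask) * x$geom$sr_pitch^2 / 1e6))
  invisible(x)
}

#' Read / write named ROI vertex files
#'
#' Plain-text round-trippable geometry: one `roi <name> <tension> <n>` header
#' per region followed by `n` lines of `z_um x_um`.
#'
#' @param rois named list of vertex matrices (or `roi_polygon`s with
#'   vertices).
#' @param path file path.
#' @export
write_rois <- function(rois, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(rois)) {
    r <- rois[[nm]]
    v <- if (inherits(r, "roi_polygon")) r$vertices else as.matrix(r)
    tn <- if (inherits(r, "roi_polygon")) r$tension else 1
    writeLines(sprintf("roi %s %s %d", nm, fmt_num(tn), nrow(v)), con)
    writeLines(sprintf("%s %s", fmt_num(v[, 1]), fmt_num(v[, 2])), con)
  }
  invisible(path)
}

#' @rdname write_rois
#' @return `read_rois`: named list with elements `vertices` and `tension`.
#' @export
read_rois <- function(path) {
  lines <- readLines(path)
  out <- list(); i <- 1L
  while (i <= length(lines)) {
    hd <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    stopifnot(hd[1] == "roi")
    n <- as.integer(hd[4])
    v <- do.call(rbind, lapply(lines[(i + 1L):(i + n)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    out[[hd[2]]] <- list(vertices = v, tension = as.numeric(hd[3]))
    i <- i + n + 1L
  }
  out
}

# --- regional metrics ------------------------------------------------------

track_in_roi <- function(tr, roi) {
  iz <- pmin(pmax(um_to_sr(roi$geom, tr$z_um), 1L), roi$geom$nz_sr)
  ix <- pmin(pmax(um_to_sr(roi$geom, tr$x_um), 1L), roi$geom$nx_sr)
  any(roi$mask[cbind(iz, ix)])
}

#' Regional blood volume: mean microbubble count per acquisition
#'
#' Blood volume is estimated as the mean, over acquisitions, of the number of
#' distinct microbubble tracks that enter the ROI (a track crossing the
#' boundary repeatedly counts once).
#'
#' @param tracksets list of `track_set`s, one per acquisition.
#' @param roi a `roi_polygon`.
#' @return mean bubbles/acquisition.
#' @export
blood_volume <- function(tracksets, roi) {
  if (!length(tracksets)) stop("zero acquisitions")
  mean(vapply(tracksets, function(ts) {
    sum(vapply(ts, track_in_roi, TRUE, roi = roi))
  }, 1))
}

#' Regional vascularity: percentage of the ROI that is perfused
#'
#' Binarizes the super-resolved density map (perfused = density >= threshold
#' traversals) and reports the perfused percentage of the ROI cross-section.
#'
#' @param image a `ulm_image`.
#' @param roi a `roi_polygon`.
#' @param binarize_threshold traversal count defining "perfused" (default 1).
#' @return percent in [0, 100].
#' @export
vascularity <- function(image, roi, binarize_threshold = 1) {
  stopifnot(any(roi$mask))
  100 * mean(image$density[roi$mask] >= binarize_threshold)
}

#' Regional mean velocity and tortuosity over intersecting tracks
#'
#' Track-level averaging: every track with at least one point inside the ROI
#' contributes its mean speed and its SOAM once.
#'
#' @param tracks a `track_set`.
#' @param roi a `roi_polygon`.
#' @param frame_rate_hz frame rate, Hz.
#' @param soam_smooth_window,soam_resample_um geometry conditioning passed to
#'   [track_summary()].
#' @return list `mean_speed_mm_s`, `mean_soam_deg_mm`, `n_tracks`; speeds are
#'   `NA` (with a warning) when no track intersects the ROI.
#' @export
region_velocity_and_soam <- function(tracks, roi,
                                     frame_rate_hz = attr(tracks, "frame_rate_hz"),
                                     soam_smooth_window = 1L,
                                     soam_resample_um = 0) {
  if (!length(tracks)) {
    warning("no tracks intersect ROI '", roi$name, "'")
    return(list(mean_speed_mm_s = NA_real_, mean_soam_deg_mm = NA_real_,
                n_tracks = 0L))
  }
  inroi <- vapply(tracks, track_in_roi, TRUE, roi = roi)
  if (!any(inroi)) {
    warning("no tracks intersect ROI '", roi$name, "'")
    return(list(mean_speed_mm_s = NA_real_, mean_soam_deg_mm = NA_real_,
                n_tracks = 0L))
  }
  sel <- tracks[inroi]
  attributes(sel) <- c(attributes(tracks)[setdiff(names(attributes(tracks)), "names")],
                       list(names = names(sel)))
  ts <- track_summary(sel, frame_rate_hz, soam_smooth_window, soam_resample_um)
  list(mean_speed_mm_s = mean(ts$mean_speed_mm_s),
       mean_soam_deg_mm = mean(ts$soam_deg_mm),
       n_tracks = nrow(ts))
}

#' Stratify vessels by accumulation density (K-means, 6 clusters)
#'
#' 1-D K-means on the log-compressed nonzero density values, with a
#' deterministic k-means++-style initialization on the sorted values (fixed
#' seed, so the segmentation is invariant to pixel order). Clusters are ranked
#' by centroid; the top `n_large` clusters form the large-vessel mask, the
#' remainder the small-vessel mask.
#'
#' @param density super-resolved traversal-count matrix.
#' @param k number of clusters (default 6).
#' @param n_large clusters labeled "large" (default 2).
#' @param seed RNG seed for the initialization.
#' @return a `vessel_segmentation`: `labels` (integer matrix, 0 = background,
#'   1..k by increasing centroid), `large_mask`, `small_mask`, `centers`
#'   (log10 density).
#' @export
kmeans_vessel_split <- function(density, k = 6L, n_large = 2L, seed = 1L) {
  nz <- which(density > 0)
  vals <- log10(as.numeric(density[nz]))
  if (length(unique(vals)) < k) {
    stop("fewer than k = ", k, " distinct nonzero density values; use a smaller k")
  }
  ord <- order(vals)
  x <- vals[ord]
  centers <- with_seed(child_seed(seed, 7L), kmeanspp_1d(x, k))
  km <- stats::kmeans(x, centers = matrix(centers, ncol = 1), iter.max = 100L)
  rank_by_center <- rank(km$centers[, 1], ties.method = "first")
  lab_sorted <- rank_by_center[km$cluster]
  labels_vec <- integer(length(vals))
  labels_vec[ord] <- lab_sorted
  labels <- matrix(0L, nrow(density), ncol(density))
  labels[nz] <- labels_vec
  large <- labels >= (k - n_large + 1L)
  small <- labels > 0L & !large
  structure(list(labels = labels, large_mask = large, small_mask = small,
                 centers = sort(km$centers[, 1])),
            class = "vessel_segmentation")
}

# k-means++ seeding on a sorted 1-D vector.
kmeanspp_1d <- function(x, k) {
  centers <- x[sample.int(length(x), 1L)]
  while (length(centers) < k) {
    d2 <- vapply(x, function(v) min((v - centers)^2), 1)
    if (all(d2 == 0)) {
      centers <- c(centers, sample(setdiff(unique(x), centers), k - length(centers)))
      break
    }
    centers <- c(centers, x[sample.int(length(x), 1L, prob = d2)])
  }
  sort(unique(centers))[seq_len(k)]
}

#' Mean intervessel distance of the large-vessel map
#'
#' Twice the mean, over non-vessel ROI pixels, of the Euclidean distance to
#' the nearest large-vessel pixel (Euclidean distance transform); the factor 2
#' converts the nearest-wall distance into a wall-to-wall spacing. This
#' construction is recorded in the result's `definition` attribute.
#'
#' @param large_mask logical large-vessel matrix.
#' @param roi a `roi_polygon`.
#' @param pitch_um pixel pitch of the mask, um.
#' @return intervessel distance, um; 0 if the ROI is fully covered by vessel.
#' @export
intervessel_distance <- function(large_mask, roi, pitch_um = roi$geom$sr_pitch) {
  if (!any(large_mask)) stop("empty large-vessel mask")
  free <- roi$mask & !large_mask
  if (!any(free)) return(structure(0, definition = "2 * mean nearest-wall distance"))
  dist_px <- EBImage::distmap(1 - large_mask)
  structure(2 * mean(dist_px[free]) * pitch_um,
            definition = "2 * mean nearest-wall distance")
}

#' Skewness of the blood-velocity distribution
#'
#' Adjusted Fisher-Pearson sample skewness G1 of per-track mean speeds,
#' `G1 = sqrt(n(n-1))/(n-2) * m3 / m2^(3/2)`; the headline metric separating
#' stratified (heavy-tailed, more fast large-vessel flow) from gradual
#' velocity distributions.
#'
#' @param speeds numeric vector of per-track mean speeds (>= 3 values).
#' @return G1; `NA` with a warning if the variance is zero.
#' @export
velocity_skewness <- function(speeds) {
  n <- length(speeds)
  if (n < 3) stop("skewness needs at least 3 values")
  m <- mean(speeds)
  m2 <- mean((speeds - m)^2)
  if (m2 == 0) {
    warning("zero variance: skewness undefined")
    return(NA_real_)
  }
  m3 <- mean((speeds - m)^3)
  sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
}
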