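#' Link per-frame localizations into microbubble tracks
#'
#' Frame-to-frame centroid pairing by gated optimal assignment: for each frame
#' pair the pairing maximizes the number of links within the speed gate
#' (distance <= `max_speed_mm_s / frame_rate * gap`) and, among those, minimizes
#' the summed Euclidean distance (max-weight bipartite matching with weight
#' `10 * gate - distance`). Unassigned detections start new tracks; a track
#' unmatched for more than `gap_close` frames is terminated. Ties are broken
#' by lowest (frame, detection index) through the deterministic construction
#' order of the assignment graph.
#'
#' @param localizations data.frame `frame, z_um, x_um` (extra columns kept).
#' @param frame_rate_hz frame rate, Hz.
#' @param max_speed_mm_s speed gate, mm/s (default 50).
#' @param gap_close number of missed frames a track may survive (default 0 =
#'   pure frame-to-frame pairing; up to 2).
#' @return a `track_set`: list of tracks (each a data.frame `frame, z_um,
#'   x_um`) with the linking parameters attached as attributes.
#' @export
link_frames <- function(localizations, frame_rate_hz, max_speed_mm_s = 50,
                        gap_close = 0L) {
  stopifnot(max_speed_mm_s > 0, gap_close >= 0L, gap_close <= 2L)
  cols <- c("frame", "z_um", "x_um")
  stopifnot(all(cols %in% names(localizations)))
  gate1 <- max_speed_mm_s * 1e3 / frame_rate_hz   # um per frame step
  done <- list()
  active <- list()   # each: list(pts = matrix(frame, z, x), last = frame)
  if (nrow(localizations)) {
    localizations <- localizations[order(localizations$frame), , drop = FALSE]
    frames <- seq(min(localizations$frame), max(localizations$frame))
    by_frame <- split(seq_len(nrow(localizations)), localizations$frame)
    for (f in frames) {
      idx <- by_frame[[as.character(f)]]
      dz <- localizations$z_um[idx]; dx <- localizations$x_um[idx]
      nd <- length(idx)
      nt <- length(active)
      assigned_trk <- integer(0); assigned_det <- integer(0)
      if (nt > 0 && nd > 0) {
        lastz <- vapply(active, function(a) a$pts[nrow(a$pts), 2], 1)
        lastx <- vapply(active, function(a) a$pts[nrow(a$pts), 3], 1)
        lastf <- vapply(active, function(a) a$last, 1)
        gates <- gate1 * (f - lastf)
        dist <- sqrt(outer(lastz, dz, "-")^2 + outer(lastx, dx, "-")^2)
        ok <- which(dist <= gates, arr.ind = TRUE)
        if (nrow(ok)) {
          gmax <- max(gates)
          wts <- 10 * gmax - dist[ok]
          edges <- rbind(ok[, 1], nt + ok[, 2])
          g <- igraph::make_bipartite_graph(c(rep(FALSE, nt), rep(TRUE, nd)),
                                            as.vector(edges))
          m <- igraph::max_bipartite_match(g, weights = wts)$matching
          assigned_trk <- which(!is.na(m[seq_len(nt)]))
          assigned_det <- m[assigned_trk] - nt
        }
      }
      if (length(assigned_trk)) {
        for (k in seq_along(assigned_trk)) {
          ti <- assigned_trk[k]; di <- assigned_det[k]
          active[[ti]]$pts <- rbind(active[[ti]]$pts, c(f, dz[di], dx[di]))
          active[[ti]]$last <- f
        }
      }
      # terminate stale tracks
      if (length(active)) {
        stale <- vapply(active, function(a) f - a$last > gap_close, TRUE)
        done <- c(done, lapply(active[stale], `[[`, "pts"))
        active <- active[!stale]
      }
      # new tracks from unassigned detections
      new_d <- setdiff(seq_len(nd), assigned_det)
      for (di in new_d) {
        active[[length(active) + 1L]] <- list(
          pts = matrix(c(f, dz[di], dx[di]), 1L), last = f)
      }
    }
  }
  done <- c(done, lapply(active, `[[`, "pts"))
  tracks <- lapply(done, function(p) {
    data.frame(frame = as.integer(p[, 1]), z_um = p[, 2], x_um = p[, 3])
  })
  structure(tracks, class = "track_set", frame_rate_hz = frame_rate_hz,
            max_speed_mm_s = max_speed_mm_s, gap_close = gap_close)
}

#' @export
print.track_set <- function(x, ...) {
  n <- vapply(x, nrow, 1L)
  cat(sprintf("track_set: %d tracks (lengths %s)\n", length(x),
              if (length(n)) paste0(min(n), "-", max(n)) else "-"))
  invisible(x)
}

#' Remove tracks shorter than a minimum trajectory length
#'
#' A 20-frame (20 ms at 1000 Hz) minimum trajectory length is applied before
#' any reconstruction or quantification.
#'
#' @param tracks a `track_set` (or plain list of track data.frames).
#' @param min_length minimum number of points (default 20).
#' @return filtered `track_set`, original order preserved.
#' @export
filter_tracks <- function(tracks, min_length = 20L) {
  keep <- vapply(tracks, nrow, 1L) >= min_length
  out <- tracks[keep]
  attributes(out) <- c(attributes(tracks)[setdiff(names(attributes(tracks)), "names")],
                       list(names = names(out)))
  out
}

#' Per-track velocity from frame-to-frame displacement
#'
#' Step speed is the Euclidean centroid displacement times the frame rate (in
#' mm/s, divided by the frame gap when a link skipped frames); the track speed
#' is the arithmetic mean of step speeds. The axial direction sign is the sign
#' of the net axial displacement (+1 away from the transducer).
#'
#' @param track data.frame `frame, z_um, x_um` with >= 2 points.
#' @param frame_rate_hz frame rate, Hz.
#' @return list `step_speeds_mm_s`, `mean_speed_mm_s`, `direction_sign`.
#' @export
track_velocity <- function(track, frame_rate_hz) {
  if (nrow(track) < 2) stop("track has fewer than 2 points")
  dz <- diff(track$z_um); dx <- diff(track$x_um); df <- diff(track$frame)
  step <- sqrt(dz^2 + dx^2) / df * frame_rate_hz / 1e3
  list(step_speeds_mm_s = step,
       mean_speed_mm_s = mean(step),
       direction_sign = sign(sum(dz)))
}

# Unsigned turning-angle tortuosity of a polyline (n x 2 matrix, um).
# Zero-length segments are dropped before angle computation.
soam_polyline <- function(pts) {
  pts <- as.matrix(pts)
  d <- diff(pts)
  len <- sqrt(rowSums(d^2))
  path <- sum(len)
  e2e <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  d <- d[len > 0, , drop = FALSE]
  len <- len[len > 0]
  ang_sum <- 0
  if (nrow(d) >= 2) {
    dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE]) /
      (len[-length(len)] * len[-1])
    ang_sum <- sum(acos(pmin(pmax(dots, -1), 1))) * 180 / pi
  }
  c(soam_deg_mm = if (path > 0) ang_sum / (path / 1e3) else 0,
    angle_sum_deg = ang_sum,
    path_um = path,
    end_to_end_um = e2e,
    dm = if (e2e > 0) path / e2e else NA_real_)
}

#' Sum-of-angles tortuosity of a microbubble track
#'
#' SOAM: the sum over interior vertices of the unsigned turning angle between
#' consecutive segments, normalized by the total path length, reported in
#' degrees per millimetre. Also returns the raw angle sum and the distance
#' metric (path length / end-to-end distance). Zero-length segments are
#' dropped before angle computation. For a curve this converges to the mean
#' unsigned curvature, so a circle of radius r gives (180/pi)/r deg per unit
#' length; a straight track gives 0.
#'
#' @param track data.frame `frame, z_um, x_um` (or an n x 2 matrix of
#'   positions in um) with >= 3 points.
#' @return named vector `soam_deg_mm, angle_sum_deg, path_um, end_to_end_um,
#'   dm`.
#' @export
track_soam <- function(track) {
  pts <- if (is.data.frame(track)) as.matrix(track[, c("z_um", "x_um")]) else as.matrix(track)
  if (nrow(pts) < 3) stop("SOAM undefined for tracks with fewer than 3 points")
  soam_polyline(pts)
}

#' Smooth and resample track geometry
#'
#' `smooth_tracks()` applies a centered moving average (odd `window`) to the
#' coordinates of every track; `resample_tracks()` resamples each track's
#' polyline at a fixed arc-length spacing. Both are geometry conditioners used
#' before tortuosity estimation: raw centroids are quantized to the
#' super-resolved grid and the resulting staircase angles would otherwise
#' dominate the turning-angle sum of slow tracks.
#'
#' @param tracks a `track_set`.
#' @param window odd moving-average window (frames).
#' @return a `track_set` with conditioned geometry.
#' @export
smooth_tracks <- function(tracks, window = 5L) {
  out <- lapply(tracks, function(tr) {
    tr$z_um <- moving_average(tr$z_um, window)
    tr$x_um <- moving_average(tr$x_um, window)
    tr
  })
  attributes(out) <- attributes(tracks)
  out
}

#' @rdname smooth_tracks
#' @param spacing_um arc-length resampling step, um.
#' @export
resample_tracks <- function(tracks, spacing_um = 15) {
  out <- lapply(tracks, function(tr) {
    pts <- as.matrix(tr[, c("z_um", "x_um")])
    arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    total <- arc[length(arc)]
    if (total <= spacing_um || nrow(pts) < 3) return(tr)
    keep <- !duplicated(arc)
    s <- unique(c(seq(0, total, by = spacing_um), total))
    data.frame(frame = round(approx(arc[keep], tr$frame[keep], xout = s)$y),
               z_um = approx(arc[keep], pts[keep, 1], xout = s)$y,
               x_um = approx(arc[keep], pts[keep, 2], xout = s)$y)
  })
  attributes(out) <- attributes(tracks)
  out
}

#' Per-track summary table
#'
#' One row per track: number of points, mean speed and direction sign (from
#' [track_velocity()]), path length, end-to-end distance, SOAM and distance
#' metric (from [track_soam()], computed on optionally smoothed/resampled
#' geometry).
#'
#' @param tracks a `track_set`.
#' @param frame_rate_hz frame rate, Hz (default: the set's attribute).
#' @param soam_smooth_window moving-average window for SOAM geometry (1 = raw).
#' @param soam_resample_um arc-length resampling step for SOAM geometry
#'   (0 = raw).
#' @return data.frame `track_id, n_points, mean_speed_mm_s, direction_sign,
#'   path_um, end_to_end_um, soam_deg_mm, angle_sum_deg, dm`.
#' @export
track_summary <- function(tracks, frame_rate_hz = attr(tracks, "frame_rate_hz"),
                          soam_smooth_window = 1L, soam_resample_um = 0) {
  stopifnot(!is.null(frame_rate_hz))
  geom_tracks <- tracks
  if (soam_smooth_window > 1L) geom_tracks <- smooth_tracks(geom_tracks, soam_smooth_window)
  if (soam_resample_um > 0) geom_tracks <- resample_tracks(geom_tracks, soam_resample_um)
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    if (nrow(tr) < 3) return(NULL)  # SOAM undefined: skipped
    v <- track_velocity(tr, frame_rate_hz)
    s <- soam_polyline(as.matrix(geom_tracks[[i]][, c("z_um", "x_um")]))
    data.frame(track_id = i, n_points = nrow(tr),
               mean_speed_mm_s = v$mean_speed_mm_s,
               direction_sign = v$direction_sign,
               path_um = s[["path_um"]], end_to_end_um = s[["end_to_end_um"]],
               soam_deg_mm = s[["soam_deg_mm"]],
               angle_sum_deg = s[["angle_sum_deg"]], dm = s[["dm"]])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(track_id = integer(), n_points = integer(),
                      mean_speed_mm_s = numeric(), direction_sign = numeric(),
                      path_um = numeric(), end_to_end_um = numeric(),
                      soam_deg_mm = numeric(), angle_sum_deg = numeric(),
                      dm = numeric()))
  }
  do.call(rbind, rows)
}

#' Export tracks as tidy CSV
#'
#' Writes one row per track point (`track_id, frame, z_um, x_um,
#' step_speed_mm_s`) and, optionally, the per-track summary.
#'
#' @param tracks a `track_set`.
#' @param path output CSV path.
#' @param summary_path optional path for the [track_summary()] CSV.
#' @param frame_rate_hz frame rate, Hz.
#' @export
export_tracks_csv <- function(tracks, path, summary_path = NULL,
                              frame_rate_hz = attr(tracks, "frame_rate_hz")) {
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    sp <- if (nrow(tr) >= 2) {
      c(NA, track_velocity(tr, frame_rate_hz)$step_speeds_mm_s)
    } else NA
    cbind(track_id = i, tr, step_speed_mm_s = sp)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(summary_path)) {
    utils::write.csv(track_summary(tracks, frame_rate_hz), summary_path,
                     row.names = FALSE)
  }
  invisible(path)
}
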