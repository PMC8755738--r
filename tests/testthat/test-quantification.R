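# ROI construction and regional metrics.

geom32 <- function() grid_geometry(acquisition_params(), c(32L, 32L))

as_track_set <- function(tracks) {
  structure(tracks, class = "track_set", frame_rate_hz = 1000)
}

test_that("Hobby ROI passes through its vertices and bounds a square", {
  geom <- geom32()
  # 1 mm axis-aligned square, high tension -> mask area within 2% of 1 mm^2
  sq <- rbind(c(300, 300), c(1300, 300), c(1300, 1300), c(300, 1300))
  roi <- roi_from_vertices(sq, geom, tension = 40)
  area_mm2 <- sum(roi$mask) * geom$sr_pitch^2 / 1e6
  expect_lt(abs(area_mm2 - 1), 0.02)

  # convex pentagon: every vertex on the boundary within half a pixel
  th <- seq(0, 2 * pi, length.out = 6)[-6]
  pent <- cbind(800 + 400 * cos(th), 800 + 400 * sin(th))
  roi_p <- roi_from_vertices(pent, geom)
  for (i in seq_len(nrow(pent))) {
    d <- sqrt(rowSums(sweep(roi_p$boundary, 2, pent[i, ])^2))
    expect_lt(min(d), geom$sr_pitch / 2)
  }

  # smooth interpolation through circle samples reproduces the circle area
  th12 <- seq(0, 2 * pi, length.out = 13)[-13]
  circ <- cbind(800 + 500 * cos(th12), 800 + 500 * sin(th12))
  roi_c <- roi_from_vertices(circ, geom)
  expect_lt(abs(roi_c$area_um2 / (pi * 500^2) - 1), 0.01)
})

test_that("degenerate and self-intersecting vertex sets are rejected", {
  geom <- geom32()
  col3 <- rbind(c(100, 100), c(200, 200), c(300, 300))
  expect_error(roi_from_vertices(col3, geom), "zero-area")
  bow <- rbind(c(300, 300), c(1300, 1000), c(1300, 300), c(300, 1100))
  expect_error(roi_from_vertices(bow, geom), "self-intersecting")
})

test_that("ROI vertex files round-trip", {
  geom <- geom32()
  sq <- rbind(c(300, 300), c(1300, 300), c(1300, 1300), c(300, 1300))
  roi <- roi_from_vertices(sq, geom, tension = 2, name = "cortex")
  path <- tempfile(fileext = ".txt")
  write_rois(list(cortex = roi), path)
  back <- read_rois(path)
  expect_equal(back$cortex$vertices, unname(sq))
  expect_equal(back$cortex$tension, 2)
  roi2 <- roi_from_vertices(back$cortex$vertices, geom,
                            tension = back$cortex$tension)
  expect_identical(roi2$mask, roi$mask)
  unlink(path)
})

test_that("blood volume counts distinct intersecting tracks per acquisition", {
  geom <- geom32()
  sq <- rbind(c(300, 300), c(1300, 300), c(1300, 1300), c(300, 1300))
  roi <- roi_from_vertices(sq, geom, tension = 40)
  inside <- function(n) lapply(seq_len(n), function(i) {
    data.frame(frame = 1:5, z_um = 500 + 20 * i, x_um = seq(400, 600, length.out = 5))
  })
  outside <- list(data.frame(frame = 1:5, z_um = 1500, x_um = 1500))
  acq1 <- as_track_set(c(inside(10), outside))
  acq2 <- as_track_set(c(inside(20), outside))
  expect_equal(blood_volume(list(acq1, acq2), roi), 15)
  expect_equal(blood_volume(list(as_track_set(outside)), roi), 0)
  expect_error(blood_volume(list(), roi), "zero acquisitions")
  # a track crossing the boundary repeatedly still counts once
  zig <- as_track_set(list(data.frame(
    frame = 1:7, z_um = 800, x_um = c(200, 500, 200, 500, 200, 500, 200))))
  expect_equal(blood_volume(list(zig), roi), 1)
  # order invariance: splitting and re-merging acquisitions changes nothing
  expect_equal(blood_volume(list(as_track_set(rev(unclass(acq1)))), roi),
               blood_volume(list(acq1), roi))
})

test_that("vascularity is the perfused percentage of the ROI", {
  geom <- geom32()
  sq <- rbind(c(300, 300), c(1300, 300), c(1300, 1300), c(300, 1300))
  roi <- roi_from_vertices(sq, geom, tension = 40)
  img <- list(density = matrix(1L, geom$nz_sr, geom$nx_sr), geom = geom)
  expect_equal(vascularity(img, roi), 100)
  img$density[] <- 0L
  expect_equal(vascularity(img, roi), 0)
  # one straight 2-px-wide vessel: percentage equals direct pixel counting
  img$density[150:151, ] <- 3L
  oracle <- 100 * sum(img$density[roi$mask] >= 1) / sum(roi$mask)
  expect_equal(vascularity(img, roi), oracle)
  # area-weighted union property for disjoint ROIs
  m1 <- matrix(FALSE, geom$nz_sr, geom$nx_sr); m1[50:100, 50:200] <- TRUE
  m2 <- matrix(FALSE, geom$nz_sr, geom$nx_sr); m2[200:240, 50:300] <- TRUE
  r1 <- roi_from_mask(m1, geom); r2 <- roi_from_mask(m2, geom)
  ru <- roi_from_mask(m1 | m2, geom)
  vu <- vascularity(img, ru)
  v1 <- vascularity(img, r1); v2 <- vascularity(img, r2)
  expect_equal(vu, (v1 * sum(m1) + v2 * sum(m2)) / sum(m1 | m2),
               tolerance = 1e-12)
  expect_true(vu >= min(v1, v2) && vu <= max(v1, v2))
})

test_that("regional velocity and SOAM average per intersecting track", {
  geom <- geom32()
  sq <- rbind(c(300, 300), c(1300, 300), c(1300, 1300), c(300, 1300))
  roi <- roi_from_vertices(sq, geom, tension = 40)
  t1 <- data.frame(frame = 1:11, z_um = 500, x_um = seq(400, 420, by = 2))
  t2 <- data.frame(frame = 1:11, z_um = 600, x_um = seq(400, 460, by = 6))
  out <- data.frame(frame = 1:11, z_um = 1500, x_um = seq(1400, 1460, by = 6))
  res <- region_velocity_and_soam(as_track_set(list(t1, t2, out)), roi)
  expect_equal(res$n_tracks, 2)
  expect_equal(res$mean_speed_mm_s, (2 + 6) / 2, tolerance = 1e-9)
  expect_equal(res$mean_soam_deg_mm, 0, tolerance = 1e-9)
  expect_warning(res0 <- region_velocity_and_soam(as_track_set(list(out)), roi),
                 "no tracks")
  expect_true(is.na(res0$mean_speed_mm_s))
})

test_that("K-means vessel split separates density strata deterministically", {
  set.seed(4)
  dens <- matrix(0, 60, 60)
  dens[sample(3600, 300)] <- sample(c(10, 1000), 300, replace = TRUE)
  seg <- kmeans_vessel_split(dens, k = 2, n_large = 1)
  expect_true(all(dens[seg$large_mask] == 1000))
  expect_true(all(dens[seg$small_mask] == 10))
  expect_false(any(seg$large_mask & seg$small_mask))
  expect_true(all((seg$large_mask | seg$small_mask) == (dens > 0)))

  # permutation invariance via fixed-seed deterministic initialization
  perm <- matrix(dens[sample(3600)], 60, 60)
  seg_p <- kmeans_vessel_split(perm, k = 2, n_large = 1)
  expect_true(all(perm[seg_p$large_mask] == 1000))

  # six exact levels, k = 6: one cluster per level; nearest-centroid oracle
  dens6 <- matrix(0, 40, 40)
  lv <- c(1, 4, 16, 64, 256, 1024)
  dens6[1:360] <- rep(lv, each = 60)
  seg6 <- kmeans_vessel_split(dens6, k = 6, n_large = 2)
  expect_equal(sort(unique(seg6$labels[dens6 > 0])), 1:6)
  for (i in seq_along(lv)) {
    expect_equal(unique(seg6$labels[dens6 == lv[i]]), i)
  }
  oracle <- vapply(log10(dens6[dens6 > 0]),
                   function(v) which.min(abs(v - seg6$centers)), 1L)
  expect_equal(unname(seg6$labels[dens6 > 0]), oracle)
  expect_error(kmeans_vessel_split(dens6, k = 7), "distinct")
})

test_that("intervessel distance matches the parallel-plate closed form", {
  geom <- grid_geometry(acquisition_params(), c(16L, 16L))
  pitch <- geom$sr_pitch
  n <- geom$nz_sr
  large <- matrix(FALSE, n, n)
  gap_px <- round(100 / pitch)             # two walls ~100 um apart
  r1 <- 40; r2 <- r1 + gap_px
  large[c(r1, r2), ] <- TRUE
  roi <- matrix(FALSE, n, n); roi[(r1 + 1):(r2 - 1), ] <- TRUE
  res <- intervessel_distance(large, roi_from_mask(roi, geom))
  L <- (r2 - r1) * pitch
  # oracle: 2 * mean of min(d, L - d) over uniform positions = L / 2
  oracle <- 2 * mean(vapply(seq(r1 + 1, r2 - 1), function(r) {
    min(r - r1, r2 - r) * pitch
  }, 1))
  expect_equal(unclass(res)[1], oracle, tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(abs(res - L / 2) / (L / 2), 0.06)   # discrete vs continuous
  # fully covered ROI -> 0; empty mask -> error
  expect_equal(as.numeric(intervessel_distance(roi | large,
                                               roi_from_mask(roi, geom))), 0)
  expect_error(intervessel_distance(matrix(FALSE, n, n),
                                    roi_from_mask(roi, geom)), "empty")
  # widening the ROI strictly increases the metric
  roi_w <- matrix(FALSE, n, n); roi_w[(r1 + 1):(r2 + 60), ] <- TRUE
  single <- matrix(FALSE, n, n); single[r1, ] <- TRUE
  d1 <- intervessel_distance(single, roi_from_mask(roi, geom))
  d2 <- intervessel_distance(single, roi_from_mask(roi_w, geom))
  expect_gt(d2, d1)
})

test_that("velocity skewness is the adjusted Fisher-Pearson G1", {
  expect_equal(velocity_skewness(c(1, 2, 3)), 0)
  expect_gt(velocity_skewness(c(1, 1, 1, 10)), 0)
  expect_warning(s <- velocity_skewness(rep(2, 5)), "zero variance")
  expect_true(is.na(s))
  expect_error(velocity_skewness(c(1, 2)), "at least 3")

  # location/scale invariance
  set.seed(2)
  x <- rlnorm(500, 0, 0.4)
  expect_equal(velocity_skewness(3 + 2 * x), velocity_skewness(x),
               tolerance = 1e-9)

  # lognormal closed form: (exp(s2) + 2) * sqrt(exp(s2) - 1)
  set.seed(7)
  y <- rlnorm(1e5, 0, 0.5)
  closed <- (exp(0.25) + 2) * sqrt(exp(0.25) - 1)
  expect_lt(abs(velocity_skewness(y) - closed) / closed, 0.05)
})
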