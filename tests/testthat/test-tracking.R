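# Centroid linking, track filtering, velocity and SOAM.

make_locs <- function(mat) {
  data.frame(frame = mat[, 1], z_um = mat[, 2], x_um = mat[, 3])
}

test_that("an unambiguous mover yields exactly one full-length track", {
  pitch <- 4.928
  locs <- make_locs(cbind(1:30, 500, 500 + (0:29) * pitch))
  ts <- link_frames(locs, 1000)
  expect_length(ts, 1)
  expect_equal(nrow(ts[[1]]), 30)
  v <- track_velocity(ts[[1]], 1000)
  expect_equal(v$mean_speed_mm_s, 4.928, tolerance = 1e-12)
})

test_that("linking matches a brute-force optimal assignment oracle", {
  set.seed(41)
  gate <- 50  # um at 1000 Hz and 50 mm/s
  for (rep in 1:25) {
    nt <- sample(1:3, 1); nd <- sample(1:3, 1)
    p0 <- cbind(runif(nt, 0, 300), runif(nt, 0, 300))
    p1 <- cbind(runif(nd, 0, 300), runif(nd, 0, 300))
    locs <- rbind(make_locs(cbind(1, p0[, 1], p0[, 2])),
                  make_locs(cbind(2, p1[, 1], p1[, 2])))
    ts <- link_frames(locs, 1000, max_speed_mm_s = 50)
    dist <- sqrt(outer(p0[, 1], p1[, 1], "-")^2 + outer(p0[, 2], p1[, 2], "-")^2)
    oracle <- brute_force_assignment(dist, gate)
    got_links <- sum(vapply(ts, nrow, 1L) == 2)
    expect_equal(got_links, oracle$links)
    cost <- sum(vapply(ts[vapply(ts, nrow, 1L) == 2], function(tr) {
      sqrt(diff(tr$z_um)^2 + diff(tr$x_um)^2)
    }, 1))
    expect_equal(cost, oracle$cost, tolerance = 1e-9)
  }
})

test_that("two parallel movers stay distinct", {
  locs <- do.call(rbind, lapply(1:20, function(f) {
    make_locs(rbind(c(f, 500, 100 + 5 * f), c(f, 550, 100 + 5 * f)))
  }))
  ts <- link_frames(locs, 1000)
  expect_length(ts, 2)
  expect_true(all(vapply(ts, nrow, 1L) == 20))
  expect_true(all(vapply(ts, function(tr) length(unique(tr$z_um)) == 1, TRUE)))
})

test_that("a jump beyond the gate splits the track", {
  locs <- make_locs(cbind(1:20, 500,
                          c(100 + 5 * (1:10), 2000 + 5 * (11:20))))
  ts <- link_frames(locs, 1000, max_speed_mm_s = 50)  # gate 50 um/frame
  expect_length(ts, 2)
  expect_equal(sort(vapply(ts, nrow, 1L)), c(10L, 10L))
})

test_that("gap closing bridges single missed frames when enabled", {
  frames <- setdiff(1:21, 11)
  locs <- make_locs(cbind(frames, 500, 100 + 5 * frames))
  expect_length(link_frames(locs, 1000, gap_close = 0L), 2)
  ts <- link_frames(locs, 1000, gap_close = 1L)
  expect_length(ts, 1)
  v <- track_velocity(ts[[1]], 1000)
  expect_equal(v$mean_speed_mm_s, 5, tolerance = 1e-9)
})

test_that("the 20-frame minimum keeps exactly the 20- and 21-point tracks", {
  mk <- function(n, z) make_locs(cbind(seq_len(n), z, 100 + 5 * seq_len(n)))
  locs <- rbind(mk(19, 300), mk(20, 600), mk(21, 900))
  ts <- link_frames(locs, 1000)
  expect_equal(sort(vapply(ts, nrow, 1L)), c(19L, 20L, 21L))
  kept <- filter_tracks(ts, min_length = 20)
  expect_equal(sort(vapply(kept, nrow, 1L)), c(20L, 21L))
  expect_s3_class(kept, "track_set")
  # empty set and all-pass set
  expect_length(filter_tracks(structure(list(), class = "track_set"), 20), 0)
  expect_length(filter_tracks(kept, 20), 2)
})

test_that("track velocity follows v = d * f and flags direction", {
  tr <- data.frame(frame = 1:10, z_um = seq(0, 45, by = 5), x_um = 0)
  v <- track_velocity(tr, 1000)
  expect_equal(v$mean_speed_mm_s, 5)
  expect_equal(v$direction_sign, 1)
  tr2 <- data.frame(frame = 1:5, z_um = rep(3, 5), x_um = rep(7, 5))
  expect_equal(track_velocity(tr2, 1000)$mean_speed_mm_s, 0)
  expect_error(track_velocity(tr2[1, ], 1000), "fewer than 2")
})

test_that("SOAM matches closed-form geometry", {
  # collinear -> 0, distance metric 1
  s <- track_soam(cbind(seq(0, 90, by = 10), seq(0, 180, by = 20)))
  expect_lt(unname(s["soam_deg_mm"]), 0.01)   # acos roundoff only
  expect_equal(unname(s["dm"]), 1, tolerance = 1e-12)

  # circle sampled at 1 degree: SOAM -> curvature 1/r
  r <- 1000
  th <- seq(0, pi, by = pi / 180)
  s2 <- track_soam(cbind(r * cos(th), r * sin(th)))
  expect_lt(abs(s2["soam_deg_mm"] - (180 / pi) / r * 1e3) / ((180 / pi) / r * 1e3),
            0.02)

  # right angle: 90 deg over 200 um = 450 deg/mm, dm = sqrt(2)
  s3 <- track_soam(rbind(c(0, 0), c(100, 0), c(100, 100)))
  expect_equal(unname(s3["soam_deg_mm"]), 450, tolerance = 1e-12)
  expect_equal(unname(s3["angle_sum_deg"]), 90, tolerance = 1e-12)
  expect_equal(unname(s3["dm"]), sqrt(2), tolerance = 1e-12)

  expect_error(track_soam(rbind(c(0, 0), c(1, 1))), "fewer than 3")
})

test_that("SOAM is rigid-motion invariant and scales as 1/s under dilation", {
  set.seed(9)
  pts <- cbind(cumsum(runif(20, 5, 15)), cumsum(rnorm(20, 0, 6)))
  base <- track_soam(pts)[["soam_deg_mm"]]
  th <- 0.83
  rot <- pts %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  shifted <- sweep(rot, 2, c(123.4, -77.2), "+")
  expect_equal(track_soam(shifted)[["soam_deg_mm"]], base, tolerance = 1e-9)
  expect_equal(track_soam(pts * 3)[["soam_deg_mm"]], base / 3, tolerance = 1e-9)
  # zero-length segments are dropped, not fatal
  dup <- pts[c(1, 1, 2:20), ]
  expect_equal(track_soam(dup)[["soam_deg_mm"]], base, tolerance = 1e-9)
})

test_that("recovered SOAM increases with sinusoid amplitude", {
  params <- acquisition_params()
  soam_for_amp <- function(amp) {
    fov <- c(32, 32) * 49.28
    v <- vessel_spec(c(700, 120), c(700, fov[2] - 120), radius_um = 10,
                     peak_speed_mm_s = 8, type = "sinusoid",
                     amplitude_um = amp, wavelength_um = 500)
    cfg <- scene_config(grid_shape = c(32L, 32L), vessels = list(v),
                        tissue_amplitude = 0, noise_floor = 0.01, seed = 2)
    scn <- make_scene(cfg, params)
    sim <- simulate_iq(scn, 170, seed = 2,
                       bubbles = data.frame(vessel = 1,
                                            t0_s = c(-0.06, -0.02, 0.02),
                                            offset_um = 0))
    locs <- localize_stack(sim$stack, psf_model(), 0.5, refine = TRUE)
    ts <- filter_tracks(link_frames(locs, 1000), 20)
    su <- track_summary(ts, soam_smooth_window = 5, soam_resample_um = 15)
    mean(su$soam_deg_mm)
  }
  s <- vapply(c(0, 20, 40), soam_for_amp, 1)
  expect_true(all(diff(s) > 0))
})

test_that("track recovery is near-complete on well-separated scenes", {
  # nearest-neighbour spacing >= 4x per-frame displacement by construction
  params <- acquisition_params()
  fov <- c(48, 32) * 49.28
  vessels <- lapply(seq(300, fov[1] - 320, by = 300), function(d) {
    vessel_spec(c(d, 90), c(d, fov[2] - 90), radius_um = 10,
                peak_speed_mm_s = 6, bubble_rate_hz = 0)
  })
  cfg <- scene_config(grid_shape = c(48L, 32L), vessels = vessels,
                      tissue_amplitude = 0, noise_floor = 0.01, seed = 6)
  scn <- make_scene(cfg, params)
  inj <- expand.grid(vessel = seq_along(vessels), t0_s = c(-0.15, -0.02))
  inj$offset_um <- 0
  sim <- simulate_iq(scn, 150, seed = 6, bubbles = inj)
  locs <- localize_stack(sim$stack, psf_model(), 0.5, refine = TRUE)
  ts <- filter_tracks(link_frames(locs, 1000), 20)
  # ground-truth tracks longer than 20 frames (visible in the margin-safe
  # interior of the field of view)
  margin_x <- 2.5 * 100 + 10
  vis <- sim$truth[sim$truth$x_um > margin_x & sim$truth$x_um < fov[2] - margin_x, ]
  gt_long <- table(vis$track_id)
  gt_long <- gt_long[gt_long >= 20]
  matched <- 0
  for (id in names(gt_long)) {
    g <- vis[vis$track_id == as.integer(id), ]
    hit <- vapply(ts, function(tr) {
      common <- intersect(tr$frame, g$frame)
      if (length(common) < 0.9 * nrow(g)) return(FALSE)
      gi <- g[match(common, g$frame), ]
      ti <- tr[match(common, tr$frame), ]
      d <- sqrt((gi$z_um - ti$z_um)^2 + (gi$x_um - ti$x_um)^2)
      mean(d < 15) >= 0.9
    }, TRUE)
    if (any(hit)) matched <- matched + 1
  }
  expect_gte(matched / length(gt_long), 0.95)
})
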