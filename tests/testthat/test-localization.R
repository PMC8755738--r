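# PSF fitting, separation filtering, upsampling and centroid localization.

test_that("fit_psf recovers generated Gaussian widths", {
  pitch <- 49.28 / 4
  zc <- (1:64 - 0.5) * pitch; xc <- (1:64 - 0.5) * pitch
  patch <- 2 * outer(exp(-(zc - 400)^2 / (2 * 60^2)),
                     exp(-(xc - 390)^2 / (2 * 100^2)))
  fit <- fit_psf(patch, pitch)
  expect_lt(abs(fit$sigma_ax_um - 60) / 60, 0.01)
  expect_lt(abs(fit$sigma_lat_um - 100) / 100, 0.01)
  expect_lt(abs(fit$amplitude - 2) / 2, 0.01)
  expect_lt(max(abs(attr(fit, "center_um") - c(400, 390))), 1)

  expect_error(fit_psf(matrix(0, 16, 16), pitch), "zero")

  # Monte-Carlo with 5% white noise: sigmas within 5% on average
  set.seed(31)
  sig <- replicate(100, {
    f <- fit_psf(patch + rnorm(length(patch), sd = 0.05 * max(patch)), pitch)
    c(f$sigma_ax_um, f$sigma_lat_um)
  })
  expect_lt(abs(mean(sig[1, ]) - 60) / 60, 0.05)
  expect_lt(abs(mean(sig[2, ]) - 100) / 100, 0.05)
})

test_that("fit_psf rejects non-bubble-like patches", {
  set.seed(5)
  junk <- matrix(abs(rnorm(900)), 30, 30)  # white noise, no dominant peak
  expect_error(fit_psf(junk, 10), "residual")
})

test_that("separation bank is a partition of unity and exactly invertible", {
  bank <- separation_bank(64, 1000, n_bands = 2L)
  expect_length(bank, 4)
  expect_equal(Reduce(`+`, bank), rep(1, 64), tolerance = 1e-12)
  expect_true(all(unlist(bank) >= 0 & unlist(bank) <= 1))

  sim <- simulate_iq(make_scene(tissue_bubble_scene(seed = 13)), 64, seed = 13)
  subs <- separation_filter(sim$stack, bank)
  resid <- Reduce(`+`, lapply(subs, function(s) s$iq)) - sim$stack$iq
  expect_lt(sqrt(sum(Mod(resid)^2) / sum(Mod(sim$stack$iq)^2)), 1e-6)

  # trivial all-ones bank is the identity
  triv <- structure(list(all = rep(1, 64)), class = "separation_bank")
  out <- separation_filter(sim$stack, triv)
  expect_lt(sqrt(sum(Mod(out$all$iq - sim$stack$iq)^2) /
                   sum(Mod(sim$stack$iq)^2)), 1e-9)

  # failing partition of unity is an error
  bad <- structure(list(a = rep(0.5, 64)), class = "separation_bank")
  expect_error(separation_filter(sim$stack, bad), "partition of unity")
})

test_that("direction split isolates opposed axial flows", {
  fov <- c(48, 16) * 49.28
  v_down <- vessel_spec(c(150, fov[2] * 0.3), c(fov[1] - 150, fov[2] * 0.3),
                        radius_um = 12, peak_speed_mm_s = 8, flow_sign = 1)
  v_up <- vessel_spec(c(150, fov[2] * 0.7), c(fov[1] - 150, fov[2] * 0.7),
                      radius_um = 12, peak_speed_mm_s = 8, flow_sign = -1)
  cfg <- scene_config(grid_shape = c(48L, 16L), vessels = list(v_down, v_up),
                      tissue_amplitude = 0, noise_floor = 0)
  sim <- simulate_iq(make_scene(cfg), 128, seed = 7,
                     bubbles = data.frame(vessel = c(1, 2), t0_s = -0.1,
                                          offset_um = 0))
  bank <- separation_bank(128, 1000, n_bands = 1L)
  subs <- separation_filter(sim$stack, bank)
  # lateral halves of the field separate the two bubbles
  lhs <- 1:8; rhs <- 9:16
  e <- function(stack, cols) sum(Mod(stack$iq[, cols, ])^2)
  # vessel 1 flows away (+z): positive Doppler -> "pos" subset
  expect_gt(e(subs$pos, lhs) / (e(subs$pos, lhs) + e(subs$neg, lhs)), 0.9)
  expect_gt(e(subs$neg, rhs) / (e(subs$pos, rhs) + e(subs$neg, rhs)), 0.9)
})

test_that("upsampling is spline-exact and registered to native centers", {
  expect_error(upsample_frame(matrix(1, 4, 4), 2.5), "integer")
  m <- matrix(rnorm(36), 6, 6)
  expect_equal(upsample_frame(m, 1), abs(m))

  # bilinear ramp reproduced exactly (splines are exact for cubics)
  z <- 1:8; x <- 1:10
  ramp <- outer(2 + 3 * z, 5 + 2 * x, function(a, b) a * b)
  up <- upsample_frame(ramp, 5)
  zu <- seq(1, 8, by = 1 / 5); xu <- seq(1, 10, by = 1 / 5)
  oracle <- outer(2 + 3 * zu, 5 + 2 * xu, function(a, b) a * b)
  expect_equal(up, oracle, tolerance = 1e-9)

  # native centers land on super-resolved centers
  expect_equal(dim(up), c(36L, 46L))
  expect_equal(up[seq(1, 36, by = 5), seq(1, 46, by = 5)], ramp)

  # peak of a shifted Gaussian lands within half a super-resolved pixel
  params <- acquisition_params()
  geom <- grid_geometry(params, c(32L, 32L))
  pos <- c(802.3, 777.9)
  fr <- render_iq_frame(matrix(pos, 1), c(32, 32), params)
  sr <- upsample_frame(fr, 10)
  # dense-evaluation oracle: the true envelope peak is at the bubble position
  pk <- which(sr == max(sr), arr.ind = TRUE)[1, ]
  pk_um <- sr_to_um(geom, pk)
  expect_lt(max(abs(pk_um - pos)), geom$sr_pitch)
})

test_that("localization hits a noiseless bubble within one super-res pixel", {
  params <- acquisition_params()
  geom <- grid_geometry(params, c(32L, 32L))
  pos <- c(743.1, 911.7)
  fr <- render_iq_frame(matrix(pos, 1), c(32, 32), params)
  loc <- localize_frame(upsample_frame(fr, 10), psf_model(), geom, 0.5)
  expect_equal(nrow(loc), 1L)
  expect_lt(sqrt((loc$z_um - pos[1])^2 + (loc$x_um - pos[2])^2),
            geom$sr_pitch)
})

test_that("pure-noise frames yield no detections at a high threshold", {
  params <- acquisition_params()
  geom <- grid_geometry(params, c(32L, 32L))
  set.seed(3)
  fr <- matrix(abs(rnorm(1024)), 32, 32)
  loc <- localize_frame(upsample_frame(fr, 10), psf_model(), geom, 0.99)
  expect_equal(nrow(loc), 0L)
  # empty frame: empty result, no error
  loc0 <- localize_frame(matrix(0, 311, 311), psf_model(), geom, 0.5)
  expect_equal(nrow(loc0), 0L)
})

test_that("bubble pairs resolve at 3 lateral sigmas but not at 0.5", {
  params <- acquisition_params()
  geom <- grid_geometry(params, c(32L, 32L))
  psf <- psf_model()   # sigma_lat 100 um
  mk <- function(sep) {
    pos <- rbind(c(700, 640 - sep / 2), c(700, 640 + sep / 2))
    localize_frame(upsample_frame(render_iq_frame(pos, c(32, 32), params), 10),
                   psf, geom, 0.5)
  }
  expect_equal(nrow(mk(3 * psf$sigma_lat_um)), 2L)
  expect_equal(nrow(mk(0.5 * psf$sigma_lat_um)), 1L)
})

test_that("raising the correlation threshold never adds detections", {
  params <- acquisition_params()
  geom <- grid_geometry(params, c(32L, 32L))
  set.seed(17)
  pos <- cbind(runif(5, 400, 1100), runif(5, 400, 1100))
  fr <- render_iq_frame(pos, c(32, 32), params) +
    matrix(complex(real = rnorm(1024, sd = 0.02),
                   imaginary = rnorm(1024, sd = 0.02)), 32, 32)
  sr <- upsample_frame(fr, 10)
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th) {
    nrow(localize_frame(sr, psf_model(), geom, th))
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("separation reduces per-subset detection counts on dense scenes", {
  fov <- c(48, 24) * 49.28
  mk_v <- function(x_frac, sgn) {
    vessel_spec(c(200, fov[2] * x_frac), c(fov[1] - 200, fov[2] * x_frac),
                radius_um = 10, peak_speed_mm_s = 8, flow_sign = sgn,
                bubble_rate_hz = 40)
  }
  cfg <- scene_config(grid_shape = c(48L, 24L),
                      vessels = lapply(seq(0.15, 0.85, length.out = 5),
                                       function(xf) mk_v(xf, sample(c(-1, 1), 1))),
                      tissue_amplitude = 0, noise_floor = 0.01, seed = 3)
  scn <- make_scene(cfg)
  sim <- simulate_iq(scn, 48, seed = 3)
  expect_gte(max(table(sim$truth$frame)), 10)  # dense concurrent bubbles
  psf <- psf_model()
  n_unsep <- nrow(localize_stack(sim$stack, psf, 0.5)) / 48
  bank <- separation_bank(48, 1000, n_bands = 1L)
  subs <- separation_filter(sim$stack, bank)
  n_sub <- vapply(subs, function(s) nrow(localize_stack(s, psf, 0.5)) / 48, 1)
  expect_true(all(n_sub < n_unsep))
})
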