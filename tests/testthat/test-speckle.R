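test_that("temporal contrast is sd-over-mean with sample (n-1) denominator", {
  # temporally constant sequence: K = 0 everywhere
  sq <- flat_seq(100, f = 10)
  sm <- temporal_speckle_contrast(sq, t_w = 10 / 30, t_on = 0)
  expect_true(all(sm$K == 0))

  # two-frame window alternating 100/200: K = sd(c(100,200)) / 150
  fr <- array(0L, dim = c(8, 8, 2))
  fr[, , 1] <- 100L; fr[, , 2] <- 200L
  sq2 <- frame_sequence(fr, 30, 1)
  sm2 <- temporal_speckle_contrast(sq2, t_w = 2 / 30, t_on = 0)
  expect_equal(sm2$K[1, 1], sd(c(100, 200)) / 150, tolerance = 1e-12)
  expect_equal(sm2$K[1, 1], 0.4714, tolerance = 1e-4)

  # multiplying all intensities by a constant leaves K unchanged
  fr3 <- fr; fr3[, , 1] <- 50L; fr3[, , 2] <- 100L
  sm3 <- temporal_speckle_contrast(frame_sequence(fr3, 30, 1), t_w = 2 / 30)
  expect_equal(sm3$K, sm2$K, tolerance = 1e-12)

  expect_error(temporal_speckle_contrast(sq, t_w = 1 / 60), "2 frames")
  expect_error(temporal_speckle_contrast(sq, t_w = 10 / 30, t_on = 5), "outside")

  # masked pixels carry NA, never numbers
  m <- matrix(FALSE, 8, 8); m[1:4, ] <- TRUE
  sq4 <- frame_sequence(fr, 30, 1, mask = m)
  sm4 <- temporal_speckle_contrast(sq4, t_w = 2 / 30)
  expect_true(all(is.na(sm4$K[1:4, ])))
  expect_true(all(is.finite(sm4$K[5:8, ])))
})

test_that("radial profiles are flat on constant-contrast data and cover 5-305 um", {
  fr <- array(0L, dim = c(100, 100, 4))
  fr[, , c(1, 3)] <- 100L; fr[, , c(2, 4)] <- 200L
  sq <- frame_sequence(fr, 30, 1, tip_center = c(50, 95))
  sm <- temporal_speckle_contrast(sq, t_w = 4 / 30)
  expect_message(
    prof <- radial_contrast_profiles(sm, directions = "vertical"),
    "omitted"
  )
  expect_equal(range(prof$r_um), c(5, 85))  # in-frame part of the 5-305 grid
  expect_equal(prof$K, rep(prof$K[1], nrow(prof)), tolerance = 1e-10)
  expect_equal(prof$K_inv, 1 / prof$K, tolerance = 1e-10)

  avg <- average_contrast_profile(
    suppressMessages(radial_contrast_profiles(
      sm, directions = c("vertical", "left-diagonal", "right-diagonal"))))
  expect_true(all(abs(avg$K - prof$K[1]) < 1e-10))
  expect_true(all(avg$K_sd[avg$n_dir > 1] < 1e-10))
})

test_that("velocity calibration fits the identity line and rejects non-physical slopes", {
  kinv <- tibble::tibble(r_um = seq(5, 305, 10), K_inv = seq(5, 305, 10) / 10)
  vel <- tibble::tibble(r_mean_um = seq(5, 305, 10), v_um_s = seq(5, 305, 10) / 10)
  cal <- calibrate_velocity(kinv, vel)
  expect_equal(cal$slope, 1, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-8)
  expect_equal(cal$zero_velocity_cutoff, 0, tolerance = 1e-8)
  expect_equal(cal$r_squared, 1, tolerance = 1e-9)
  g <- glance(cal)
  expect_equal(g$slope, 1, tolerance = 1e-9)

  # a fitted line crossing v = 0 at K^-1 = 3.855 puts the cutoff there
  cal2 <- calibrate_velocity(
    tibble::tibble(r_um = 1:20, K_inv = 3.855 + (1:20) / 2),
    tibble::tibble(r_mean_um = 1:20, v_um_s = (1:20)))
  expect_equal(cal2$zero_velocity_cutoff, 3.855, tolerance = 1e-6)

  # anti-correlated data has no physical calibration
  expect_error(
    calibrate_velocity(tibble::tibble(r_um = 1:10, K_inv = 10:1),
                       tibble::tibble(r_mean_um = 1:10, v_um_s = 1:10)),
    "not positive"
  )

  # noisy calibration recovers the slope within 10% across replicates
  set.seed(12)
  slopes <- replicate(100, {
    ki <- tibble::tibble(r_um = seq(5, 295, 10), K_inv = 2 + seq(5, 295, 10) / 30)
    ve <- tibble::tibble(r_mean_um = ki$r_um,
                         v_um_s = pmax(4 * (ki$K_inv - 2) + rnorm(30, 0, 2), 0))
    calibrate_velocity(ki, ve)$slope
  })
  expect_gt(mean(abs(slopes - 4) / 4 < 0.10), 0.95)
})

test_that("velocity maps clamp below the cutoff, stay non-negative, and zero out masked pixels", {
  fr <- array(0L, dim = c(20, 20, 4))
  fr[, , c(1, 3)] <- 100L; fr[, , c(2, 4)] <- 200L
  m <- matrix(FALSE, 20, 20); m[, 1:5] <- TRUE
  sq <- frame_sequence(fr, 30, 1, mask = m)
  sm <- temporal_speckle_contrast(sq, t_w = 4 / 30)
  kinv_val <- 1 / sm$K[1, 10]

  # cutoff above the map's K^-1: everything maps to zero
  cal_hi <- structure(list(slope = 10, intercept = -10 * (kinv_val + 1),
                           zero_velocity_cutoff = kinv_val + 1,
                           r_squared = 1, n = 10,
                           data = tibble::tibble(r_um = 1, K_inv = 1, v_um_s = 50)),
                      class = "speckle_calibration")
  vm0 <- velocity_map(sm, cal_hi)
  expect_true(all(vm0$v == 0))

  # K^-1 one unit above the cutoff with slope 10: v = 10 um/s
  cal <- structure(list(slope = 10, intercept = -10 * (kinv_val - 1),
                        zero_velocity_cutoff = kinv_val - 1,
                        r_squared = 1, n = 10,
                        data = tibble::tibble(r_um = 1, K_inv = kinv_val, v_um_s = 50)),
                   class = "speckle_calibration")
  vm <- velocity_map(sm, cal)
  expect_equal(vm$v[1, 10], 10, tolerance = 1e-9)
  expect_true(all(vm$v[m] == 0))
  expect_true(all(vm$v >= 0))
})

test_that("speckle contrast of the synthetic video orders windows and tracks speed", {
  # window-length trade-off, isolated on a statistically stationary scene
  # (pure Brownian suspension): longer windows reduce the spatial variance
  # of the K estimate, shorter windows are noisier
  cfg_s <- sim_config(frame_width_px = 120, frame_height_px = 120,
                      fiber_diameter = 20, duration = 40, v_max = 0,
                      trap_rate = 0, recirculation = 0, bath_exchange = 0,
                      seed = 8)
  vid_s <- render_frames(simulate_tracks(cfg_s), cfg_s)
  v5 <- var(as.vector(temporal_speckle_contrast(vid_s, t_w = 5, t_on = 10)$K),
            na.rm = TRUE)
  v20 <- var(as.vector(temporal_speckle_contrast(vid_s, t_w = 20, t_on = 10)$K),
             na.rm = TRUE)
  expect_gt(v5, v20)

  sv <- shared_video()
  cfg <- sv$cfg

  # K^-1 is monotonically associated with the ground-truth speed
  sm <- temporal_speckle_contrast(sv$video, t_w = 15, t_on = 25, smooth_px = 9)
  avg <- average_contrast_profile(suppressMessages(radial_contrast_profiles(
    sm, directions = c("left-diagonal", "vertical", "right-diagonal"),
    r_range = c(5, 145), entry_edge = "bottom")))
  v_true <- velocity_field(avg$r_um, t = 1e6, cfg)
  expect_gt(cor(avg$K_inv, v_true, method = "spearman"), 0.9)
})
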