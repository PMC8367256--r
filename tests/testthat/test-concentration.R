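test_that("ROI concentration is 255 minus the mean intensity", {
  seq_white <- flat_seq(255, h = 300, w = 300, f = 3, tip_center = c(150, 290))
  roi <- roi_concentration(seq_white, directions = "vertical", n_rois = 10)
  expect_true(all(roi$C == 0))

  seq_gray <- flat_seq(155, h = 300, w = 300, f = 3, tip_center = c(150, 290))
  roi <- roi_concentration(seq_gray, directions = "vertical", n_rois = 10)
  expect_true(all(roi$C == 100))
  expect_equal(sort(unique(roi$r_um)), seq(5, 95, by = 10))

  # darkening pixels inside an ROI strictly raises its C
  fr <- array(200L, dim = c(300, 300, 2))
  fr[260:270, 145:155, ] <- 60L   # near r = 25 um on the vertical ray
  seq_dark <- frame_sequence(fr, 30, 1, tip_center = c(150, 290))
  roi2 <- roi_concentration(seq_dark, directions = "vertical", n_rois = 10)
  expect_gt(mean(roi2$C[roi2$r_um == 25]), mean(roi2$C[roi2$r_um == 95]))

  # ROIs that leave the frame are dropped with a message
  expect_message(
    roi_concentration(flat_seq(100, h = 60, w = 60, f = 2, tip_center = c(30, 50)),
                      directions = "vertical", n_rois = 20),
    "dropped"
  )
  # masked pixels never contribute: mask the left half of each ROI and
  # blacken it; C must reflect only the unmasked pixels
  m <- matrix(FALSE, 300, 300); m[, 1:150] <- TRUE
  fr2 <- array(200L, dim = c(300, 300, 2))
  fr2[, 1:150, ] <- 0L
  sq <- frame_sequence(fr2, 30, 1, tip_center = c(150, 290), mask = m)
  roi3 <- roi_concentration(sq, directions = "vertical", n_rois = 5)
  expect_true(all(roi3$C == 55))
})

test_that("moving average uses a truncated centered window and reports spread", {
  const <- moving_average(rep(7, 30))
  expect_equal(const$C_smooth, rep(7, 30))
  expect_equal(const$C_sd, rep(0, 30))

  ramp <- moving_average(0:20, half_width = 5)
  expect_equal(ramp$C_smooth[11], 10)       # symmetric window on linear data
  expect_equal(ramp$C_smooth[1], mean(0:5)) # truncated left edge: 2.5
  expect_equal(ramp$C_sd[11], sd(5:15))

  df <- tibble::tibble(direction = "vertical",
                       r_um = rep(c(5, 15), each = 21),
                       t_s = rep(0:20, 2), C = rep(0:20, 2))
  sm <- moving_average(df)
  expect_equal(sm$C_smooth[sm$r_um == 15][1], 2.5)
  expect_error(moving_average(numeric(0)), "empty")
})

test_that("noise-free exponential decay is recovered to machine-level accuracy", {
  t <- seq(0, 150, by = 0.5)
  C <- 100 - 80 * exp(-t / 20)
  fit <- fit_exponential_decay(tibble::tibble(t_s = t, C = C))
  expect_equal(fit$C_sat, 100, tolerance = 1e-6)
  expect_equal(fit$a, -80, tolerance = 1e-6)
  expect_equal(fit$tau, 20, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_false(fit$flagged)
  td <- tidy(fit)
  expect_equal(unname(td$estimate[td$term == "tau"]), 20, tolerance = 1e-6)

  flat <- fit_exponential_decay(tibble::tibble(t_s = t, C = rep(5, length(t))))
  expect_true(flat$flagged)
})

test_that("decay parameters are recovered from noisy traces within 5 percent", {
  set.seed(314)
  est <- t(replicate(100, {
    t <- seq(0, 150, length.out = 1000)
    C <- 100 - 80 * exp(-t / 20) + rnorm(1000, 0, 2)
    f <- fit_exponential_decay(tibble::tibble(t_s = t, C = C))
    c(f$C_sat, f$a, f$tau)
  }))
  truth <- c(100, -80, 20)
  rel <- sweep(sweep(est, 2, truth), 2, abs(truth), "/")
  expect_true(all(abs(colMeans(rel)) < 0.02))       # unbiased at the 2% level
  expect_gt(mean(abs(rel[, 3]) < 0.05), 0.95)       # tau within 5% almost always
})

test_that("Gaussian profile fits recover width exactly and under noise", {
  r <- seq(5, 195, by = 10)
  C <- 10 + 120 * exp(-r^2 / (2 * 63.70^2))
  fit <- fit_gaussian_profile(tibble::tibble(r_um = r, C = C))
  expect_equal(fit$fwhm, 150.0, tolerance = 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # height scaling leaves the width untouched
  fit2 <- fit_gaussian_profile(tibble::tibble(r_um = r, C = 10 + 240 * exp(-r^2 / (2 * 63.70^2))))
  expect_equal(fit2$fwhm, fit$fwhm, tolerance = 1e-6)
  expect_equal(fit2$height, 2 * fit$height, tolerance = 1e-6)

  flat <- fit_gaussian_profile(tibble::tibble(r_um = r, C = rep(3, length(r))))
  expect_true(flat$flagged)

  set.seed(99)
  sig <- replicate(100, {
    Cn <- 10 + 120 * exp(-r^2 / (2 * 63.70^2)) + rnorm(length(r), 0, 2)
    fit_gaussian_profile(tibble::tibble(r_um = r, C = Cn))$sigma
  })
  expect_true(all(abs(sig - 63.70) / 63.70 < 0.10))
})

test_that("accumulation limit reads the C_sat step and degenerates gracefully", {
  fits <- tibble::tibble(r_um = seq(5, 195, 10),
                         C_sat = ifelse(seq(5, 195, 10) <= 75, 100, 5),
                         tau = 20)
  lim <- estimate_accumulation_limit(fits)
  expect_equal(lim$r_lim_um, 75)
  expect_named(lim$profile, c("r_um", "C_sat", "tau"))

  expect_warning(
    lim2 <- estimate_accumulation_limit(tibble::tibble(r_um = seq(5, 95, 10),
                                                       C_sat = 50)),
    "no decay"
  )
  expect_equal(lim2$r_lim_um, 95)
  expect_warning(
    lim3 <- estimate_accumulation_limit(tibble::tibble(r_um = seq(5, 95, 10),
                                                       C_sat = 0.01)),
    "noise floor"
  )
  expect_true(is.na(lim3$r_lim_um))
})

test_that("radially symmetric accumulation gives agreeing directional profiles", {
  sv <- shared_video()
  roi <- suppressMessages(roi_concentration(
    sv$video, directions = c("left-horizontal", "vertical", "right-horizontal"),
    n_rois = 8))
  # time-averaged late-phase concentration per direction at matched radii
  late <- roi |>
    dplyr::filter(t_s > 30) |>
    dplyr::group_by(direction, r_um) |>
    dplyr::summarise(C = mean(C), .groups = "drop") |>
    tidyr::pivot_wider(names_from = direction, values_from = C)
  common <- stats::na.omit(late)
  expect_gt(nrow(common), 4)
  spread <- apply(common[, -1], 1, function(x) diff(range(x)))
  scale <- max(abs(as.matrix(common[, -1])))
  expect_lt(max(spread) / scale, 0.30)
})
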