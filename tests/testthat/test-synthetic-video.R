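test_that("velocity field is zero in the boundary layer, plateaus at v_max, and ramps from zero", {
  cfg <- sim_config(seed = 1)
  # inside the boundary layer: no in-plane flow, at any time
  expect_equal(velocity_field(c(0, 10, 25.6), t = 1e6, cfg), c(0, 0, 0))
  # far field with ramp disabled: the plateau speed
  cfg_nr <- sim_config(ramp = FALSE, seed = 1)
  expect_equal(velocity_field(300, t = 0, cfg_nr), 34.2)
  expect_equal(velocity_field(cfg$r_plateau, t = 1e9, cfg), 34.2, tolerance = 1e-9)
  # ramp enabled at t = 0: field is off everywhere
  expect_equal(velocity_field(c(50, 300), t = 0, cfg), c(0, 0))
  # monotone non-decreasing in r
  r <- seq(0, 400, by = 0.5)
  v <- velocity_field(r, t = 50, cfg)
  expect_true(all(diff(v) >= -1e-12))
  expect_error(velocity_field(-1, 0, cfg), "non-negative")
})

test_that("force-free bacteria stay put and identical seeds give identical tracks", {
  cfg <- sim_config(frame_width_px = 100, frame_height_px = 100,
                    n_bacteria = 30, duration = 1, v_max = 0, D_brownian = 0,
                    trap_rate = 0, seed = 9)
  sim <- simulate_tracks(cfg)
  spread <- sim$tracks |>
    dplyr::group_by(id) |>
    dplyr::summarise(dx = diff(range(x_um)), dy = diff(range(y_um)))
  expect_equal(max(spread$dx), 0)
  expect_equal(max(spread$dy), 0)

  cfg2 <- sim_config(frame_width_px = 120, frame_height_px = 100,
                     n_bacteria = 25, duration = 1, seed = 33)
  expect_identical(simulate_tracks(cfg2)$tracks, simulate_tracks(cfg2)$tracks)
})

test_that("pure drift in the plateau advances exactly v_max per unit time", {
  cfg <- drift_config(n_bacteria = 12, init_r_range = c(260, 380))
  sim <- simulate_tracks(cfg)
  tip <- (cfg$tip_center - 1) * cfg$pixel_size
  rr <- sim$tracks |>
    dplyr::mutate(r = sqrt((x_um - tip[1])^2 + (y_um - tip[2])^2)) |>
    dplyr::group_by(id) |>
    dplyr::summarise(dr = list(diff(r)), rmin = min(r))
  for (i in seq_len(nrow(rr))) {
    d <- rr$dr[[i]]
    # while above the plateau radius the step is exactly v_max * dt
    expect_equal(d[seq_len(5)], rep(-cfg$v_max / cfg$frame_rate, 5),
                 tolerance = 1e-9)
    # and r never increases anywhere along the track
    expect_true(all(d <= 1e-9))
  }
})

test_that("a drift step overshooting the boundary layer is refused", {
  expect_error(
    simulate_tracks(sim_config(frame_width_px = 100, frame_height_px = 100,
                               n_bacteria = 5, duration = 1, frame_rate = 1,
                               n_substeps = 1, v_max = 50, d_bl = 10,
                               r_plateau = 30, seed = 1)),
    "substep"
  )
})

test_that("ensemble MSD of free diffusion grows as 4 D t", {
  D <- 0.3
  cfg <- sim_config(frame_width_px = 2000, frame_height_px = 2000,
                    pixel_size = 1, n_bacteria = 600, duration = 1,
                    v_max = 0, D_brownian = D, trap_rate = 0,
                    recirculation = 0, bath_exchange = 0,
                    fiber_diameter = 1, seed = 21)
  sim <- simulate_tracks(cfg)
  tr <- sim$tracks
  t_end <- (max(tr$frame) - 1) / cfg$frame_rate
  first <- tr[tr$frame == 1, ]
  last <- tr[tr$frame == max(tr$frame), ]
  stopifnot(identical(first$id, last$id))
  sq <- (last$x_um - first$x_um)^2 + (last$y_um - first$y_um)^2
  msd <- mean(sq)
  se <- sd(sq) / sqrt(length(sq))
  expect_lt(abs(msd - 4 * D * t_end), 3 * se)
})

test_that("trapping is monotone, capacity-limited, and settled bacteria barely move", {
  cfg <- sim_config(frame_width_px = 200, frame_height_px = 200,
                    tip_center = c(100, 190), fiber_diameter = 20,
                    duration = 8, ramp = FALSE, trap_capacity = 60, seed = 4)
  sim <- simulate_tracks(cfg)
  expect_true(all(diff(sim$n_trapped) >= 0))
  expect_lte(max(sim$n_trapped), 60)
  # per-frame displacement of trapped bacteria stays below one pixel
  tr <- sim$tracks[sim$tracks$trapped, ]
  step <- tr |>
    dplyr::group_by(id) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(mx = max(sqrt(diff(x_um)^2 + diff(y_um)^2)))
  expect_lt(max(step$mx), cfg$pixel_size)
  # a bacterium never un-traps
  flips <- sim$tracks |>
    dplyr::group_by(id) |>
    dplyr::summarise(bad = any(diff(as.integer(trapped)) < 0))
  expect_false(any(flips$bad))
})

test_that("rendered frames are 8-bit, reproducible, and show bacteria as local minima", {
  # empty scene, no noise: every non-fiber pixel is exactly the background
  cfg0 <- sim_config(frame_width_px = 60, frame_height_px = 60,
                     tip_center = c(30, 50), fiber_diameter = 10,
                     n_bacteria = 0, duration = 0.1, noise_sigma = 0, seed = 1)
  vid0 <- render_frames(simulate_tracks(cfg0), cfg0)
  f1 <- vid0$frames[, , 1]
  expect_true(all(f1[!vid0$mask] == cfg0$background_level))

  # one stationary bacterium at a pixel center, no occluder: global minimum there
  cfg1 <- sim_config(frame_width_px = 41, frame_height_px = 41,
                     tip_center = c(21, 21), fiber_diameter = 0,
                     n_bacteria = 1, duration = 0.1, v_max = 0,
                     D_brownian = 0, trap_rate = 0, noise_sigma = 0,
                     contrast_flicker = 0, seed = 2)
  tracks <- tibble::tibble(frame = 1:2, id = 1L,
                           x_um = 10 * cfg1$pixel_size,
                           y_um = 15 * cfg1$pixel_size, trapped = FALSE)
  vid1 <- render_frames(tracks, cfg1)
  f <- vid1$frames[, , 1]
  expect_equal(which(f == min(f)), (10L) * 41L + 16L)  # column-major index of (row 16, col 11)
  expect_equal(min(f), cfg1$background_level - cfg1$bacterium_contrast,
               tolerance = 1)

  # more bacteria in an ROI -> lower mean intensity there
  mk <- function(n) {
    tr <- tibble::tibble(frame = rep(1:2, each = n), id = rep(seq_len(n), 2),
                         x_um = rep(seq(14, 22, length.out = n), 2),
                         y_um = rep(seq(14, 22, length.out = n), 2),
                         trapped = FALSE)
    render_frames(tr, cfg1)$frames[10:30, 10:30, 1]
  }
  expect_lt(mean(mk(6)), mean(mk(2)))

  # pixel range and reproducibility
  sv <- shared_video()
  expect_gte(min(sv$video$frames), 0)
  expect_lte(max(sv$video$frames), 255)
  cfg_r <- sim_config(frame_width_px = 50, frame_height_px = 50,
                      fiber_diameter = 10, n_bacteria = 10, duration = 0.2,
                      trap_rate = 0, seed = 77)
  expect_identical(render_frames(simulate_tracks(cfg_r), cfg_r)$frames,
                   render_frames(simulate_tracks(cfg_r), cfg_r)$frames)
})

test_that("simulation output round-trips through TIFF/CSV/JSON sidecars", {
  cfg <- sim_config(frame_width_px = 40, frame_height_px = 40,
                    fiber_diameter = 10, n_bacteria = 8, duration = 0.2,
                    trap_rate = 0, seed = 3)
  sv <- simulate_video(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sv$sim, sv$video, dir)
  expect_true(all(file.exists(file.path(dir, c("video.tif", "tracks.csv", "config.json")))))
  back <- read_video(file.path(dir, "video.tif"), cfg$frame_rate, cfg$pixel_size)
  expect_identical(back$frames, sv$video$frames)
  tr <- read_tracks(file.path(dir, "tracks.csv"))
  expect_equal(nrow(tr), nrow(sv$sim$tracks))
  meta <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(meta$config$seed, 3)
})
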