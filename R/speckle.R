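# Temporal speckle-contrast velocimetry. The per-pixel temporal contrast
# K = sigma_I / <I> over a time window falls as intensity fluctuations speed
# up, so K^-1 is proportional to the local speed; a linear calibration of
# K^-1 against tracked velocities converts contrast maps into wide-area
# speed maps.

#' Temporal speckle-contrast map
#'
#' For every unmasked pixel, computes `K = sd(I) / mean(I)` (sample standard
#' deviation, n - 1 denominator) across the frames falling in the window
#' `[t_on, t_on + t_w]`. Frames should be histogram-matched beforehand so
#' background brightness drifts do not masquerade as contrast. Pixels with
#' zero mean are flagged invalid; pixels whose windowed mean falls below
#' `low_mean` gray levels are flagged separately -- in saturated
#' accumulation regions the intensity bottoms out and the contrast there
#' reflects the swarm boundary, not a speed (the "high velocity ring"
#' artifact).
#'
#' @param seq A [frame_sequence()].
#' @param t_w Window length (s); 15 s is the resolution/sensitivity
#'   compromise used throughout.
#' @param t_on Window start time (s) relative to the first frame.
#' @param low_mean Gray-level threshold for the saturated-region flag.
#' @param smooth_px Side of the spatial box average applied to the contrast
#'   image (odd; 1 = none). A few pixels of spatial averaging is the usual
#'   speckle-contrast trade of resolution against per-pixel estimator noise.
#'
#' @return An object of class `speckle_map`: list with matrices `K`,
#'   `mean_I`, logical `valid` and `low_mean_flag`, and the window/geometry
#'   metadata. Masked or invalid pixels hold `NA` in `K`.
#' @export
temporal_speckle_contrast <- function(seq, t_w = 15, t_on = 0, low_mean = 5,
                                      smooth_px = 1L) {
  stopifnot(inherits(seq, "frame_sequence"))
  n_win <- round(t_w * seq$frame_rate)
  if (n_win < 2) abort("window must span at least 2 frames")
  i0 <- floor(t_on * seq$frame_rate) + 1L
  i1 <- i0 + n_win - 1L
  if (i0 < 1 || i1 > n_frames(seq)) {
    abort(sprintf("window [%g, %g] s falls outside the sequence", t_on, t_on + t_w))
  }
  d <- dim(seq$frames)
  s1 <- matrix(0, d[1], d[2]); s2 <- matrix(0, d[1], d[2])
  for (k in i0:i1) {
    f <- seq$frames[, , k]
    s1 <- s1 + f
    s2 <- s2 + f * f
  }
  m <- s1 / n_win
  v <- pmax(s2 - n_win * m * m, 0) / (n_win - 1)
  valid <- m > 0
  if (!is.null(seq$mask)) valid <- valid & !seq$mask
  K <- matrix(NA_real_, d[1], d[2])
  K[valid] <- sqrt(v[valid]) / m[valid]
  if (smooth_px > 1) K <- box_mean_na(K, as.integer(smooth_px))
  structure(list(
    K = K, mean_I = m, valid = valid,
    low_mean_flag = valid & m < low_mean,
    t_w = t_w, t_on = t_on,
    mask_applied = !is.null(seq$mask),
    frame_rate = seq$frame_rate, pixel_size = seq$pixel_size,
    tip_center = seq$tip_center
  ), class = "speckle_map")
}

#' @export
print.speckle_map <- function(x, ...) {
  cat(sprintf(
    "<speckle_map> %d x %d px, window [%g, %g] s, median K = %.3g%s\n",
    ncol(x$K), nrow(x$K), x$t_on, x$t_on + x$t_w,
    median(x$K, na.rm = TRUE),
    if (x$mask_applied) ", fiber masked" else ""
  ))
  invisible(x)
}

#' Inverse-contrast image
#'
#' `1 / K` with a floor `eps` on K so static (K = 0) pixels give a large
#' finite value rather than infinity; invalid pixels stay `NA`.
#'
#' @param map A `speckle_map`.
#' @param eps Floor applied to K.
#' @export
contrast_inverse <- function(map, eps = 1e-12) {
  stopifnot(inherits(map, "speckle_map"))
  1 / pmax(map$K, eps)
}

#' Radial contrast profiles along rays from the tip
#'
#' Samples the contrast map along each requested ray by bilinear
#' interpolation, averaging over a transverse band of `band_um`
#' perpendicular to the ray, at radial steps covering `r_range`
#' (5 to 305 um by 10 um by default). Radii whose sample points are all
#' masked or outside the frame are omitted with a notice.
#'
#' @param map A `speckle_map` with tip geometry.
#' @param directions Ray directions (see [roi_concentration()]).
#' @param r_range `c(min, max)` radial range (um).
#' @param r_step Radial step (um).
#' @param band_um Width of the transverse averaging band (um).
#' @param entry_edge Fiber entry edge defining the outward axis.
#'
#' @return A tibble `(direction, r_um, K, K_inv)`.
#' @export
radial_contrast_profiles <- function(map, directions = roi_directions(),
                                     r_range = c(5, 305), r_step = 10,
                                     band_um = 10, entry_edge = "bottom") {
  stopifnot(inherits(map, "speckle_map"))
  if (is.null(map$tip_center)) abort("`map` carries no tip_center")
  px <- map$pixel_size
  rs <- seq(r_range[1], r_range[2], by = r_step)
  offs <- seq(-band_um / 2, band_um / 2, length.out = 11)
  omitted <- 0L

  res <- purrr::map_dfr(directions, function(dir) {
    u <- direction_unit(dir, entry_edge)
    perp <- c(-u[2], u[1])
    kv <- vapply(rs, function(r) {
      xs <- map$tip_center[1] + (u[1] * r + perp[1] * offs) / px
      ys <- map$tip_center[2] + (u[2] * r + perp[2] * offs) / px
      mean(bilinear_sample(map$K, xs, ys), na.rm = TRUE)
    }, numeric(1))
    tibble::tibble(direction = dir, r_um = rs, K = kv)
  })
  res <- res[is.finite(res$K), ]
  omitted <- length(directions) * length(rs) - nrow(res)
  if (omitted > 0) {
    inform(sprintf("omitted %d profile point(s) outside the usable image", omitted))
  }
  if (!nrow(res)) abort("all profile points are masked or outside the frame")
  res$K_inv <- 1 / pmax(res$K, 1e-12)
  res
}

# NA-aware k x k box mean (edge-replicated); NA where no neighbor is valid
box_mean_na <- function(m, k) {
  if (k %% 2L == 0L) abort("`smooth_px` must be odd")
  pad <- (k - 1L) %/% 2L
  acc <- matrix(0, nrow(m), ncol(m))
  cnt <- matrix(0L, nrow(m), ncol(m))
  ri <- seq_len(nrow(m)); ci <- seq_len(ncol(m))
  for (di in -pad:pad) {
    rows <- pmin(pmax(ri + di, 1L), nrow(m))
    for (dj in -pad:pad) {
      cols <- pmin(pmax(ci + dj, 1L), ncol(m))
      sh <- m[rows, cols]
      ok <- !is.na(sh)
      acc[ok] <- acc[ok] + sh[ok]
      cnt <- cnt + ok
    }
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  out[is.na(m)] <- NA_real_   # never invent values on masked pixels
  out
}

# bilinear interpolation on a matrix at fractional pixel coordinates
# (x = column, y = row, 1-based); NA outside or where any corner is NA
bilinear_sample <- function(mat, x, y) {
  h <- nrow(mat); w <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  ok <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]
  fx <- x[ok] - x0; fy <- y[ok] - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  out[ok] <- (1 - fy) * ((1 - fx) * mat[i00] + fx * mat[i01]) +
    fy * ((1 - fx) * mat[i10] + fx * mat[i11])
  out
}

#' Direction-averaged contrast profile
#'
#' @param profiles Output of [radial_contrast_profiles()].
#' @return A tibble `(r_um, K, K_sd, K_inv, K_inv_sd, n_dir)` averaging the
#'   per-direction profiles at each radius.
#' @export
average_contrast_profile <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$r_um) |>
    dplyr::summarise(
      K_sd = sd(.data$K), K = mean(.data$K),
      K_inv_sd = sd(.data$K_inv), K_inv = mean(.data$K_inv),
      n_dir = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::select("r_um", "K", "K_sd", "K_inv", "K_inv_sd", "n_dir")
}

#' Calibrate inverse contrast against tracked velocities
#'
#' Linearly interpolates the tracked speed-versus-distance profile onto the
#' radii of the averaged K^-1 profile (only radii inside the tracked range
#' are used) and fits `v = slope * K^-1 + intercept` by ordinary least
#' squares. The zero-velocity cutoff is the K^-1 value where the line
#' crosses v = 0: predictions below it are mathematically sound but not
#' physically meaningful and are clamped to zero when mapping.
#'
#' @param kinv_profile Tibble with `r_um` and `K_inv` (e.g. from
#'   [average_contrast_profile()]).
#' @param vel_profile Tibble with `r_mean_um` and `v_um_s` (from
#'   [velocity_profile()]).
#'
#' @return An object of class `speckle_calibration` with `slope` (um/s per
#'   unit K^-1), `intercept` (um/s), `zero_velocity_cutoff`, `r_squared`,
#'   `n`, and the paired calibration `data`.
#' @export
calibrate_velocity <- function(kinv_profile, vel_profile) {
  stopifnot(all(c("r_um", "K_inv") %in% names(kinv_profile)),
            all(c("r_mean_um", "v_um_s") %in% names(vel_profile)))
  vp <- vel_profile[order(vel_profile$r_mean_um), ]
  rng <- range(vp$r_mean_um)
  kp <- kinv_profile[kinv_profile$r_um >= rng[1] & kinv_profile$r_um <= rng[2], ]
  if (nrow(kp) < 3) abort("fewer than 3 radii overlap between the two profiles")
  v_interp <- approx(vp$r_mean_um, vp$v_um_s, xout = kp$r_um, ties = mean)$y
  dat <- tibble::tibble(r_um = kp$r_um, K_inv = kp$K_inv, v_um_s = v_interp)
  fit <- lm(v_um_s ~ K_inv, data = dat)
  slope <- coef(fit)[["K_inv"]]
  if (!is.finite(slope) || slope <= 0) {
    abort("calibration slope is not positive; no physical K^-1 to velocity mapping")
  }
  intercept <- coef(fit)[["(Intercept)"]]
  structure(list(
    slope = slope, intercept = intercept,
    zero_velocity_cutoff = -intercept / slope,
    r_squared = suppressWarnings(summary(fit)$r.squared), n = nrow(dat),
    data = dat, fit = fit
  ), class = "speckle_calibration")
}

#' @export
print.speckle_calibration <- function(x, ...) {
  cat(sprintf(
    "<speckle_calibration> v = %.3g * K^-1 + %.3g um/s (R^2 = %.3f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  cat(sprintf("  zero-velocity cutoff: K^-1 = %.4g\n", x$zero_velocity_cutoff))
  invisible(x)
}

#' @export
tidy.speckle_calibration <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit)$coefficients)
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = s[, 1], std.error = s[, 2])
}

#' @export
glance.speckle_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 zero_velocity_cutoff = x$zero_velocity_cutoff,
                 r_squared = x$r_squared, n = x$n)
}

#' Convert a contrast map into an in-plane velocity map
#'
#' Applies the linear calibration per pixel: `v = slope * K^-1 + intercept`,
#' clamped to zero wherever K^-1 falls below the zero-velocity cutoff, and
#' zero on invalid or masked pixels. By default predictions are also capped
#' at the largest velocity in the calibration data: beyond it the linear
#' map is extrapolation outside its fitted domain. Saturated-region pixels
#' (low windowed mean) keep their value but are flagged.
#'
#' @param map A `speckle_map`.
#' @param calibration A `speckle_calibration`.
#' @param clamp_to_calibrated Cap predictions at the maximum calibrated
#'   speed.
#'
#' @return An object of class `velocity_map`: list with matrix `v` (um/s,
#'   everywhere >= 0), logical `flagged` (saturated-region pixels), and the
#'   geometry/window metadata.
#' @export
velocity_map <- function(map, calibration, clamp_to_calibrated = TRUE) {
  stopifnot(inherits(map, "speckle_map"), inherits(calibration, "speckle_calibration"))
  kinv <- contrast_inverse(map)
  v <- calibration$slope * kinv + calibration$intercept
  v[!is.finite(v)] <- 0
  v[kinv < calibration$zero_velocity_cutoff] <- 0
  v[!map$valid] <- 0
  v[v < 0] <- 0
  if (clamp_to_calibrated) v <- pmin(v, max(calibration$data$v_um_s))
  structure(list(
    v = v, flagged = map$low_mean_flag, t_w = map$t_w, t_on = map$t_on,
    pixel_size = map$pixel_size, tip_center = map$tip_center,
    calibration = calibration
  ), class = "velocity_map")
}

#' @export
print.velocity_map <- function(x, ...) {
  cat(sprintf(
    "<velocity_map> %d x %d px, window [%g, %g] s, max v = %.3g um/s, %d flagged px\n",
    ncol(x$v), nrow(x$v), x$t_on, x$t_on + x$t_w, max(x$v), sum(x$flagged)))
  invisible(x)
}

#' Velocity maps for a sweep of window start times
#'
#' Computes [temporal_speckle_contrast()] and [velocity_map()] at each
#' requested `t_on` (e.g. 0, 20, 40, 60 s), reusing one calibration.
#'
#' @param seq A [frame_sequence()].
#' @param calibration A `speckle_calibration`.
#' @param t_on_values Window start times (s).
#' @param t_w Window length (s).
#'
#' @return A named list of `velocity_map`s.
#' @export
velocity_map_sweep <- function(seq, calibration, t_on_values = c(0, 20, 40, 60),
                               t_w = 15) {
  maps <- lapply(t_on_values, function(t0) {
    velocity_map(temporal_speckle_contrast(seq, t_w = t_w, t_on = t0), calibration)
  })
  names(maps) <- paste0("t_on_", t_on_values)
  maps
}
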