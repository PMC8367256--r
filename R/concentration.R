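# ROI concentration traces and accumulation-kinetics fits. Concentration is
# the arbitrary transmitted-light proxy C = 255 - mean ROI intensity: darker
# ROIs (more bacteria blocking the light) score higher.

direction_unit <- function(direction, entry_edge) {
  # outward = away from the fiber along its axis; "left"/"right" are the
  # observer's left/right when looking outward from the tip
  ang <- switch(direction,
    "vertical" = 0,
    "left-diagonal" = -pi / 4, "right-diagonal" = pi / 4,
    "left-horizontal" = -pi / 2, "right-horizontal" = pi / 2,
    abort(sprintf("unknown direction '%s'", direction))
  )
  out <- switch(entry_edge,
    bottom = c(0, -1), top = c(0, 1), left = c(1, 0), right = c(-1, 0)
  )
  perp <- c(-out[2], out[1])
  cos(ang) * out + sin(ang) * perp
}

roi_directions <- function() {
  c("left-horizontal", "left-diagonal", "vertical",
    "right-diagonal", "right-horizontal")
}

#' ROI concentration time series along rays from the tip
#'
#' Places `n_rois` contiguous square ROIs (default twenty 10 x 10 um^2
#' squares, centers at r = 5, 15, ..., 195 um) along each requested ray from
#' the tip center and extracts `C(t) = 255 - mean(I)` over the unmasked ROI
#' pixels of every frame. ROIs that do not fit inside the frame, or whose
#' pixels are all masked, are dropped with a message.
#'
#' @param seq A [frame_sequence()] with `tip_center` set.
#' @param directions Character vector among `"left-horizontal"`,
#'   `"left-diagonal"`, `"vertical"`, `"right-diagonal"`,
#'   `"right-horizontal"`.
#' @param n_rois Number of ROIs per ray.
#' @param roi_size_um ROI side length (um).
#' @param entry_edge Fiber entry edge defining the outward axis.
#'
#' @return A tibble `(direction, r_um, frame, t_s, C)`.
#' @export
roi_concentration <- function(seq, directions = roi_directions(),
                              n_rois = 20, roi_size_um = 10,
                              entry_edge = "bottom") {
  stopifnot(inherits(seq, "frame_sequence"))
  if (is.null(seq$tip_center)) abort("`seq` has no tip_center")
  d <- dim(seq$frames)
  px <- seq$pixel_size
  half_px <- roi_size_um / px / 2
  r_centers <- roi_size_um * (seq_len(n_rois) - 0.5)
  times <- frame_times(seq)
  keep_mask <- if (!is.null(seq$mask)) !seq$mask else NULL

  out <- list()
  dropped <- character(0)
  for (dir in directions) {
    u <- direction_unit(dir, entry_edge)
    for (r in r_centers) {
      cx <- seq$tip_center[1] + u[1] * r / px
      cy <- seq$tip_center[2] + u[2] * r / px
      cols <- seq.int(ceiling(cx - half_px), floor(cx + half_px))
      rows <- seq.int(ceiling(cy - half_px), floor(cy + half_px))
      if (min(cols) < 1 || max(cols) > d[2] || min(rows) < 1 || max(rows) > d[1]) {
        dropped <- c(dropped, sprintf("%s r=%g (outside frame)", dir, r))
        next
      }
      sel <- if (is.null(keep_mask)) NULL else keep_mask[rows, cols]
      if (!is.null(sel) && !any(sel)) {
        dropped <- c(dropped, sprintf("%s r=%g (fully masked)", dir, r))
        next
      }
      block <- seq$frames[rows, cols, , drop = FALSE]
      mi <- if (is.null(sel)) {
        colMeans(matrix(block, ncol = d[3]))
      } else {
        colMeans(matrix(block, ncol = d[3])[as.vector(sel), , drop = FALSE])
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        direction = dir, r_um = r, frame = seq_len(d[3]),
        t_s = times, C = 255 - mi
      )
    }
  }
  if (length(dropped)) {
    inform(paste0("dropped ", length(dropped), " ROI(s): ",
                  paste(head(dropped, 5), collapse = "; "),
                  if (length(dropped) > 5) " ..." else ""))
  }
  if (!length(out)) abort("no usable ROI")
  dplyr::bind_rows(out)
}

#' Centered moving average of concentration traces
#'
#' For each time point, averages the value at that point and the
#' `half_width` points on either side (window truncated at the ends), and
#' reports the within-window standard deviation. Applied per
#' `(direction, r_um)` series when those columns are present.
#'
#' @param data A tibble with a `C` column (e.g. from [roi_concentration()]),
#'   or a bare numeric vector.
#' @param half_width Points on each side of the center (default 5, i.e. an
#'   11-point window).
#'
#' @return The input with `C_smooth` and `C_sd` columns added (for a vector:
#'   a tibble with `C`, `C_smooth`, `C_sd`).
#' @export
moving_average <- function(data, half_width = 5) {
  if (half_width < 0) abort("`half_width` must be non-negative")
  smooth_one <- function(v) {
    n <- length(v)
    if (n == 0L) abort("empty series")
    m <- s <- numeric(n)
    for (i in seq_len(n)) {
      w <- v[max(1, i - half_width):min(n, i + half_width)]
      m[i] <- mean(w)
      s[i] <- if (length(w) > 1) sd(w) else 0
    }
    list(mean = m, sd = s)
  }
  if (is.numeric(data)) {
    sm <- smooth_one(data)
    return(tibble::tibble(C = data, C_smooth = sm$mean, C_sd = sm$sd))
  }
  if (!"C" %in% names(data)) abort("`data` must have a `C` column")
  grp <- intersect(c("direction", "r_um"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(
      C_smooth = smooth_one(.data$C)$mean,
      C_sd = smooth_one(.data$C)$sd
    ) |>
    dplyr::ungroup()
}

#' Fit saturating exponential accumulation kinetics
#'
#' Fits `C(t) = C_sat + a * exp(-t / tau)` by nonlinear least squares
#' (Levenberg-Marquardt), initialized from the tail mean, the initial
#' offset, and the 1/e crossing time. Near-constant input or a failed fit
#' yields a flagged result rather than silent numbers.
#'
#' @param data A tibble with columns `t_s` and `C` (or `C_smooth`, used when
#'   `use_smoothed = TRUE` and present).
#' @param use_smoothed Fit the moving-averaged trace when available.
#'
#' @return An object of class `decay_fit` with fields `C_sat`, `a`, `tau`,
#'   `r_squared`, `converged`, `flagged`, `reason`. [tidy()] and [glance()]
#'   methods are provided.
#' @examples
#' t <- seq(0, 150, by = 0.5)
#' fit <- fit_exponential_decay(tibble::tibble(t_s = t, C = 100 - 80 * exp(-t / 20)))
#' glance(fit)
#' @export
fit_exponential_decay <- function(data, use_smoothed = FALSE) {
  y <- if (use_smoothed && "C_smooth" %in% names(data)) data$C_smooth else data$C
  t <- data$t_s
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 5) abort("need at least 5 time points")
  if (diff(range(t)) <= 0) abort("`t_s` must span a positive range")

  flagged_fit <- function(reason) {
    structure(list(C_sat = NA_real_, a = NA_real_, tau = NA_real_,
                   r_squared = NA_real_, converged = FALSE, flagged = TRUE,
                   reason = reason, n = length(t)),
              class = "decay_fit")
  }

  tail_n <- max(3L, round(length(y) / 10))
  c_sat0 <- mean(tail(y, tail_n))
  a0 <- y[1] - c_sat0
  noise <- sd(diff(y)) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  if (sd(y) < 1e-12 || abs(a0) <= 2 * noise / sqrt(length(y)) + 1e-12 && sd(y) <= noise * 1.05) {
    return(flagged_fit("near-constant series: amplitude below noise floor"))
  }
  dev <- abs(y - c_sat0)
  idx <- which(dev <= abs(a0) / exp(1))
  tau0 <- if (length(idx)) max(t[min(idx)] - t[1], diff(range(t)) / 20) else diff(range(t)) / 3

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ C_sat + a * exp(-t / tau),
      start = list(C_sat = c_sat0, a = a0, tau = tau0),
      lower = c(-Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(flagged_fit("nonlinear least squares did not converge"))
  cf <- coef(fit)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  flag <- abs(cf[["a"]]) <= 2 * noise
  structure(list(
    C_sat = cf[["C_sat"]], a = cf[["a"]], tau = cf[["tau"]],
    r_squared = r2, converged = TRUE, flagged = flag,
    reason = if (flag) "amplitude within noise floor" else NA_character_,
    n = length(t), fit = fit
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$flagged) {
    cat("<decay_fit> flagged:", x$reason, "\n")
  } else {
    cat(sprintf("<decay_fit> C_sat = %.3g, a = %.3g, tau = %.3g s (R^2 = %.4f)\n",
                x$C_sat, x$a, x$tau, x$r_squared))
  }
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("C_sat", "a", "tau"),
                          estimate = NA_real_, std.error = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(C_sat = x$C_sat, a = x$a, tau = x$tau,
                 r_squared = x$r_squared, n = x$n,
                 converged = x$converged, flagged = x$flagged)
}

#' Fit decay kinetics for every ROI series
#'
#' Convenience wrapper applying [fit_exponential_decay()] per
#' `(direction, r_um)` group.
#'
#' @inheritParams fit_exponential_decay
#' @return A tibble with one row per series: `direction`, `r_um`, `C_sat`,
#'   `a`, `tau`, `r_squared`, `converged`, `flagged`.
#' @export
fit_decay_profile <- function(data, use_smoothed = TRUE) {
  grp <- intersect(c("direction", "r_um"), names(data))
  if (!length(grp)) abort("`data` must carry direction/r_um grouping columns")
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(df, key) {
      glance(fit_exponential_decay(df, use_smoothed = use_smoothed))
    }) |>
    dplyr::ungroup()
}

#' Fit a Gaussian concentration-versus-distance profile
#'
#' Fits `C(r) = baseline + height * exp(-r^2 / (2 sigma^2))` with the peak
#' pinned at r = 0, and reports `fwhm = 2 sqrt(2 ln 2) sigma`. The baseline
#' and height are constrained to the physical concentration range (C is an
#' 8-bit-derived quantity in `[0, 255]`). Flat profiles are flagged.
#'
#' @param data A tibble with columns `r_um` and `C`.
#'
#' @return An object of class `gaussian_fit` with fields `height`, `sigma`,
#'   `fwhm`, `baseline`, `r_squared`, `flagged`.
#' @export
fit_gaussian_profile <- function(data) {
  r <- data$r_um; y <- data$C
  ok <- is.finite(r) & is.finite(y)
  r <- r[ok]; y <- y[ok]
  if (length(unique(r)) < 4) abort("need at least 4 distinct r values")

  flagged_fit <- function(reason) {
    structure(list(height = NA_real_, sigma = NA_real_, fwhm = NA_real_,
                   baseline = NA_real_, r_squared = NA_real_,
                   flagged = TRUE, reason = reason, n = length(r)),
              class = "gaussian_fit")
  }
  if (sd(y) < 1e-12) return(flagged_fit("flat profile"))

  b0 <- max(min(y), 0)
  h0 <- max(max(y) - b0, 1e-6)
  above <- which(y - b0 <= h0 / 2)
  s0 <- if (length(above)) max(r[min(above)], diff(range(r)) / 10) / 1.1774 else diff(range(r)) / 3
  try_fit <- function(b, h, s) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ baseline + height * exp(-r^2 / (2 * sigma^2)),
        start = list(baseline = b, height = h, sigma = s),
        lower = c(0, 0, 1e-9),
        upper = c(255, 510, 10 * max(abs(r))),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  fit <- try_fit(b0, h0, s0)
  if (is.null(fit)) fit <- try_fit(median(y), h0, diff(range(r)) / 3)
  if (is.null(fit)) return(flagged_fit("nonlinear least squares did not converge"))
  cf <- coef(fit)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(
    height = cf[["height"]], sigma = cf[["sigma"]],
    fwhm = 2 * sqrt(2 * log(2)) * cf[["sigma"]],
    baseline = cf[["baseline"]], r_squared = r2,
    flagged = FALSE, reason = NA_character_, n = length(r), fit = fit
  ), class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (x$flagged) {
    cat("<gaussian_fit> flagged:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<gaussian_fit> height = %.3g, FWHM = %.3g um, baseline = %.3g (R^2 = %.4f)\n",
      x$height, x$fwhm, x$baseline, x$r_squared))
  }
  invisible(x)
}

#' @export
tidy.gaussian_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("baseline", "height", "sigma"),
                          estimate = NA_real_, std.error = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(height = x$height, sigma = x$sigma, fwhm = x$fwhm,
                 baseline = x$baseline, r_squared = x$r_squared,
                 n = x$n, flagged = x$flagged)
}

#' Gaussian profile fits over time
#'
#' Fits the C-vs-r profile of one direction at a set of times and returns
#' the height/FWHM trajectories (the maturation curves of the accumulation).
#'
#' @param data ROI series tibble (one direction) with `t_s`, `r_um` and a
#'   concentration column.
#' @param times Times (s) at which to fit; defaults to ~40 evenly spaced
#'   frames.
#' @param use_smoothed Use `C_smooth` when present.
#'
#' @return A tibble `(t_s, height, sigma, fwhm, baseline, r_squared, flagged)`.
#' @export
fit_gaussian_maturation <- function(data, times = NULL, use_smoothed = TRUE) {
  val <- if (use_smoothed && "C_smooth" %in% names(data)) "C_smooth" else "C"
  all_t <- sort(unique(data$t_s))
  if (is.null(times)) {
    times <- all_t[unique(round(seq(1, length(all_t), length.out = min(40, length(all_t)))))]
  }
  purrr::map_dfr(times, function(tt) {
    t0 <- all_t[which.min(abs(all_t - tt))]
    df <- data[data$t_s == t0, c("r_um", val)]
    names(df) <- c("r_um", "C")
    g <- glance(fit_gaussian_profile(df))
    dplyr::bind_cols(tibble::tibble(t_s = t0), g[, c("height", "sigma", "fwhm",
                                                     "baseline", "r_squared", "flagged")])
  })
}

#' Matured accumulation width from a maturation curve
#'
#' Reads [fit_gaussian_maturation()] output and reports the FWHM of the
#' fully matured accumulation: fits that explain little of the profile
#' variance (`r_squared < min_r_squared`, typical of the pre-accumulation
#' phase where no Gaussian exists yet) are discarded, the height curve is
#' smoothed (running median then centered mean, robust against isolated
#' unstable fits), the plateau is the set of times from the first crossing
#' of `frac` times the maximum smoothed height onward, and the returned
#' FWHM is the median fitted FWHM over the plateau.
#'
#' @param maturation Tibble from [fit_gaussian_maturation()].
#' @param frac Fraction of the maximum smoothed height defining maturity.
#' @param min_r_squared Minimum fit quality for a time point to count.
#'
#' @return A list with `fwhm_um`, `t_matured_s` (first plateau time), and
#'   the number of fits used.
#' @export
matured_fwhm <- function(maturation, frac = 0.9, min_r_squared = 0.5) {
  ok <- !maturation$flagged & is.finite(maturation$height) &
    is.finite(maturation$fwhm) & maturation$r_squared >= min_r_squared
  m <- maturation[ok, ]
  if (nrow(m) < 3) abort("too few usable Gaussian fits to locate maturity")
  m <- m[order(m$t_s), ]
  h <- stats::runmed(m$height, k = min(5L, nrow(m) - (nrow(m) + 1) %% 2))
  h <- moving_average(h, half_width = 2)$C_smooth
  i0 <- which(h >= frac * max(h))[1]
  sel <- seq(i0, nrow(m))
  list(fwhm_um = median(m$fwhm[sel]), t_matured_s = m$t_s[i0],
       n_fits = length(sel))
}

#' Effective accumulation limit from the saturation-concentration profile
#'
#' The accumulation limit is the largest distance whose fitted saturation
#' concentration `C_sat` still reaches a fraction `f` of the maximum
#' `C_sat` over all distances; beyond it saturation is fast and shallow
#' (no effective accumulation).
#'
#' @param fits A tibble with columns `r_um` and `C_sat` (e.g. from
#'   [fit_decay_profile()]); a `tau` column, when present, is carried into
#'   the returned profile.
#' @param f Threshold fraction of the maximum `C_sat`.
#' @param noise_floor `C_sat` values below this are treated as noise.
#'
#' @return A list with `r_lim_um`, the `threshold` used, and the inspected
#'   `profile` tibble.
#' @export
estimate_accumulation_limit <- function(fits, f = 0.25, noise_floor = 1) {
  if (!all(c("r_um", "C_sat") %in% names(fits))) {
    abort("`fits` must have columns r_um and C_sat")
  }
  prof <- fits[is.finite(fits$C_sat), ]
  if (nrow(prof) < 5) abort("need fits at >= 5 distances")
  prof <- prof[order(prof$r_um), ]
  mx <- max(prof$C_sat)
  if (mx < noise_floor) {
    warn("all C_sat below the noise floor; accumulation limit undefined")
    return(list(r_lim_um = NA_real_, threshold = f * mx, profile = prof))
  }
  sel <- prof$C_sat >= f * mx
  r_lim <- max(prof$r_um[sel])
  if (all(sel)) {
    warn("C_sat profile shows no decay; r_lim is the largest sampled distance")
  }
  cols <- intersect(c("r_um", "C_sat", "tau"), names(prof))
  list(r_lim_um = r_lim, threshold = f * mx, profile = prof[, cols])
}
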