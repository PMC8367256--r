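# Frame-by-frame track velocimetry: radial-distance series, per-track
# linear r-t fits, the speed-versus-distance profile, and the boundary
# layer. The primary ingestion path mirrors manual annotation (a CSV of
# frame/id/x/y); greedy nearest-neighbor linking is provided for synthetic
# detections.

#' Read or write track annotations
#'
#' Tracks are tabular: one observation per row with columns `frame`, `id`
#' and positions either in pixels (`x_px`, `y_px`) or micrometres
#' (`x_um`, `y_um`).
#'
#' @param path CSV file path.
#' @param tracks A tracks tibble.
#' @return `read_tracks()` a tibble; `write_tracks()` the path, invisibly.
#' @export
read_tracks <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  if (!all(c("frame", "id") %in% names(df))) {
    abort("track CSV must have `frame` and `id` columns")
  }
  if (!(all(c("x_px", "y_px") %in% names(df)) ||
        all(c("x_um", "y_um") %in% names(df)))) {
    abort("track CSV must have x_px/y_px or x_um/y_um columns")
  }
  df
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbor linking: detections in consecutive frames (gap of
#' at most `max_gap` frames) are joined when closer than `max_step_um` per
#' frame step; ambiguities are resolved by smallest displacement, ties by
#' lowest track id; unlinked detections start new tracks.
#'
#' @param detections Tibble with columns `frame`, `x_um`, `y_um`.
#' @param max_step_um Maximum linking distance per frame interval (um).
#' @param max_gap Maximum number of skipped frames bridged by a link.
#'
#' @return A tracks tibble `(id, frame, x_um, y_um)` sorted by id and frame.
#' @export
link_tracks <- function(detections, max_step_um, max_gap = 1L) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)))
  det <- detections[order(detections$frame), ]
  frames <- sort(unique(det$frame))
  # active track tails
  tail_id <- integer(0); tail_f <- integer(0)
  tail_x <- numeric(0); tail_y <- numeric(0)
  next_id <- 1L
  out_id <- integer(nrow(det))
  row_of <- split(seq_len(nrow(det)), det$frame)

  for (f in frames) {
    rows <- row_of[[as.character(f)]]
    dx <- det$x_um[rows]; dy <- det$y_um[rows]
    live <- which(tail_f >= f - 1L - max_gap & tail_f < f)
    assigned <- rep(NA_integer_, length(rows))   # index into live
    if (length(live)) {
      dist <- outer(seq_along(live), seq_along(rows), function(i, j) {
        sqrt((tail_x[live[i]] - dx[j])^2 + (tail_y[live[i]] - dy[j])^2)
      })
      gapf <- f - tail_f[live]                    # frames spanned by the link
      lim <- max_step_um * gapf
      cand <- which(dist <= lim, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dist[cand], tail_id[live][cand[, 1]])
        used_t <- logical(length(live)); used_d <- logical(length(rows))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_t[i] && !used_d[j]) {
            assigned[j] <- i
            used_t[i] <- TRUE; used_d[j] <- TRUE
          }
        }
      }
    }
    for (j in seq_along(rows)) {
      if (is.na(assigned[j])) {
        tail_id <- c(tail_id, next_id); tail_f <- c(tail_f, f)
        tail_x <- c(tail_x, dx[j]); tail_y <- c(tail_y, dy[j])
        out_id[rows[j]] <- next_id
        next_id <- next_id + 1L
      } else {
        i <- assigned[j]
        out_id[rows[j]] <- tail_id[i]
        tail_f[i] <- f; tail_x[i] <- dx[j]; tail_y[i] <- dy[j]
      }
    }
  }
  res <- tibble::tibble(id = out_id, frame = det$frame,
                        x_um = det$x_um, y_um = det$y_um)
  res[order(res$id, res$frame), ]
}

#' Radial distance of each track observation from the tip
#'
#' Converts positions to micrometres when given in pixels and computes the
#' Euclidean distance to the tip center and the time of each observation.
#'
#' @param tracks Tracks tibble with `frame`, `id` and `x_um`/`y_um` or
#'   `x_px`/`y_px` columns.
#' @param tip_center `c(x, y)` tip position in pixels (1-based).
#' @param pixel_size Micrometres per pixel.
#' @param frame_rate Frames per second.
#'
#' @return A tibble `(id, frame, t_s, x_um, y_um, r_um)`, time measured from
#'   the first frame present.
#' @export
radial_distance_series <- function(tracks, tip_center, pixel_size, frame_rate) {
  stopifnot(all(c("frame", "id") %in% names(tracks)))
  if (all(c("x_um", "y_um") %in% names(tracks))) {
    x <- tracks$x_um; y <- tracks$y_um
  } else if (all(c("x_px", "y_px") %in% names(tracks))) {
    x <- (tracks$x_px - 1) * pixel_size
    y <- (tracks$y_px - 1) * pixel_size
  } else {
    abort("`tracks` must have x_um/y_um or x_px/y_px columns")
  }
  tip <- (tip_center - 1) * pixel_size
  tibble::tibble(
    id = tracks$id, frame = tracks$frame,
    t_s = (tracks$frame - min(tracks$frame)) / frame_rate,
    x_um = x, y_um = y,
    r_um = sqrt((x - tip[1])^2 + (y - tip[2])^2)
  ) |> dplyr::arrange(.data$id, .data$frame)
}

#' In-plane speed of one track from a linear r-t fit
#'
#' Ordinary least squares of distance against time; the reported speed is
#' the magnitude of the slope (speeds over the ~1 s fit window are
#' approximately constant, so a line is adequate), with the slope's
#' standard error as the uncertainty. The signed slope is retained for
#' diagnostics (negative = moving toward the tip).
#'
#' @param r_series Tibble with columns `t_s` and `r_um` (one track).
#'
#' @return One-row tibble `(v_um_s, se_um_s, slope_um_s, r_mean_um, n)`.
#' @export
fit_track_speed <- function(r_series) {
  if (nrow(r_series) < 3) abort("need at least 3 points to fit a speed")
  fit <- lm(r_um ~ t_s, data = r_series)
  sl <- coef(fit)[["t_s"]]
  # summary.lm warns on exact fits; a zero standard error is a valid answer
  se <- suppressWarnings(summary(fit)$coefficients["t_s", "Std. Error"])
  tibble::tibble(
    v_um_s = abs(sl), se_um_s = se, slope_um_s = sl,
    r_mean_um = mean(r_series$r_um), n = nrow(r_series)
  )
}

#' Speed-versus-distance profile over all tracks
#'
#' Fits each track's first `fit_window_frames` observations (tracks shorter
#' than `min_obs` are skipped with a notice) and pairs the fitted speed with
#' the track's mean distance over the fit window.
#'
#' @param tracks Tracks tibble (see [radial_distance_series()]).
#' @param tip_center,pixel_size,frame_rate Geometry of the recording.
#' @param fit_window_frames Number of leading observations fitted per track
#'   (default 30, i.e. 1 s at 30 frames/s).
#' @param min_obs Minimum observations required.
#'
#' @return A tibble `(id, r_mean_um, v_um_s, se_um_s, slope_um_s, n)` sorted
#'   by `r_mean_um`.
#' @export
velocity_profile <- function(tracks, tip_center, pixel_size, frame_rate,
                             fit_window_frames = 30L, min_obs = 3L) {
  rs <- radial_distance_series(tracks, tip_center, pixel_size, frame_rate)
  min_obs <- max(min_obs, 3L)
  idx <- split(seq_len(nrow(rs)), rs$id)
  keep <- lengths(idx) >= min_obs
  skipped <- sum(!keep)
  if (skipped > 0) inform(sprintf("skipped %d track(s) shorter than %d observations",
                                  skipped, min_obs))
  idx <- idx[keep]
  if (!length(idx)) abort("no track long enough to fit")
  res <- vapply(idx, function(ii) {
    ii <- head(ii, fit_window_frames)   # rows are frame-ordered per track
    t <- rs$t_s[ii]; r <- rs$r_um[ii]
    n <- length(ii)
    tc <- t - mean(t)
    sxx <- sum(tc^2)
    slope <- sum(tc * r) / sxx
    resid <- r - mean(r) - slope * tc
    se <- sqrt(sum(resid^2) / (n - 2) / sxx)
    c(r_mean = mean(r), v = abs(slope), se = se, slope = slope, n = n)
  }, numeric(5))
  prof <- tibble::tibble(
    id = if (is.numeric(rs$id)) as.numeric(names(idx)) else names(idx),
    r_mean_um = res["r_mean", ], v_um_s = res["v", ],
    se_um_s = res["se", ], slope_um_s = res["slope", ], n = as.integer(res["n", ])
  )
  prof[order(prof$r_mean_um), ]
}

#' Boundary-layer radius from a speed-versus-distance profile
#'
#' The boundary layer is the near-tip region where the in-plane speed
#' vanishes (the convection current turns vertical). Estimated as the
#' largest mean distance such that every profile point at or below it is
#' consistent with zero speed: `v <= max(v_zero_threshold, 2 * SE)`.
#'
#' @param profile Output of [velocity_profile()].
#' @param v_zero_threshold Speed regarded as zero (um/s).
#'
#' @return Boundary-layer radius in um (`NA` with a warning when no
#'   near-zero points exist).
#' @export
boundary_layer_radius <- function(profile, v_zero_threshold = 1) {
  stopifnot(all(c("r_mean_um", "v_um_s") %in% names(profile)))
  p <- profile[order(profile$r_mean_um), ]
  se <- if ("se_um_s" %in% names(p)) p$se_um_s else 0
  zeroish <- p$v_um_s <= pmax(v_zero_threshold, 2 * se)
  if (!any(zeroish)) {
    warn("no near-zero speeds in the profile; boundary layer undefined")
    return(NA_real_)
  }
  if (all(zeroish)) {
    warn("all speeds are near zero; boundary layer extends to the farthest track")
    return(max(p$r_mean_um))
  }
  runs <- cumsum(!zeroish) == 0   # leading block of near-zero points
  if (!any(runs)) {
    warn("nearest tracks already move; boundary layer unresolved below them")
    return(NA_real_)
  }
  max(p$r_mean_um[runs])
}
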