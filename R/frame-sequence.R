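#' Ordered stack of 8-bit grayscale frames
#'
#' The container every analysis stage works on: an integer array
#' `[row, col, frame]` with values in `[0, 255]`, the acquisition frame rate
#' and pixel size, the fiber-tip position, and optionally a logical fiber
#' mask (`TRUE` = excluded pixels).
#'
#' @param frames Integer/numeric array `[height, width, n_frames]` (a single
#'   matrix is promoted to one frame), values in `[0, 255]`.
#' @param frame_rate Frames per second.
#' @param pixel_size Micrometres per pixel.
#' @param tip_center Optional `c(x, y)` tip position in pixels
#'   (x = column, y = row, 1-based).
#' @param mask Optional logical matrix of the frame shape; `TRUE` marks
#'   pixels excluded from every downstream statistic.
#'
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate, pixel_size,
                           tip_center = NULL, mask = NULL) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (length(dim(frames)) != 3L) abort("`frames` must be a [H, W, F] array")
  if (anyNA(frames) || min(frames) < 0 || max(frames) > 255) {
    abort("frame pixel values must lie in [0, 255] with no NAs")
  }
  if (frame_rate <= 0 || pixel_size <= 0) {
    abort("`frame_rate` and `pixel_size` must be positive")
  }
  storage.mode(frames) <- "integer"
  if (!is.null(tip_center)) {
    if (tip_center[1] < 1 || tip_center[1] > dim(frames)[2] ||
        tip_center[2] < 1 || tip_center[2] > dim(frames)[1]) {
      abort("`tip_center` must lie within the frame")
    }
  }
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(frames)[1:2])) {
      abort("`mask` must be a logical matrix matching the frame shape")
    }
  }
  structure(
    list(frames = frames, frame_rate = frame_rate, pixel_size = pixel_size,
         tip_center = if (!is.null(tip_center)) as.numeric(tip_center),
         mask = mask),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_sequence> %d x %d px, %d frames @ %g fps, %.2f um/px%s%s\n",
    d[2], d[1], d[3], x$frame_rate, x$pixel_size,
    if (!is.null(x$tip_center))
      sprintf(", tip (%g, %g)", x$tip_center[1], x$tip_center[2]) else "",
    if (!is.null(x$mask)) ", masked" else ""
  ))
  invisible(x)
}

#' @export
dim.frame_sequence <- function(x) dim(x$frames)

#' Number of frames and frame times
#'
#' @param seq A [frame_sequence()].
#' @return `n_frames()` the frame count; `frame_times()` the time of each
#'   frame in seconds (first frame at t = 0).
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' @rdname n_frames
#' @export
frame_times <- function(seq) (seq_len(n_frames(seq)) - 1) / seq$frame_rate

#' Render a track simulation into a frame sequence
#'
#' Draws each bacterium as a subtracted Gaussian blob on a uniform bright
#' background, motion-blurred over the exposure (sub-exposure positions
#' interpolated between consecutive frames; the blur is suppressed across a
#' trapping transition, whose settling jump is not physical motion), draws
#' the fiber occluder, adds Gaussian camera noise, and quantizes to 8-bit.
#' The camera-noise stream is seeded from `config$seed` so the rendered
#' video is reproducible independently of the simulation RNG.
#'
#' @param sim A `track_sim` from [simulate_tracks()], or a tracks tibble
#'   with columns `frame, id, x_um, y_um` (and optionally `trapped`).
#' @param config The [sim_config()] used to generate the tracks.
#'
#' @return A [frame_sequence()] with the geometric fiber mask attached.
#' @export
render_frames <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  tracks <- if (inherits(sim, "track_sim")) sim$tracks else sim
  req <- c("frame", "id", "x_um", "y_um")
  if (!all(req %in% names(tracks))) {
    abort("`sim` must carry columns frame, id, x_um, y_um")
  }
  if (!"trapped" %in% names(tracks)) tracks$trapped <- FALSE
  w_um <- (config$frame_width_px - 1) * config$pixel_size
  h_um <- (config$frame_height_px - 1) * config$pixel_size
  if (nrow(tracks) &&
      (min(tracks$x_um) < -config$pixel_size || max(tracks$x_um) > w_um + config$pixel_size ||
       min(tracks$y_um) < -config$pixel_size || max(tracks$y_um) > h_um + config$pixel_size)) {
    abort("track positions must lie within the frame bounds")
  }

  n_fr <- if (nrow(tracks)) max(tracks$frame) else max(2L, round(config$duration * config$frame_rate) + 1L)
  frames <- array(0L, dim = c(config$frame_height_px, config$frame_width_px, n_fr))

  rect <- fiber_rect_um(config)
  fiber_px <- as.integer(c(
    floor(rect[1] / config$pixel_size), ceiling(rect[2] / config$pixel_size),
    floor(rect[3] / config$pixel_size), ceiling(rect[4] / config$pixel_size)
  ))
  if (config$fiber_diameter <= 0) fiber_px <- c(-1L, -1L, -1L, -1L)

  by_frame <- split(seq_len(nrow(tracks)), tracks$frame)
  set.seed(config$seed + 1L)
  for (k in seq_len(n_fr)) {
    ii <- by_frame[[as.character(k)]]
    if (is.null(ii)) ii <- integer(0)
    x0 <- tracks$x_um[ii]; y0 <- tracks$y_um[ii]
    x1 <- x0; y1 <- y0
    blur <- rep(FALSE, length(ii))
    jj <- by_frame[[as.character(k + 1L)]]
    if (length(ii) && !is.null(jj) && config$exposure_fraction > 0) {
      nxt <- match(tracks$id[ii], tracks$id[jj])
      has <- !is.na(nxt)
      x1[has] <- tracks$x_um[jj][nxt[has]]
      y1[has] <- tracks$y_um[jj][nxt[has]]
      trapped_next <- rep(FALSE, length(ii))
      trapped_next[has] <- tracks$trapped[jj][nxt[has]]
      blur <- has & !tracks$trapped[ii] & !trapped_next
    }
    frames[, , k] <- render_frame_cpp(
      config$frame_width_px, config$frame_height_px,
      x0, y0, x1, y1, blur,
      config$pixel_size, config$background_level, config$bacterium_contrast,
      config$bacterium_sigma, config$n_exposure_samples,
      config$exposure_fraction, config$noise_sigma, config$contrast_flicker,
      fiber_px, fiber_level = 15
    )
  }

  seq <- frame_sequence(frames, config$frame_rate, config$pixel_size,
                        tip_center = config$tip_center)
  if (config$fiber_diameter > 0) {
    seq$mask <- fiber_mask(seq, entry_edge = config$entry_edge,
                           width_um = config$fiber_diameter,
                           tip_center = config$tip_center)
  }
  seq
}
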