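# Preprocessing: intensity rescaling to the analysis range, histogram
# matching against a reference frame, and the fiber occluder mask.

#' Rescale frame intensities to an 8-bit output range
#'
#' Applies one linear map to every frame:
#' `I' = out_low + (I - in_low) * (out_high - out_low) / (in_high - in_low)`,
#' clipped to `[0, 255]` and quantized half-away-from-zero. Using the same
#' map for all frames preserves relative brightness changes over time. The
#' default ranges rescale `0--198.9` onto `25.5--255`, maximizing bacterial
#' contrast in transmitted-light recordings.
#'
#' @param seq A [frame_sequence()] (or a numeric array/matrix).
#' @param in_range,out_range Length-2 `c(low, high)` input and output
#'   intensity ranges.
#'
#' @return The rescaled object, same class as the input.
#' @export
rescale_to_8bit <- function(seq, in_range = c(0, 198.9),
                            out_range = c(25.5, 255)) {
  if (in_range[2] <= in_range[1]) abort("`in_range` must satisfy low < high")
  if (out_range[2] < out_range[1]) abort("`out_range` must satisfy low <= high")
  map <- function(v) {
    v <- out_range[1] + (v - in_range[1]) *
      diff(out_range) / diff(in_range)
    round_half_away(pmin(pmax(v, 0), 255))
  }
  if (inherits(seq, "frame_sequence")) {
    out <- seq
    f <- map(as.numeric(seq$frames))
    out$frames <- array(as.integer(f), dim = dim(seq$frames))
    out
  } else {
    out <- map(seq)
    storage.mode(out) <- "integer"
    out
  }
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Match frame histograms to a reference frame
#'
#' Maps each frame through the monotone 8-bit transform that makes its
#' cumulative intensity histogram match that of the reference frame
#' (by default the first frame, taken before any background brightness
#' change). Masked pixels are excluded from histogram estimation but the
#' fitted monotone map is applied to every pixel.
#'
#' @param seq A [frame_sequence()].
#' @param reference Index of the reference frame (default 1).
#'
#' @return A [frame_sequence()] with matched frames.
#' @export
match_histograms <- function(seq, reference = 1L) {
  stopifnot(inherits(seq, "frame_sequence"))
  nf <- n_frames(seq)
  if (reference < 1 || reference > nf) abort("`reference` frame index out of range")
  keep <- if (!is.null(seq$mask)) !seq$mask else NULL

  grab <- function(k) {
    f <- seq$frames[, , k]
    if (is.null(keep)) as.integer(f) else as.integer(f[keep])
  }
  ref_vals <- grab(reference)
  if (length(unique(ref_vals)) < 2L) {
    abort("reference frame is constant; histogram matching is undefined")
  }
  ref_cdf <- cumsum(tabulate(ref_vals + 1L, 256L)) / length(ref_vals)

  out <- seq
  for (k in seq_len(nf)) {
    vals <- grab(k)
    cdf <- cumsum(tabulate(vals + 1L, 256L)) / length(vals)
    # monotone lookup: gray g -> smallest reference gray with CDF >= CDF(g)
    lut <- findInterval(cdf, ref_cdf, left.open = TRUE)
    lut <- pmin(lut, 255L)
    out$frames[, , k] <- matrix(
      lut[seq$frames[, , k] + 1L],
      nrow = dim(seq$frames)[1]
    )
  }
  out
}

#' Geometric fiber occluder mask
#'
#' Builds the boolean mask that removes the fiber from every downstream
#' statistic: a rectangle of width `width_um` running from the entry edge up
#' to the tip center, dilated by 2 px.
#'
#' @param seq A [frame_sequence()] (supplies frame shape and pixel size).
#' @param entry_edge Edge the fiber enters from.
#' @param width_um Fiber width in micrometres (cladding diameter).
#' @param tip_center `c(x, y)` tip position in pixels; defaults to the
#'   sequence's stored tip.
#' @param dilate_px Safety margin added around the rectangle.
#'
#' @return A logical matrix (`TRUE` = masked fiber pixels).
#' @export
fiber_mask <- function(seq, entry_edge = c("bottom", "top", "left", "right"),
                       width_um = 220, tip_center = NULL, dilate_px = 2L) {
  stopifnot(inherits(seq, "frame_sequence"))
  entry_edge <- match.arg(entry_edge)
  if (width_um <= 0) abort("`width_um` must be positive")
  if (is.null(tip_center)) tip_center <- seq$tip_center
  if (is.null(tip_center)) abort("no `tip_center` available")
  d <- dim(seq$frames)
  h <- d[1]; w <- d[2]
  if (tip_center[1] < 1 || tip_center[1] > w ||
      tip_center[2] < 1 || tip_center[2] > h) {
    abort("`tip_center` outside the frame")
  }
  half_px <- width_um / seq$pixel_size / 2
  tx <- tip_center[1]; ty <- tip_center[2]
  rect <- switch(entry_edge,  # c(col0, col1, row0, row1)
    bottom = c(tx - half_px, tx + half_px, ty, h),
    top    = c(tx - half_px, tx + half_px, 1, ty),
    left   = c(1, tx, ty - half_px, ty + half_px),
    right  = c(tx, w, ty - half_px, ty + half_px)
  )
  rect <- rect + c(-dilate_px, dilate_px, -dilate_px, dilate_px)
  cols <- seq_len(w); rows <- seq_len(h)
  mask <- outer(rows >= rect[3] & rows <= rect[4],
                cols >= rect[1] & cols <= rect[2], `&`)
  degenerate <- switch(entry_edge,
    bottom = ty >= h, top = ty <= 1, left = tx <= 1, right = tx >= w)
  if (degenerate) warn("tip_center lies on the entry edge; fiber mask is degenerate")
  mask
}

#' @rdname fiber_mask
#' @return `add_fiber_mask()` returns the sequence with the mask attached.
#' @export
add_fiber_mask <- function(seq, entry_edge = c("bottom", "top", "left", "right"),
                           width_um = 220, tip_center = NULL, dilate_px = 2L) {
  seq$mask <- fiber_mask(seq, entry_edge, width_um, tip_center, dilate_px)
  seq
}
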