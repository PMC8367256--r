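# Video I/O: multi-page 8-bit grayscale TIFF, plus JSON/CSV sidecars for
# simulated recordings.

#' Read a multi-page grayscale TIFF as a frame sequence
#'
#' @param path TIFF file.
#' @param frame_rate,pixel_size Acquisition metadata (not stored in plain
#'   TIFF).
#' @param tip_center Optional tip position `c(x, y)` in pixels.
#' @return A [frame_sequence()].
#' @export
read_video <- function(path, frame_rate, pixel_size, tip_center = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  to_gray <- function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    round_half_away(p * 255)
  }
  mats <- lapply(pages, to_gray)
  frames <- array(unlist(mats),
                  dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
  frame_sequence(frames, frame_rate, pixel_size, tip_center = tip_center)
}

#' Write a frame sequence as a multi-page 8-bit TIFF
#'
#' @param seq A [frame_sequence()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_video <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  pages <- lapply(seq_len(n_frames(seq)), function(k) seq$frames[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a simulated recording with its ground truth
#'
#' Writes the rendered video (`video.tif`), the configuration and a
#' ground-truth summary (`config.json`), and the ground-truth tracks
#' (`tracks.csv`: frame, id, x_um, y_um, trapped) into a directory.
#'
#' @param sim A `track_sim` from [simulate_tracks()].
#' @param video The matching [frame_sequence()] from [render_frames()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, video, dir) {
  stopifnot(inherits(sim, "track_sim"), inherits(video, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_video(video, file.path(dir, "video.tif"))
  write_tracks(sim$tracks, file.path(dir, "tracks.csv"))
  cfg <- sim$config
  cfg$init_r_range <- if (is.null(cfg$init_r_range)) NULL else cfg$init_r_range
  meta <- list(
    config = unclass(cfg),
    ground_truth = list(
      n_frames = max(sim$tracks$frame),
      n_trapped_final = sim$n_trapped[length(sim$n_trapped)],
      seed = cfg$seed
    )
  )
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
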