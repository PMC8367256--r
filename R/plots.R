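# ggplot2 displays for the main result types.

#' Plot concentration traces over time
#'
#' One line per ROI distance, optionally with the moving-average ribbon.
#'
#' @param data Output of [roi_concentration()] (optionally through
#'   [moving_average()]).
#' @return A ggplot.
#' @export
plot_concentration <- function(data) {
  smooth <- "C_smooth" %in% names(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = .data$t_s,
    y = if (smooth) .data$C_smooth else .data$C,
    colour = factor(.data$r_um), group = .data$r_um
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration C (a.u.)",
                  colour = "r (um)") +
    ggplot2::theme_minimal()
  if (smooth) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$C_smooth - .data$C_sd,
                   ymax = .data$C_smooth + .data$C_sd,
                   fill = factor(.data$r_um)),
      alpha = 0.2, colour = NA, show.legend = FALSE)
  }
  if ("direction" %in% names(data) && dplyr::n_distinct(data$direction) > 1) {
    p <- p + ggplot2::facet_wrap(~direction)
  }
  p
}

#' Plot a speed-versus-distance profile
#'
#' @param profile Output of [velocity_profile()].
#' @param d_bl Optional boundary-layer radius to annotate (um).
#' @return A ggplot.
#' @export
plot_velocity_profile <- function(profile, d_bl = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$r_mean_um, y = .data$v_um_s)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$v_um_s - .data$se_um_s,
      ymax = .data$v_um_s + .data$se_um_s)) +
    ggplot2::labs(x = "distance from tip (um)", y = "in-plane speed (um/s)") +
    ggplot2::theme_minimal()
  if (!is.null(d_bl)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = d_bl,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p
}

map_to_tibble <- function(m, value_name) {
  df <- expand.grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df[[value_name]] <- as.vector(m)
  tibble::as_tibble(df)
}

#' @export
autoplot.speckle_map <- function(object, ...) {
  df <- map_to_tibble(object$K, "K")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$K)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("temporal speckle contrast, window [%g, %g] s",
                                  object$t_on, object$t_on + object$t_w),
                  x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.velocity_map <- function(object, ...) {
  df <- map_to_tibble(object$v, "v")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "v (um/s)",
                  title = sprintf("in-plane velocity map, window [%g, %g] s",
                                  object$t_on, object$t_on + object$t_w),
                  x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.speckle_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$K_inv, y = .data$v_um_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = object$zero_velocity_cutoff,
                        linetype = "dotted") +
    ggplot2::labs(x = expression(K^-1), y = "in-plane speed (um/s)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.track_sim <- function(object, ...) {
  ggplot2::ggplot(object$tracks,
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               group = .data$id, colour = .data$trapped)) +
    ggplot2::geom_path(alpha = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
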