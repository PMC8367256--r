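#' Configuration for the synthetic accumulation-video generator
#'
#' Defines the imaging geometry, the in-plane convection field, the trapping
#' zone, and the rendering model for a simulated recording of bacteria
#' accumulating at a heated plasmonic fiber tip. Defaults emulate the
#' experimental recordings: 0.89 um/px, 30 frames/s, a 220 um-wide fiber
#' entering from the bottom edge, a radial inflow that is zero inside a
#' 25.7 um boundary layer and plateaus at 34.2 um/s by 200 um, a trapping
#' zone of 75 um radius, and a heating ramp with a 40 s time constant.
#'
#' @param frame_width_px,frame_height_px Frame size in pixels.
#' @param pixel_size Pixel pitch (um/px).
#' @param frame_rate Acquisition rate (frames/s).
#' @param duration Recording length (s).
#' @param tip_center Fiber-tip position `c(x, y)` in pixel coordinates
#'   (x = column, y = row, 1-based). Default: the frame center, with the
#'   fiber running in from the entry edge, so the rays from the tip toward
#'   the opposite half of the frame are unobstructed.
#' @param fiber_diameter Fiber cladding width (um); drawn as a dark occluder
#'   from the entry edge up to the tip.
#' @param entry_edge Edge the fiber enters from: `"bottom"`, `"top"`,
#'   `"left"` or `"right"`.
#' @param n_bacteria Number of free-swimming bacteria in the frame. Default:
#'   effective areal density 0.04 cells/um^2 times the frame area
#'   (transmitted light integrates scatterers through the chamber depth, so
#'   the effective 2D density is well above that of a single focal slice).
#' @param v_max Plateau in-plane convection speed (um/s).
#' @param d_bl Boundary-layer radius (um); in-plane flow is zero inside.
#' @param r_plateau Distance (um) at which the field reaches `v_max`.
#' @param r_trap Trapping/accumulation-zone radius (um).
#' @param trap_rate Capture rate (1/s) experienced by a free bacterium while
#'   inside the trapping zone: the near-field attraction is a finite force,
#'   so bacteria linger (drifting slowly and diffusing) for about
#'   `1/trap_rate` seconds before settling into the swarm.
#' @param recirculation Scale factor (default 1; 0 disables) on the
#'   out-of-plane recirculation rate. The in-plane field decelerates toward
#'   the tip because the toroidal convection turns vertical; the in-plane
#'   flux it loses, `lambda(r) = v/r + dv/dr`, lifts bacteria out of the
#'   imaging plane at exactly the rate that keeps the free density uniform,
#'   and each lifted bacterium re-enters at the frame border (the return
#'   limb feeds the far-field inflow). Without it, planar advection piles
#'   bacteria into an unphysical traffic jam where the field decelerates.
#' @param bath_exchange Rate (1/s) at which a free bacterium swaps with the
#'   3D reservoir above/below the imaging plane (it leaves the plane and an
#'   unrelated one enters at a uniform position). The imaged slice of a
#'   deep, well-mixed chamber constantly exchanges bacteria through the
#'   depth; this keeps the free density near-uniform against the advective
#'   distortions of a purely planar model.
#' @param D_brownian Translational diffusivity (um^2/s).
#' @param ramp Logical; apply the heating ramp `1 - exp(-t/ramp_tau)`.
#' @param ramp_tau Heating-ramp time constant (s).
#' @param trap_capacity Maximum number of trapped bacteria; accumulation
#'   saturates once reached.
#' @param trap_jitter Residual positional jitter of trapped bacteria (um,
#'   bounded: uniform in a disk of this radius around the settling point).
#'   Must stay below half a pixel so trapped cells move by less than 1 px
#'   between frames.
#' @param replenish Logical; when a bacterium is trapped, a replacement
#'   enters uniformly over the free region, emulating the open 3D reservoir
#'   that resupplies the imaging plane through the depth.
#' @param init_r_range Optional `c(min, max)` distance range (um) from the
#'   tip for initial placement; `NULL` places bacteria uniformly over the
#'   frame.
#' @param background_level Background gray level (8-bit).
#' @param bacterium_contrast Gray-level depression at a bacterium center.
#' @param bacterium_sigma Gaussian blob scale of a rendered bacterium (um).
#' @param noise_sigma Additive Gaussian camera noise (gray levels).
#' @param contrast_flicker Relative orientation flicker of the rendered
#'   contrast (0 to < 1): a rod-shaped bacterium tumbles between frames, so
#'   its projected optical depth varies; each bacterium's blob amplitude is
#'   scaled by an independent uniform factor in
#'   `1 +/- contrast_flicker` per frame. This is what makes a dense but
#'   settled swarm flicker in time, as live swarms do.
#' @param exposure_fraction Fraction of the inter-frame interval the shutter
#'   integrates over; moving bacteria are rendered as motion-blurred streaks.
#' @param n_exposure_samples Sub-exposure samples used to integrate the blur.
#' @param n_substeps Euler-Maruyama substeps per frame interval.
#' @param seed Integer seed; identical seed and config give identical output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(frame_width_px = 160, frame_height_px = 120,
#'                   duration = 2, n_bacteria = 50, seed = 7)
#' velocity_field(c(10, 100, 300), t = 10, config = cfg)
#' @export
sim_config <- function(frame_width_px = 640,
                       frame_height_px = 480,
                       pixel_size = 0.89,
                       frame_rate = 30,
                       duration = 60,
                       tip_center = NULL,
                       fiber_diameter = 220,
                       entry_edge = c("bottom", "top", "left", "right"),
                       n_bacteria = NULL,
                       v_max = 34.2,
                       d_bl = 25.7,
                       r_plateau = 200,
                       r_trap = 75,
                       trap_rate = 0.4,
                       recirculation = 1,
                       bath_exchange = 0.3,
                       D_brownian = 0.3,
                       ramp = TRUE,
                       ramp_tau = 40,
                       trap_capacity = 6000,
                       trap_jitter = 0.4,
                       replenish = TRUE,
                       init_r_range = NULL,
                       background_level = 230,
                       bacterium_contrast = 60,
                       bacterium_sigma = 0.8,
                       noise_sigma = 3,
                       contrast_flicker = 0.8,
                       exposure_fraction = 1,
                       n_exposure_samples = 4,
                       n_substeps = 10,
                       seed = 1L) {
  entry_edge <- match.arg(entry_edge)
  if (is.null(tip_center)) {
    tip_center <- c(frame_width_px / 2, frame_height_px / 2)
  }
  if (is.null(n_bacteria)) {
    n_bacteria <- round(0.04 * frame_width_px * frame_height_px * pixel_size^2)
  }

  cfg <- list(
    frame_width_px = as.integer(frame_width_px),
    frame_height_px = as.integer(frame_height_px),
    pixel_size = pixel_size, frame_rate = frame_rate, duration = duration,
    tip_center = as.numeric(tip_center), fiber_diameter = fiber_diameter,
    entry_edge = entry_edge, n_bacteria = as.integer(n_bacteria),
    v_max = v_max, d_bl = d_bl, r_plateau = r_plateau, r_trap = r_trap,
    trap_rate = trap_rate, recirculation = recirculation,
    bath_exchange = bath_exchange,
    D_brownian = D_brownian, ramp = isTRUE(ramp), ramp_tau = ramp_tau,
    trap_capacity = trap_capacity, trap_jitter = trap_jitter,
    replenish = isTRUE(replenish), init_r_range = init_r_range,
    background_level = background_level,
    bacterium_contrast = bacterium_contrast,
    bacterium_sigma = bacterium_sigma, noise_sigma = noise_sigma,
    contrast_flicker = contrast_flicker,
    exposure_fraction = exposure_fraction,
    n_exposure_samples = as.integer(n_exposure_samples),
    n_substeps = as.integer(n_substeps), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (frame_width_px < 1 || frame_height_px < 1) {
      abort("frame dimensions must be positive")
    }
    if (pixel_size <= 0) abort("`pixel_size` must be positive")
    if (frame_rate <= 0) abort("`frame_rate` must be positive")
    if (duration <= 0) abort("`duration` must be positive")
    if (!(d_bl > 0 && d_bl < r_plateau)) {
      abort("need 0 < d_bl < r_plateau")
    }
    if (r_trap <= 0) abort("`r_trap` must be positive")
    if (trap_rate < 0) abort("`trap_rate` must be non-negative")
    if (recirculation < 0) abort("`recirculation` must be non-negative")
    if (bath_exchange < 0) abort("`bath_exchange` must be non-negative")
    if (v_max < 0) abort("`v_max` must be non-negative")
    if (D_brownian < 0) abort("`D_brownian` must be non-negative")
    if (ramp && ramp_tau <= 0) abort("`ramp_tau` must be positive")
    if (background_level - bacterium_contrast < 0) {
      abort("`background_level - bacterium_contrast` must stay within 8-bit range")
    }
    if (contrast_flicker < 0 || contrast_flicker >= 1) {
      abort("`contrast_flicker` must be in [0, 1)")
    }
    if (background_level > 255 || background_level < 0) {
      abort("`background_level` must be an 8-bit gray level")
    }
    if (tip_center[1] < 1 || tip_center[1] > frame_width_px ||
        tip_center[2] < 1 || tip_center[2] > frame_height_px) {
      abort("`tip_center` must lie within the frame")
    }
    if (trap_jitter < 0 || 2 * trap_jitter >= pixel_size) {
      abort("`trap_jitter` must satisfy 0 <= 2*trap_jitter < pixel_size (trapped cells move < 1 px/frame)")
    }
    if (n_substeps < 1 || n_exposure_samples < 1) {
      abort("`n_substeps` and `n_exposure_samples` must be >= 1")
    }
    if (!is.null(init_r_range) &&
        (length(init_r_range) != 2 || init_r_range[1] < 0 ||
         init_r_range[2] <= init_r_range[1])) {
      abort("`init_r_range` must be c(min, max) with 0 <= min < max")
    }
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d x %d px (%.2f um/px), %g fps, %g s, %d bacteria\n",
    x$frame_width_px, x$frame_height_px, x$pixel_size, x$frame_rate,
    x$duration, x$n_bacteria
  ))
  cat(sprintf(
    "  field: v_max %g um/s, d_bl %g um, plateau at %g um, trap %g um%s\n",
    x$v_max, x$d_bl, x$r_plateau, x$r_trap,
    if (x$ramp) sprintf(", ramp tau %g s", x$ramp_tau) else ", ramp off"
  ))
  invisible(x)
}

#' In-plane radial convection speed toward the tip
#'
#' The field is zero inside the boundary layer (`r < d_bl`), rises as a cubic
#' smoothstep between `d_bl` and `r_plateau`, and equals `v_max` beyond.
#' A heating ramp `1 - exp(-t/ramp_tau)` scales the whole field in time
#' (identically 1 when the ramp is disabled).
#'
#' @param r Distance(s) from the tip center (um); must be non-negative.
#' @param t Time(s) since laser-on (s).
#' @param config A [sim_config()].
#'
#' @return Speed(s) in um/s, directed toward the tip.
#' @export
velocity_field <- function(r, t, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(r < 0)) abort("`r` must be non-negative")
  if (any(t < 0)) abort("`t` must be non-negative")
  s <- (r - config$d_bl) / (config$r_plateau - config$d_bl)
  s <- pmin(pmax(s, 0), 1)
  shape <- s * s * (3 - 2 * s)
  ramp <- if (config$ramp) 1 - exp(-t / config$ramp_tau) else rep(1, length(t))
  config$v_max * shape * ramp
}

# local out-of-plane divergence rate of the in-plane field:
# lambda(r) = v/r + dv/dr (1/s), the rate at which converging planar flow
# sheds volume vertically; keeps advected tracer density uniform
field_divergence_rate <- function(r, t, config) {
  v <- velocity_field(r, t, config)
  s <- (r - config$d_bl) / (config$r_plateau - config$d_bl)
  inside <- s > 0 & s < 1
  s <- pmin(pmax(s, 0), 1)
  ramp <- if (config$ramp) 1 - exp(-t / config$ramp_tau) else 1
  dv <- ifelse(inside,
               config$v_max * ramp * 6 * s * (1 - s) /
                 (config$r_plateau - config$d_bl),
               0)
  ifelse(r > 0, v / r, 0) + dv
}
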