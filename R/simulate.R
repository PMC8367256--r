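# Brownian-dynamics generator for bacterial accumulation at a heated fiber
# tip. Free bacteria follow an Euler-Maruyama update (radial drift from the
# convection field plus isotropic diffusion); bacteria reaching the trapping
# zone settle into the swarm and are frozen up to bounded sub-pixel jitter.

#' Simulate ground-truth bacterial tracks
#'
#' Integrates the motion of `n_bacteria` point bacteria under the in-plane
#' convection field of `config` (drift toward the tip, zero inside the
#' boundary layer), isotropic Brownian diffusion, reflective frame borders,
#' and trapping: a free bacterium inside the accumulation zone
#' (`r < r_trap`) is captured at rate `trap_rate`, so it lingers there --
#' drifting slowly and diffusing -- for about `1/trap_rate` seconds before
#' settling at a position drawn from the swarm density (a 2D Gaussian with
#' sigma = r_trap / sqrt(2 ln 2), truncated at 2 r_trap, so the matured
#' swarm profile has FWHM = 2 r_trap). Settled bacteria only jitter within
#' `trap_jitter`. Where the in-plane field decelerates, free bacteria are
#' lifted out of the plane at the local flow-divergence rate (the toroidal
#' current turns vertical; see `recirculation` in [sim_config()]) and
#' re-enter under a fresh track id, uniformly over the free region -- the
#' return limb and the 3D reservoir resupply through the depth, not through
#' the frame edges. With `replenish = TRUE` every capture admits a
#' replacement the same way. Once `trap_capacity` is reached the swarm is in
#' equilibrium: arrivals are still captured but are balanced by release, so
#' the accumulation saturates.
#'
#' @param config A [sim_config()].
#'
#' @return An object of class `track_sim`: a list with
#'   * `tracks`: tibble `(frame, id, x_um, y_um, trapped)` -- frame is
#'     1-based (time of frame k is `(k - 1) / frame_rate` seconds),
#'     positions are lab-frame micrometres with the origin at the center of
#'     pixel (1, 1);
#'   * `config`: the configuration;
#'   * `field`: the exact field function `f(r, t)` used;
#'   * `n_trapped`: trapped count per frame.
#' @examples
#' cfg <- sim_config(frame_width_px = 120, frame_height_px = 120,
#'                   duration = 1, n_bacteria = 20, seed = 3)
#' sim <- simulate_tracks(cfg)
#' head(sim$tracks)
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dt <- 1 / cfg$frame_rate
  dts <- dt / cfg$n_substeps
  if (dts * cfg$v_max > cfg$d_bl) {
    abort(paste0(
      "drift per substep (", signif(dts * cfg$v_max, 3), " um) exceeds the ",
      "boundary layer (", cfg$d_bl, " um); increase `n_substeps` or `frame_rate`"
    ))
  }
  set.seed(cfg$seed)

  w_um <- (cfg$frame_width_px - 1) * cfg$pixel_size
  h_um <- (cfg$frame_height_px - 1) * cfg$pixel_size
  tip <- (cfg$tip_center - 1) * cfg$pixel_size
  rect <- fiber_rect_um(cfg)
  n_frames <- max(2L, round(cfg$duration * cfg$frame_rate) + 1L)
  sigma_settle <- cfg$r_trap / sqrt(2 * log(2))
  diff_sd <- sqrt(2 * cfg$D_brownian * dts)

  in_rect <- function(px, py) {
    px >= rect[1] & px <= rect[2] & py >= rect[3] & py <= rect[4]
  }

  ## initial placement (outside the fiber occluder)
  draw_init <- function(n) {
    out_x <- out_y <- numeric(0)
    tries <- 0L
    while (length(out_x) < n) {
      m <- 4L * (n - length(out_x)) + 16L
      if (is.null(cfg$init_r_range)) {
        px <- runif(m, 0, w_um); py <- runif(m, 0, h_um)
      } else {
        rr <- sqrt(runif(m, cfg$init_r_range[1]^2, cfg$init_r_range[2]^2))
        th <- runif(m, 0, 2 * pi)
        px <- tip[1] + rr * cos(th); py <- tip[2] + rr * sin(th)
      }
      keep <- px >= 0 & px <= w_um & py >= 0 & py <= h_um & !in_rect(px, py)
      out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
      tries <- tries + 1L
      if (tries > 1000L) abort("cannot place bacteria: placement region is empty")
    }
    cbind(out_x[seq_len(n)], out_y[seq_len(n)])
  }

  draw_settle <- function(n) {
    out <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(out) < n) {
      m <- 4L * (n - nrow(out)) + 16L
      rr <- sigma_settle * sqrt(-2 * log(runif(m)))   # Rayleigh radius
      th <- runif(m, 0, 2 * pi)
      px <- tip[1] + rr * cos(th); py <- tip[2] + rr * sin(th)
      keep <- rr <= 2 * cfg$r_trap & px >= 0 & px <= w_um &
        py >= 0 & py <= h_um & !in_rect(px, py)
      out <- rbind(out, cbind(px[keep], py[keep]))
      tries <- tries + 1L
      if (tries > 1000L) abort("cannot settle trapped bacteria inside the frame")
    }
    out[seq_len(n), , drop = FALSE]
  }

  # uniform re-entry from the 3D reservoir, anywhere outside the fiber --
  # bacteria descending over the trapping zone are subsequently captured
  # like any other zone resident
  draw_reentry <- function(n) {
    out <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(out) < n) {
      m <- 2L * (n - nrow(out)) + 8L
      px <- runif(m, 0, w_um); py <- runif(m, 0, h_um)
      keep <- !in_rect(px, py)
      out <- rbind(out, cbind(px[keep], py[keep]))
      tries <- tries + 1L
      if (tries > 1000L) abort("cannot re-enter bacteria: free region is empty")
    }
    out[seq_len(n), , drop = FALSE]
  }

  # border re-entry: recirculated flow feeds the far-field inflow
  draw_border <- function(n) {
    out <- matrix(NA_real_, 0, 2)
    per <- 2 * (w_um + h_um)
    while (nrow(out) < n) {
      m <- 2L * (n - nrow(out)) + 8L
      s <- runif(m, 0, per)
      px <- ifelse(s < w_um, s,
            ifelse(s < w_um + h_um, w_um,
            ifelse(s < 2 * w_um + h_um, s - w_um - h_um, 0)))
      py <- ifelse(s < w_um, 0,
            ifelse(s < w_um + h_um, s - w_um,
            ifelse(s < 2 * w_um + h_um, h_um, s - 2 * w_um - h_um)))
      keep <- !in_rect(px, py)
      out <- rbind(out, cbind(px[keep], py[keep]))
    }
    out[seq_len(n), , drop = FALSE]
  }

  pos <- draw_init(cfg$n_bacteria)
  x <- pos[, 1]; y <- pos[, 2]
  id <- seq_len(cfg$n_bacteria)
  next_id <- cfg$n_bacteria + 1L
  trapped <- rep(FALSE, cfg$n_bacteria)
  settle_x <- settle_y <- rep(NA_real_, cfg$n_bacteria)
  n_trapped <- 0L

  trap_now <- function(idx) {
    k <- length(idx)
    if (k == 0L) return(invisible())
    room <- max(0L, floor(cfg$trap_capacity) - n_trapped)
    if (k > room) {
      # matured swarm at equilibrium: arrivals are captured and balanced by
      # release -- net exchange with the reservoir, no net accumulation
      overflow <- idx[-seq_len(room)]
      nb <- draw_reentry(length(overflow))
      x[overflow] <<- nb[, 1]; y[overflow] <<- nb[, 2]
      id[overflow] <<- seq.int(next_id, length.out = length(overflow))
      next_id <<- next_id + length(overflow)
      idx <- idx[seq_len(room)]
    }
    k <- length(idx)
    if (k == 0L) return(invisible())
    trapped[idx] <<- TRUE
    st <- draw_settle(k)
    settle_x[idx] <<- st[, 1]; settle_y[idx] <<- st[, 2]
    x[idx] <<- st[, 1]; y[idx] <<- st[, 2]
    n_trapped <<- n_trapped + k
    if (cfg$replenish) {
      nb <- draw_reentry(k)
      x <<- c(x, nb[, 1]); y <<- c(y, nb[, 2])
      trapped <<- c(trapped, rep(FALSE, k))
      settle_x <<- c(settle_x, rep(NA_real_, k))
      settle_y <<- c(settle_y, rep(NA_real_, k))
      id <<- c(id, seq.int(next_id, length.out = k))
      next_id <<- next_id + k
    }
    invisible()
  }

  cap <- n_frames * (cfg$n_bacteria + min(cfg$trap_capacity, 1e7) *
                       as.integer(cfg$replenish) + 8L)
  rec_frame <- integer(cap); rec_id <- integer(cap)
  rec_x <- numeric(cap); rec_y <- numeric(cap); rec_tr <- logical(cap)
  ptr <- 0L
  n_trapped_frame <- integer(n_frames)

  record <- function(k) {
    n_cur <- length(x)
    ii <- ptr + seq_len(n_cur)
    jx <- x; jy <- y
    ti <- which(trapped)
    if (length(ti) && cfg$trap_jitter > 0) {
      jr <- cfg$trap_jitter * sqrt(runif(length(ti)))
      ja <- runif(length(ti), 0, 2 * pi)
      jx[ti] <- settle_x[ti] + jr * cos(ja)
      jy[ti] <- settle_y[ti] + jr * sin(ja)
    }
    rec_frame[ii] <<- k; rec_id[ii] <<- id
    rec_x[ii] <<- jx; rec_y[ii] <<- jy; rec_tr[ii] <<- trapped
    ptr <<- ptr + n_cur
    n_trapped_frame[k] <<- n_trapped
  }

  reflect <- function(p, lo, hi) {
    bad <- p < lo | p > hi
    while (any(bad)) {
      p[p < lo] <- 2 * lo - p[p < lo]
      p[p > hi] <- 2 * hi - p[p > hi]
      bad <- p < lo | p > hi
    }
    p
  }

  for (k in seq_len(n_frames)) {
    record(k)
    if (k == n_frames) break
    for (s in seq_len(cfg$n_substeps)) {
      t_cur <- (k - 1) * dt + (s - 1) * dts
      free <- which(!trapped)
      if (length(free) == 0L) next
      dx <- x[free] - tip[1]; dy <- y[free] - tip[2]
      r <- sqrt(dx^2 + dy^2)
      v <- velocity_field(r, t_cur, cfg)
      fac <- ifelse(r > 0, -v * dts / r, 0)
      nx <- x[free] + fac * dx
      ny <- y[free] + fac * dy
      if (cfg$D_brownian > 0) {
        nx <- nx + rnorm(length(free), 0, diff_sd)
        ny <- ny + rnorm(length(free), 0, diff_sd)
      }
      x[free] <- reflect(nx, 0, w_um)
      y[free] <- reflect(ny, 0, h_um)
      rn <- sqrt((x[free] - tip[1])^2 + (y[free] - tip[2])^2)
      if (cfg$trap_rate > 0) {
        # the capturing near-field force grows with the heating ramp
        ramp_fac <- if (cfg$ramp) 1 - exp(-t_cur / cfg$ramp_tau) else 1
        inside <- free[rn < cfg$r_trap]
        caught <- inside[runif(length(inside)) < cfg$trap_rate * ramp_fac * dts]
        trap_now(caught)
      }
      if (cfg$recirculation > 0 || cfg$bath_exchange > 0) {
        # (i) where the planar field decelerates the toroidal cell turns
        # vertical: lift at the local divergence rate, re-enter at the
        # border (the return limb feeds the far-field inflow);
        # (ii) uniform exchange with the 3D bath keeps the slice mixed
        # only outside the trapping zone: inside it the thermophoretic
        # near-field retains bacteria against the vertical flow
        keep_free <- !trapped[free] & rn >= cfg$r_trap
        still_free <- free[keep_free]
        lam <- cfg$recirculation * field_divergence_rate(rn[keep_free], t_cur, cfg)
        u <- runif(length(still_free)) / dts
        lifted <- still_free[u < lam]
        swapped <- still_free[u >= lam & u < lam + cfg$bath_exchange]
        n_lift <- length(lifted)
        if (n_lift > 0L) {
          nb <- draw_border(n_lift)
          x[lifted] <- nb[, 1]; y[lifted] <- nb[, 2]
          id[lifted] <- seq.int(next_id, length.out = n_lift)
          next_id <- next_id + n_lift
        }
        n_swap <- length(swapped)
        if (n_swap > 0L) {
          nb <- draw_reentry(n_swap)
          x[swapped] <- nb[, 1]; y[swapped] <- nb[, 2]
          id[swapped] <- seq.int(next_id, length.out = n_swap)
          next_id <- next_id + n_swap
        }
      }
    }
  }

  length(rec_frame) <- ptr; length(rec_id) <- ptr
  length(rec_x) <- ptr; length(rec_y) <- ptr; length(rec_tr) <- ptr
  tracks <- tibble::new_tibble(
    list(frame = rec_frame, id = rec_id,
         x_um = rec_x, y_um = rec_y, trapped = rec_tr),
    nrow = ptr
  )
  structure(
    list(
      tracks = tracks, config = cfg,
      field = function(r, t) velocity_field(r, t, cfg),
      n_trapped = n_trapped_frame
    ),
    class = "track_sim"
  )
}

#' @export
print.track_sim <- function(x, ...) {
  nf <- max(x$tracks$frame)
  cat(sprintf(
    "<track_sim> %d bacteria ids over %d frames; %d trapped at end (seed %d)\n",
    dplyr::n_distinct(x$tracks$id), nf, x$n_trapped[nf], x$config$seed
  ))
  invisible(x)
}

# fiber occluder rectangle in lab micrometres: c(x0, x1, y0, y1)
fiber_rect_um <- function(cfg) {
  tip <- (cfg$tip_center - 1) * cfg$pixel_size
  w_um <- (cfg$frame_width_px - 1) * cfg$pixel_size
  h_um <- (cfg$frame_height_px - 1) * cfg$pixel_size
  half <- cfg$fiber_diameter / 2
  switch(cfg$entry_edge,
    bottom = c(tip[1] - half, tip[1] + half, tip[2], h_um),
    top    = c(tip[1] - half, tip[1] + half, 0, tip[2]),
    left   = c(0, tip[1], tip[2] - half, tip[2] + half),
    right  = c(tip[1], w_um, tip[2] - half, tip[2] + half)
  )
}

#' Simulate a full synthetic accumulation video
#'
#' Convenience wrapper: [simulate_tracks()] followed by [render_frames()].
#'
#' @inheritParams simulate_tracks
#' @return A list with elements `video` (a [frame_sequence()]) and `sim`
#'   (the `track_sim` ground truth).
#' @export
simulate_video <- function(config) {
  sim <- simulate_tracks(config)
  list(video = render_frames(sim, config), sim = sim)
}
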