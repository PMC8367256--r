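# Shared fixtures, built in code. Expensive synthetic videos are generated
# once per test run and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# uniform-gray sequence
flat_seq <- function(value, h = 20, w = 20, f = 5, frame_rate = 30,
                     pixel_size = 1, tip_center = NULL) {
  frame_sequence(array(as.integer(value), dim = c(h, w, f)),
                 frame_rate = frame_rate, pixel_size = pixel_size,
                 tip_center = tip_center)
}

# mid-sized radially-symmetric accumulation video shared by the speckle and
# concentration integration tests (one simulation per run)
shared_video <- function() {
  memo("shared_video", {
    cfg <- sim_config(
      frame_width_px = 200, frame_height_px = 200,
      tip_center = c(100, 190), fiber_diameter = 30,
      duration = 45, ramp = FALSE, seed = 42
    )
    sv <- simulate_video(cfg)
    sv$cfg <- cfg
    sv
  })
}

# drift-only configuration: no diffusion, no ramp, no trapping, no vertical
# recirculation or bath exchange, no noise -- pure in-plane advection
drift_config <- function(..., seed = 7) {
  sim_config(
    frame_width_px = 640, frame_height_px = 480, duration = 1,
    D_brownian = 0, ramp = FALSE, trap_rate = 0, recirculation = 0,
    bath_exchange = 0, noise_sigma = 0, seed = seed, ...
  )
}
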