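# plasmotrap

Quantitative video analysis of **plasmo-thermal bacterial trapping**: the
accumulation of swimming bacteria at the tip of a plasmonic optical fiber
whose localized heating drives a toroidal convection current (far-field
pull) and a thermophoretic near-field force (trapping). The package is
aimed at researchers analyzing transmitted-light microscopy recordings of
micro-scale thermal manipulation, and at anyone who wants a reproducible,
ground-truthed testbed for the three measurement techniques the analysis
combines:

- **Concentration kinetics** — an arbitrary concentration `C = 255 − ⟨I⟩`
  per 10 × 10 µm² ROI along rays from the tip; accumulation kinetics are
  fit with `C(t) = C_sat + a·exp(−t/τ)` and the spatial profile with a
  Gaussian pinned at the tip, `C(r) = baseline + height·exp(−r²/2σ²)`,
  whose FWHM = 2√(2 ln 2)·σ measures the matured swarm size.
- **Frame-by-frame track velocimetry** — per-bacterium radial distance
  series `r(t)`, linear fits over a 1 s window give in-plane speeds, the
  speed-versus-distance profile, and the boundary-layer radius where the
  in-plane flow vanishes.
- **Temporal laser-speckle-contrast velocimetry** — the per-pixel temporal
  contrast `K = σ_I/⟨I⟩` over a time window `t_w`; since speed is
  proportional to the inverse decorrelation time, `v ∝ 1/τ_c ∝ 1/K`, a
  linear calibration of `K⁻¹` against the tracked speeds converts contrast
  images into wide-area velocity maps, with a zero-velocity cutoff where
  the regression crosses `v = 0`.
- **Transport physics** — the supporting dimensionless numbers and forces:
  Rayleigh number `Ra = ρβl³gΔT/(µα)` and the critical ΔT for classical
  convection, Stokes number `St = ρ_p d_p² u/(18 µ_f L)`, Reynolds number,
  Stokes drag `F = −3πµ d_p v`, terminal trapping speed `|v| = √(2 a d_bl)`,
  Soret coefficient `S_T = D_T/D`, and the gravity–buoyancy balance.

Because raw recordings of such experiments are rarely public, the package
includes a first-class **synthetic video generator**
(`sim_config()`, `simulate_tracks()`, `render_frames()`): a seeded
Brownian-dynamics simulation of bacteria in the convection field (zero
inside a 25.7 µm boundary layer, plateau 34.2 µm/s by 200 µm, trapping
zone of 75 µm radius, 40 s heating ramp) rendered into 8-bit
transmitted-light frames with known ground truth. Every stage of the
pipeline is validated end-to-end against that ground truth.

## Worked example

```r
library(plasmotrap)
library(dplyr)

# a small synthetic accumulation recording with known ground truth
cfg <- sim_config(frame_width_px = 320, frame_height_px = 240,
                  duration = 60, ramp = FALSE, tip_center = c(160, 230),
                  seed = 1)
sv  <- simulate_video(cfg)

# tracking stage: in-plane speed vs distance from ground-truth tracks
free <- filter(sv$sim$tracks, !trapped)
prof <- velocity_profile(free, cfg$tip_center, cfg$pixel_size, cfg$frame_rate)
mean(prof$v_um_s[prof$r_mean_um > 200 & prof$n >= 10])
#> [1] 34.18411

# concentration stage: matured swarm width
roi <- roi_concentration(sv$video,
                         directions = c("left-diagonal", "vertical", "right-diagonal"))
avg <- roi |>
  group_by(r_um, frame, t_s) |>
  summarise(C = mean(C), .groups = "drop") |>
  moving_average()
matured_fwhm(fit_gaussian_maturation(avg))$fwhm_um
#> [1] 138.6795

# speckle stage: contrast map, calibration against the tracked speeds,
# and a wide-area velocity map
sm  <- temporal_speckle_contrast(sv$video, t_w = 15, t_on = 30, smooth_px = 9)
avgK <- average_contrast_profile(
  radial_contrast_profiles(sm, r_range = c(5, 195), entry_edge = "bottom"))
cal <- calibrate_velocity(avgK, prof)
cal
#> <speckle_calibration> v = 2.34 * K^-1 + -3.82 um/s (R^2 = 0.976, n = 20)
#>   zero-velocity cutoff: K^-1 = 1.632
vmap <- velocity_map(sm, cal)
```

The plateau of the tracked profile recovers the simulator's 34.2 µm/s
within 0.1%; the matured Gaussian FWHM recovers twice the 75 µm trapping
radius within 8%; and the calibrated velocity map agrees with the
ground-truth field to an RMS error of about 9% of the plateau speed over
the calibrated range. `autoplot()` methods display contrast maps, velocity
maps and calibrations; `tidy()`/`glance()` return fit tables.

The physics calculators ship the water / *E. coli* constants as defaults:

```r
critical_delta_T(fluid_params(), l = 1.25e-4)   # ~70,700 K: classical
#> [1] 70699.81                                  # convection is impossible
N_to_fN(abs(stokes_drag(1e-3, 1.075e-6, 9.91e-6)))
#> [1] 100.4045                                  # the ~100 fN trapping force
```

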