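---
title: "Models and methods behind plasmotrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plasmotrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plasmotrap analyzes transmitted-light recordings of bacteria accumulating
at a heated plasmonic fiber tip, and ships a ground-truthed synthetic-video
generator used to validate every analysis stage. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not demonstrate about real data.

## The physical picture

Localized plasmonic heating at the fiber tip drives a toroidal convection
cell: fluid flows radially inward along the imaging plane, turns vertical
near the tip, and returns through the bulk. Suspended bacteria are
near-perfect tracers of this flow (Stokes number ~1e-8, Reynolds number
~7.5e-3; see `stokes_number()`, `reynolds_number()`). The in-plane speed
therefore rises with distance up to a plateau (34.2 µm/s around 200 µm by
default) and vanishes inside a boundary layer (25.7 µm) where the current
turns vertical. Near the tip, a thermophoretic near-field force captures
bacteria into a growing swarm; the accumulation zone has a 75 µm radius
and the matured swarm's concentration profile is Gaussian-like with
FWHM ≈ 2 × 75 µm. Classical Rayleigh–Bénard convection would require a
temperature difference of order 7×10⁴ K at this length scale
(`critical_delta_T()`), so the convection must come from the localized
heating profile, not bulk instability — the package's transport module
makes that argument quantitative.

## The synthetic-video generator

`sim_config()` holds the study conditions; the defaults emulate the
recordings the analyses were designed for: 640×480 px at 0.89 µm/px,
30 frames/s, 60 s, a 220 µm fiber entering from the bottom edge to the
frame center, and the field above. Key model components, each a deliberate
design choice:

* **Field shape.** Between the boundary layer `d_bl` and the plateau
  radius `r_plateau` the speed follows a cubic smoothstep (C¹,
  `velocity_field()`); only the endpoints are constrained by measurement,
  and the smoothstep is documented and swappable. A heating ramp
  `1 − exp(−t/40 s)` scales the field and the capture rate: plasmonic
  structures submerged in fluid heat up with a time constant of tens of
  seconds.

* **Motion.** Euler–Maruyama with 10 substeps per frame: radial drift plus
  isotropic diffusion (default D = 0.3 µm²/s, the order of magnitude for a
  ~1 µm particle in water; no measured diffusivity exists for these
  conditions). The integrator refuses configurations whose drift per
  substep exceeds the boundary layer.

* **Trapping.** A free bacterium inside the 75 µm zone is captured at a
  finite rate (0.4 /s at full heating) — the near-field attraction is a
  force, not an absorbing wall — and settles at a position drawn from a 2D
  Gaussian with σ = r_trap/√(2 ln 2) truncated at 2 r_trap, so the matured
  swarm has the Gaussian areal density with FWHM = 2 r_trap that matured
  accumulations show. Settled bacteria jitter within a bounded 0.4 µm
  radius (< 1 px/frame). Captures stop at `trap_capacity`; beyond it
  arrivals are balanced by release (equilibrium exchange), which is what
  ends net accumulation in a real matured swarm.

* **The third dimension.** A purely planar advection model is wrong in two
  ways: converging inward flow would pile tracers into an unphysical
  "traffic jam" where the field decelerates, and a thin imaging slice of a
  deep chamber constantly exchanges bacteria with the bulk. The generator
  represents the vertical physics with two exchange channels:
  out-of-plane lifting at the local divergence rate λ(r) = v/r + dv/dr
  (exactly the in-plane flux the toroidal cell sheds vertically; lifted
  bacteria re-enter at the border, the return limb feeding the far-field
  inflow), and a uniform bath exchange (0.3 /s) with re-entry anywhere in
  the frame. Bath re-entries descending over the trapping zone are
  captured like any zone resident; this depth-resupply is what gives the
  swarm a realistic mass within one minute — the 2D advective flux alone
  is an order of magnitude too small.

* **Rendering.** Bacteria are subtracted Gaussian blobs (amplitude 60 gray
  on a 230 background, scale 0.8 µm) with three imaging effects that
  matter for speckle analysis: finite-exposure motion blur (sub-exposure
  positions averaged across the frame interval), per-frame orientation
  flicker (a tumbling rod's projected optical depth varies; amplitude
  scaled by U(1±0.8) per frame — without it a settled swarm is temporally
  static and its contrast is camera-noise-limited), and additive Gaussian
  camera noise (σ = 3 gray) with 8-bit quantization. The effective areal
  density (0.04 /µm²) reflects that transmitted light integrates
  scatterers through the chamber depth.

What the generator does **not** model: hydrodynamic interactions, bacterial
motility (swimming), diffraction or defocus, the vertical coordinate
explicitly, or heat transfer. Passing the end-to-end tests therefore shows
that the analysis stages correctly invert the model's imaging physics at
realistic noise levels; it does not certify performance on every real
recording — in particular, real speckle statistics depend on optics the
blob renderer only caricatures.

## Concentration kinetics

`roi_concentration()` places twenty contiguous 10×10 µm² ROIs along each of
five rays (centers at r = 5, 15, …, 195 µm) and reports
`C = 255 − ⟨I⟩` over unmasked pixels per frame. Choices: diagonal-ray ROIs
are axis-aligned squares centered on the 45° ray; ROIs that leave the
frame or are fully masked are dropped with a message. `moving_average()`
smooths with an 11-point centered window (truncated at the ends) and
reports the within-window standard deviation.

`fit_exponential_decay()` fits `C(t) = C_sat + a·exp(−t/τ)` by
Levenberg–Marquardt, initialized from the tail mean, the initial offset
and the 1/e crossing; near-constant input (amplitude within the noise
floor estimated from first differences) is flagged, never silently
numbered. `fit_gaussian_profile()` pins the peak at r = 0 and constrains
baseline and height to the physical 8-bit range, which keeps fits on
half-formed profiles from wandering into negative baselines.
R² is 1 − SS_res/SS_tot in both.

For the matured swarm width, the package fits the **direction-averaged**
profile: each 10×10 µm ROI holds only ~15 bacteria, and once the swarm is
frozen that shot noise does not average out over time; pooling rays of a
radially symmetric accumulation is the cheap, legitimate variance
reduction. `matured_fwhm()` then requires fit R² ≥ 0.5 (pre-accumulation
profiles have no Gaussian), smooths the height curve with a running median
plus moving average, and reports the median FWHM from the first crossing
of 90% of the maximum smoothed height onward.

`estimate_accumulation_limit()` reports the largest distance whose fitted
`C_sat` still reaches a quarter of the maximum (the threshold fraction is
configurable; the effective-accumulation boundary is a definition, not a
measurement).

## Track velocimetry

The primary ingestion path is an annotation table (frame, id, x, y), the
same information manual tracking produces; `link_tracks()` adds greedy
nearest-neighbor linking (gap ≤ 1 frame, step gate, ties by smallest
displacement then lowest id) for synthetic detections.
`velocity_profile()` fits each track's first 30 observations (1 s at
30 frames/s; speeds are nearly constant over that window, so a line is
adequate) and pairs |slope| with the mean distance over the window —
"mean" rather than "starting" distance is a documented convention. The
boundary layer estimate is the largest leading distance at which every
nearer track is consistent with zero speed (`v ≤ max(threshold, 2·SE)`).
Note that with a C¹ smoothstep field the speed stays below 1 µm/s out to
~44 µm, so threshold-based estimates on noise-free data should use a
smaller threshold (the tests use 0.1 µm/s); on noisy data the boundary
estimate is threshold-limited, which is inherent to any zero-crossing
definition on a field with zero slope at the boundary.

## Speckle velocimetry

`temporal_speckle_contrast()` computes `K = σ_I/⟨I⟩` per pixel across the
frames in `[t_ON, t_ON + t_w]` with the sample (n−1) standard deviation (a
fixed convention so results are bit-reproducible). Defaults follow the
measurement practice the method was built around: `t_w = 15 s` (longer
windows blur spatial structure, shorter ones are noisy — the package tests
this as a variance ordering), histogram matching against an early
reference frame beforehand (`match_histograms()`, a monotone 8-bit CDF
map, so background brightness drift does not masquerade as contrast), and
the fiber masked out. Optional spatial box averaging of the K image
(`smooth_px`, odd; 9 px ≈ 8 µm is used by the validated pipeline) is the
standard speckle trade of resolution against per-pixel estimator noise —
with 450 frames of discrete blob traffic, the raw per-pixel K is
shot-noise dominated. Pixels whose windowed mean falls below 5 gray are
flagged: where accumulation saturates the sensor there are no speckles
left and K⁻¹ reflects the swarm boundary, not a speed (the "high-velocity
ring" artifact) — flagged, not suppressed.

`radial_contrast_profiles()` samples K along the five rays (bilinear
interpolation, 10 µm transverse averaging band, steps of 10 µm from 5 to
305 µm by default; points outside the usable image are omitted with a
notice). `calibrate_velocity()` interpolates the tracked speeds linearly
onto the profile radii and fits `v = slope·K⁻¹ + intercept` by OLS; a
non-positive slope is an error, and the zero-velocity cutoff is the K⁻¹
at which the line crosses zero — predictions below it are mathematically
sound but not physically meaningful and are clamped to zero.
`velocity_map()` applies the calibration per pixel and, by default, also
caps predictions at the largest calibrated speed, because beyond it the
linear map is extrapolation outside its fitted domain. K = 0 pixels are
handled with a 1e-12 floor rather than infinities.

In this system the K⁻¹–speed relation has two physical sources: the
exposure-time blur of fast-moving scatterers, and the coupling between
speed and concentration (slow regions are dense — the swarm and its
surroundings — and dense, slowly rearranging scatterers fluctuate
strongly). Both are present in the synthetic videos, and the validation
shows the calibrated maps recover the ground-truth field to an RMS error
under 10% of the plateau speed over the calibrated range, with the
K⁻¹–speed Spearman correlation above 0.95.

## Transport physics

All calculators are closed-form with SI inputs and explicit converters
(`um_s_to_m_s()`, `N_to_fN()`). The shipped constants are water at 20 °C
(ρ = 997 kg/m³, β = 1.8×10⁻⁴ /K, µ = 10⁻³ Pa·s, α = 1.43×10⁻⁷ m²/s) and
the *E. coli* cell (ρ_p = 1105 kg/m³, d_p = 1.075 µm volume-equivalent).
The terminal trapping speed uses constant-acceleration kinematics across
the boundary layer, `|v| = √(2 a d_bl)`, with the acceleration magnitude
1.91 µm/s² shipped as a named constant — it comes from a motion-equation
analysis whose derivation is not reproduced here, so it is an input, not a
derived quantity. The Reynolds characteristic length defaults to the
220 µm fiber diameter and is configurable. ΔT values are differences, so
Kelvin and Celsius are numerically identical.

## Problem sizes and reproducibility

The validation suite exercises the full pipeline on a 320×240 px, 60 s
video (the statistical behavior is scale-free in the frame size once the
field geometry fits) and checks the transport physics exactly; the
acceptance script runs the default 640×480 px, 60 s recording. All
randomness flows from a single integer seed per simulation; identical seed
and configuration give bit-identical tracks, frames, and downstream
results. The rendered stack is held as an 8-bit-valued integer array
(~0.5 GB for the scaled video, ~2.2 GB for the default scale), so a few
GB of memory are needed for full-scale runs.

## Known limitations

- The generator's vertical-exchange rates (bath 0.3 /s, capture 0.4 /s,
  capacity 6000) are modeling conventions chosen to reproduce the
  qualitative regime (matured swarm within a minute, steady free traffic);
  they are not measured quantities.
- The speckle stage yields speed magnitudes only, and its calibration is
  only as good as the tracked-velocity profile it is anchored to.
- `C` is an arbitrary concentration proxy; no calibration to cells/µm³ is
  attempted.
- The boundary-layer estimator inherits the resolution limits of a
  zero-crossing definition on a field that leaves zero smoothly.
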