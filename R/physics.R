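#' Fluid parameter set
#'
#' Bundles the fluid properties entering the Rayleigh-number and drag
#' calculations. The default values are those of water at room temperature
#' (20 degrees C), the medium in which the bacterial suspensions are imaged.
#'
#' @param rho Density (kg/m^3).
#' @param beta Volumetric thermal expansion coefficient (1/K).
#' @param mu Dynamic viscosity (Pa s).
#' @param alpha Thermal diffusivity (m^2/s).
#' @param g Gravitational acceleration (m/s^2).
#'
#' @return An object of class `fluid_params`.
#' @examples
#' water <- fluid_params()
#' rayleigh_number(water, l = 1.25e-4, delta_T = 10)
#' @export
fluid_params <- function(rho = 997, beta = 0.18e-3, mu = 1e-3,
                         alpha = 0.143e-6, g = 9.81) {
  vals <- c(rho = rho, beta = beta, mu = mu, alpha = alpha, g = g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all fluid parameters must be finite and strictly positive")
  }
  structure(as.list(vals), class = "fluid_params")
}

#' Suspended-particle parameter set
#'
#' Default values describe an *E. coli* cell: density 1105 kg/m^3 and a
#' volume-equivalent spherical diameter of 1.075 um.
#'
#' @param rho_p Particle density (kg/m^3).
#' @param d_p Volume-equivalent particle diameter (m).
#'
#' @return An object of class `particle_params`.
#' @export
particle_params <- function(rho_p = 1.105e3, d_p = 1.075e-6) {
  if (!is.finite(rho_p) || !is.finite(d_p) || rho_p <= 0 || d_p <= 0) {
    abort("particle parameters must be finite and strictly positive")
  }
  structure(list(rho_p = rho_p, d_p = d_p), class = "particle_params")
}

#' Rayleigh number
#'
#' Ra = rho * beta * l^3 * g * dT / (mu * alpha), the ratio of buoyancy-driven
#' to diffusive heat transport over a fluid layer of depth `l` heated by
#' `delta_T`. For uniform heating, natural convection classically sets in
#' above Ra ~ 1700; a highly localized heat source convects at any Ra > 0.
#'
#' @param fluid A [fluid_params()] object.
#' @param l Characteristic length (m); here the plasmonic array footprint.
#' @param delta_T Temperature difference (K).
#'
#' @return Dimensionless Rayleigh number.
#' @export
rayleigh_number <- function(fluid, l, delta_T) {
  stopifnot(inherits(fluid, "fluid_params"))
  if (!is.numeric(l) || any(l <= 0)) abort("`l` must be positive")
  if (any(delta_T < 0)) abort("`delta_T` must be non-negative")
  fluid$rho * fluid$beta * l^3 * fluid$g * delta_T / (fluid$mu * fluid$alpha)
}

#' Critical temperature difference for classical convection onset
#'
#' Inverts the Rayleigh number at its critical value: the `delta_T` a uniform
#' heating scenario would require before natural convection starts. With the
#' water defaults and `l` = 125 um this is about 7.1e4 K -- far beyond what
#' plasmonic heating can deliver, which is the argument that the observed
#' convection is driven by the localized temperature profile rather than by
#' bulk Rayleigh-Benard instability.
#'
#' @inheritParams rayleigh_number
#' @param Ra_crit Critical Rayleigh number (default 1700).
#'
#' @return Temperature difference in K (numerically identical in degrees C).
#' @examples
#' critical_delta_T(fluid_params(), l = 1.25e-4)
#' @export
critical_delta_T <- function(fluid, l, Ra_crit = 1700) {
  stopifnot(inherits(fluid, "fluid_params"))
  if (!is.numeric(l) || any(l <= 0)) abort("`l` must be positive")
  Ra_crit * fluid$mu * fluid$alpha / (fluid$rho * fluid$beta * l^3 * fluid$g)
}

#' Stokes number of a suspended particle
#'
#' St = rho_p * d_p^2 * u / (18 * mu_f * L). St << 1 means the particle
#' follows the flow faithfully even where the flow bends around obstacles,
#' i.e. it is a perfect tracer of the convection current.
#'
#' @param particle A [particle_params()] object.
#' @param u Flow speed (m/s).
#' @param mu_f Fluid dynamic viscosity (Pa s).
#' @param L Characteristic obstacle length (m); the fiber diameter by default
#'   in the bundled examples.
#'
#' @return Dimensionless Stokes number.
#' @export
stokes_number <- function(particle, u, mu_f = 1e-3, L) {
  stopifnot(inherits(particle, "particle_params"))
  if (!is.numeric(L) || any(L <= 0)) abort("`L` must be positive")
  particle$rho_p * particle$d_p^2 * u / (18 * mu_f * L)
}

#' Reynolds number
#'
#' Re = rho * u * L / mu. The characteristic length defaults to the fiber
#' diameter; with the measured plateau speed the flow is deep in the laminar
#' regime (Re ~ 1e-2).
#'
#' @inheritParams rayleigh_number
#' @param u Flow speed (m/s).
#' @param L Characteristic length (m).
#' @export
reynolds_number <- function(fluid, u, L = 220e-6) {
  stopifnot(inherits(fluid, "fluid_params"))
  if (!is.numeric(L) || any(L <= 0)) abort("`L` must be positive")
  fluid$rho * u * L / fluid$mu
}

#' Stokes drag force on a sphere
#'
#' F = -3 * pi * mu * d_p * v; the sign opposes the velocity. Use
#' [N_to_fN()] to express the magnitude in femtonewtons.
#'
#' @param mu Dynamic viscosity (Pa s).
#' @param d_p Particle diameter (m).
#' @param v Particle speed relative to the fluid (m/s).
#'
#' @return Force in N (negative when `v` is positive).
#' @examples
#' N_to_fN(abs(stokes_drag(1e-3, 1.075e-6, 9.91e-6)))
#' @export
stokes_drag <- function(mu, d_p, v) {
  if (any(d_p <= 0)) abort("`d_p` must be positive")
  -3 * pi * mu * d_p * v
}

#' Terminal in-plane trapping speed
#'
#' Constant-acceleration kinematics across the boundary layer: a particle
#' accelerated at `a` toward the tip over the boundary-layer distance `d_bl`
#' reaches |v| = sqrt(2 * a * d_bl). The expression is dimensionally
#' homogeneous, so micrometre-based inputs give a micrometre-based speed;
#' defaults are the shipped constants a = 1.91 um/s^2 and d_bl = 25.7 um.
#' The returned value is negative: motion toward the fiber tip.
#'
#' @param a Acceleration magnitude (um/s^2 with the defaults).
#' @param d_bl Boundary-layer thickness (um with the defaults).
#'
#' @return Signed terminal speed (negative, toward the tip).
#' @export
terminal_inplane_speed <- function(a = 1.91, d_bl = 25.7) {
  if (any(a < 0) || any(d_bl <= 0)) {
    abort("`a` must be non-negative and `d_bl` positive")
  }
  -sqrt(2 * a * d_bl)
}

#' Soret coefficient
#'
#' S_T = D_T / D, the ratio of the thermal-diffusion to the Fickian diffusion
#' coefficient. Particles migrate from warm to cool regions when S_T > 0 and
#' accumulate at warm regions when S_T < 0.
#'
#' @param D_T Thermal diffusion coefficient (m^2/(s K)).
#' @param D Fickian diffusion coefficient (m^2/s).
#' @export
soret_coefficient <- function(D_T, D) {
  if (any(D <= 0)) abort("`D` must be strictly positive")
  D_T / D
}

#' Net vertical body force (gravity minus buoyancy)
#'
#' (rho_p - rho_f) * (pi/6) * d_p^3 * g. For an *E. coli* cell in water this
#' is ~0.7 fN, two orders of magnitude below the ~100 fN trapping force,
#' confirming near-neutral buoyancy.
#'
#' @inheritParams stokes_number
#' @param fluid A [fluid_params()] object.
#' @export
net_body_force <- function(particle, fluid) {
  stopifnot(inherits(particle, "particle_params"), inherits(fluid, "fluid_params"))
  (particle$rho_p - fluid$rho) * (pi / 6) * particle$d_p^3 * fluid$g
}

#' Unit converters
#'
#' Small explicit converters between the SI quantities used internally and
#' the micrometre/femtonewton units used at the interface.
#'
#' @param x Value(s) to convert.
#' @name unit-converters
NULL

#' @rdname unit-converters
#' @export
um_s_to_m_s <- function(x) x * 1e-6

#' @rdname unit-converters
#' @export
m_s_to_um_s <- function(x) x * 1e6

#' @rdname unit-converters
#' @export
N_to_fN <- function(x) x * 1e15
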