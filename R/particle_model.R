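# Particle parameters and the forces/torques entering the overdamped Langevin
# equations: WCA pair repulsion, intensity-scaled acoustic propulsion, and the
# magnetic alignment torque.

#' Friction coefficients of a sphere in a viscous medium
#'
#' Stokes friction for translation, \eqn{\gamma_t = 3\pi\eta\sigma}, and the
#' corresponding rotational coefficient \eqn{\gamma_r = \pi\eta\sigma^3}.
#'
#' @param sigma Particle diameter (m).
#' @param eta Dynamic viscosity (Pa s).
#' @return Named vector `c(gamma_t, gamma_r)` (kg/s, kg m^2/s).
#' @export
frictionCoefficients <- function(sigma, eta) {
  stopifnot(sigma > 0, eta > 0)
  c(gamma_t = 3 * pi * eta * sigma, gamma_r = pi * eta * sigma^3)
}

#' Characteristic WCA interaction energy
#'
#' The interaction energy is set to the thermal energy at body temperature,
#' \eqn{\epsilon = k_B T_b}, so that passive particles keep a typical
#' separation of one diameter.
#'
#' @param T_b Temperature (K).
#' @return Energy (J).
#' @export
interactionEnergy <- function(T_b) {
  stopifnot(T_b >= 0)
  .kB * T_b
}

#' Physical particle parameters with derived transport coefficients
#'
#' @param sigma Particle diameter (m).
#' @param v0 Propulsion speed prescribed at the focus centre (m/s).
#' @param mu Remanent magnetic moment (J/T).
#' @param eta Medium viscosity (Pa s); blood plasma by default.
#' @param T_b Temperature (K); body temperature by default.
#' @param eps WCA interaction energy (J); defaults to \eqn{k_B T_b}.
#' @return Object of class `particleParams` including the derived friction
#'   coefficients and diffusion constants (`gamma_t`, `gamma_r`, `D_t`,
#'   `D_r`); the Einstein relations \eqn{D \gamma = k_B T_b} hold by
#'   construction.
#' @export
particleParams <- function(sigma = 1e-7, v0 = 1e-3, mu = 1.394e-17,
                           eta = 1e-3, T_b = 310,
                           eps = interactionEnergy(T_b)) {
  stopifnot(sigma > 0, v0 >= 0, mu >= 0, eta > 0, T_b > 0, eps >= 0)
  fr <- frictionCoefficients(sigma, eta)
  structure(list(sigma = sigma, v0 = v0, mu = mu, eta = eta, T_b = T_b,
                 eps = eps,
                 gamma_t = unname(fr["gamma_t"]),
                 gamma_r = unname(fr["gamma_r"]),
                 D_t = .kB * T_b / unname(fr["gamma_t"]),
                 D_r = .kB * T_b / unname(fr["gamma_r"])),
            class = "particleParams")
}

#' @export
print.particleParams <- function(x, ...) {
  cat(sprintf(paste0("particle: sigma %g nm, v0 %g mm/s, mu %.4g J/T\n",
                     "  D_t %.3g m^2/s, D_r %.3g 1/s\n"),
              x$sigma * 1e9, x$v0 * 1e3, x$mu, x$D_t, x$D_r))
  invisible(x)
}

#' Dimensionless magnetic alignment strength
#'
#' \eqn{\kappa = \mu B / (k_B T_b)}: the concentration parameter of the
#' stationary (von Mises) orientation distribution in a static field.
#'
#' @param params A [particleParams()].
#' @param B Magnetic flux density (T).
#' @return Dimensionless alignment strength.
#' @export
alignmentStrength <- function(params, B = 1e-3) {
  stopifnot(inherits(params, "particleParams"))
  params$mu * B / (.kB * params$T_b)
}

#' Orientational alignment time
#'
#' Time scale \eqn{\gamma_r / (\mu B)} over which the magnetic torque aligns a
#' particle; about 0.2 ms for the default parameters, far below the
#' sub-0.1 Hz rotation of the field.
#'
#' @param params A [particleParams()].
#' @param B Magnetic flux density (T).
#' @return Alignment time (s).
#' @export
alignmentTime <- function(params, B = 1e-3) {
  stopifnot(inherits(params, "particleParams"))
  params$gamma_r / (params$mu * B)
}

#' Weeks-Chandler-Andersen pair potential
#'
#' Purely repulsive truncated-and-shifted Lennard-Jones potential:
#' \eqn{V(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r < 2^{1/6}\sigma}, zero beyond.  `V(sigma) = eps`.
#'
#' @param r Pair distances (m).
#' @param sigma Particle diameter (m).
#' @param eps Interaction energy (J).
#' @return Potential energies (J).
#' @export
wcaPotential <- function(r, sigma, eps) {
  stopifnot(all(r > 0))
  cut <- 2^(1 / 6) * sigma
  sr6 <- (sigma / r)^6
  ifelse(r < cut, 4 * eps * (sr6^2 - sr6) + eps, 0)
}

#' WCA cutoff radius
#'
#' @param sigma Particle diameter (m).
#' @return \eqn{2^{1/6}\sigma} (m).
#' @export
wcaCutoff <- function(sigma) 2^(1 / 6) * sigma

#' WCA pair force
#'
#' Central repulsive force \eqn{-\nabla V} derived from [wcaPotential()]:
#' magnitude \eqn{(24\epsilon/r)[2(\sigma/r)^{12} - (\sigma/r)^6]} inside the
#' cutoff, zero (continuously) at and beyond it.
#'
#' @param rvec Separation vector(s) \eqn{r_1 - r_2} (m): length-2 vector or
#'   n x 2 matrix.
#' @param sigma Particle diameter (m).
#' @param eps Interaction energy (J).
#' @return List with `f1` (force on the first particle, n x 2 matrix, N) and
#'   `f2 = -f1` (force on the second; Newton's third law).
#' @export
wcaPairForce <- function(rvec, sigma, eps) {
  rv <- .asPointMatrix(rvec, 2L)
  r <- sqrt(rowSums(rv^2))
  if (any(r == 0)) stop("overlapping particles: pair distance is zero")
  mag <- wcaForceMagnitude(r, sigma, eps)
  f1 <- rv * (mag / r)
  list(f1 = f1, f2 = -f1)
}

#' Magnitude of the WCA pair force
#'
#' @param r Pair distances (m), positive.
#' @param sigma Particle diameter (m).
#' @param eps Interaction energy (J).
#' @return Force magnitudes (N); repulsive (positive along the separation).
#' @export
wcaForceMagnitude <- function(r, sigma, eps) {
  stopifnot(all(r > 0))
  cut <- 2^(1 / 6) * sigma
  sr6 <- (sigma / r)^6
  ifelse(r < cut, 24 * eps / r * (2 * sr6^2 - sr6), 0)
}

#' Acoustic propulsion force
#'
#' \eqn{F_p = v_0 \gamma_t I_n(r, t)\,\hat u(\varphi)}: the prescribed focal
#' propulsion speed scaled by the local normalized intensity, along the
#' particle orientation.
#'
#' @param position In-plane particle positions (n x 2 matrix or length-2
#'   vector, m); interpreted in the cross-section plane of `focus` given by
#'   `plane` (x-y runs: z = z0; x-z runs: y = y0).
#' @param phi Orientation angles (rad), length n.
#' @param focus A [gaussianFocus()] whose centre is the current focus
#'   position; the two in-plane centre coordinates are matched against
#'   `position`.
#' @param params A [particleParams()].
#' @param plane `"xy"` or `"xz"`.
#' @return n x 2 matrix of forces (N).
#' @export
propulsionForce <- function(position, phi, focus, params,
                            plane = c("xy", "xz")) {
  plane <- match.arg(plane)
  pos <- .asPointMatrix(position, 2L)
  stopifnot(inherits(focus, "gaussianFocus"), inherits(params, "particleParams"))
  b <- focusWidthsInPlane(focus, plane)
  ctr <- if (plane == "xy") focus$center[c(1, 2)] else focus$center[c(1, 3)]
  I <- exp(-((pos[, 1] - ctr[1]) / b[1])^2 - ((pos[, 2] - ctr[2]) / b[2])^2)
  mag <- params$v0 * params$gamma_t * I
  cbind(mag * cos(phi), mag * sin(phi))
}

#' Magnetic alignment torque
#'
#' Plane-normal component of \eqn{\mu\hat u(\varphi) \times B}: restoring
#' torque \eqn{T = \mu B \sin(\theta_B - \varphi)} that rotates the particle
#' orientation towards the field angle \eqn{\theta_B}.
#'
#' @param phi Orientation angles (rad).
#' @param field A `magneticField` (from [magneticFlux()]) or a list with
#'   elements `B` (T) and `angle` (rad).
#' @param mu Magnetic moment (J/T).
#' @return Torques (N m, scalar plane-normal component).
#' @export
magneticTorque <- function(phi, field, mu) {
  stopifnot(mu >= 0, !is.null(field$B), !is.null(field$angle))
  mu * field$B * sin(field$angle - phi)
}

#' Magnetite core specification
#'
#' @param core_diameter Diameter of the ferrimagnetic core (m).
#' @param mass_density Core material density (kg/m^3).
#' @param specific_moment Remanent specific magnetic moment (A m^2/kg;
#'   1 emu/g = 1 A m^2/kg).
#' @return Object of class `magnetiteCoreSpec`.
#' @export
magnetiteCoreSpec <- function(core_diameter = 80e-9, mass_density = 5200,
                              specific_moment = 10) {
  stopifnot(core_diameter >= 0, mass_density > 0, specific_moment >= 0)
  structure(list(core_diameter = core_diameter, mass_density = mass_density,
                 specific_moment = specific_moment),
            class = "magnetiteCoreSpec")
}

#' Remanent magnetic moment of a spherical core
#'
#' \eqn{\mu = m_{spec} \rho (\pi/6) d^3}: specific moment times core mass.
#' The defaults (80 nm magnetite core, 5.2 g/cm^3, 10 emu/g) give
#' \eqn{\mu = 1.394\times10^{-17}} J/T.
#'
#' @param spec A [magnetiteCoreSpec()].
#' @return Magnetic moment (J/T).
#' @export
magneticMomentFromCore <- function(spec = magnetiteCoreSpec()) {
  stopifnot(inherits(spec, "magnetiteCoreSpec"))
  spec$specific_moment * spec$mass_density * pi / 6 * spec$core_diameter^3
}

#' Particle ensemble state
#'
#' @param positions n x 2 matrix of in-plane positions (m).
#' @param orientations Orientation angles (rad), length n.
#' @param plane `"xy"` or `"xz"`.
#' @return Object of class `particleEnsemble`.
#' @export
particleEnsemble <- function(positions, orientations, plane = c("xy", "xz")) {
  plane <- match.arg(plane)
  positions <- .asPointMatrix(positions, 2L)
  stopifnot(length(orientations) == nrow(positions))
  structure(list(positions = positions,
                 orientations = as.numeric(orientations), plane = plane),
            class = "particleEnsemble")
}

#' @export
print.particleEnsemble <- function(x, ...) {
  cat(sprintf("particle ensemble: %d particles in the %s plane\n",
              nrow(x$positions), x$plane))
  invisible(x)
}
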