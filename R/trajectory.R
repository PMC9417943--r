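# Focus trajectory: inward Archimedean spiral at constant tangential speed,
# followed by a final orbit of radius R_f around the target.  Neighbouring
# spiral revolutions are separated radially by the focus diameter 2 R_f, i.e.
# dr/dphi = -R_f/pi, which together with r dphi/dt = v_phi fixes the closed
# forms used below.

#' Tangential focus speed for a prescribed run duration
#'
#' Solves (spiral arc length + final-circle circumference) / v_phi = t_s for
#' the tangential speed: the spiral runs from radius R_f + R_0 down to R_f
#' with radial pitch 2 R_f per revolution, the final orbit is a circle of
#' radius R_f.
#'
#' @param R_f Focus radius (m).
#' @param R_0 Radius of the initial particle distribution (m); `0` degenerates
#'   to the final circle alone.
#' @param t_s Total run duration (s).
#' @return Tangential speed v_phi (m/s).
#' @export
tangentialSpeedForDuration <- function(R_f, R_0, t_s) {
  stopifnot(R_f > 0, R_0 >= 0, t_s > 0)
  arc <- pi * ((R_f + R_0)^2 - R_f^2) / (2 * R_f) + 2 * pi * R_f
  arc / t_s
}

#' Spiral guiding plan for the ultrasound focus
#'
#' @param R_f Focus radius (m); half the lateral focal FWHM.
#' @param R_0 Radius of the initial particle distribution (m).
#' @param t_s Total duration of a guiding run (s).
#' @param v_phi Tangential speed (m/s); `NULL` calibrates it so that the
#'   spiral plus the final orbit take exactly `t_s` (via
#'   [tangentialSpeedForDuration()]).
#' @param plane Guiding plane: `"xy"` (circular spiral) or `"xz"` (spiral
#'   stretched along z by the focal aspect ratio).
#' @param chi Focal aspect ratio, used only for `plane = "xz"`.
#' @return An object of class `spiralPlan` with the derived phase times `t1`
#'   (spiral end) and `t2` (final-orbit duration), `t1 + t2 = t_s`.
#' @export
spiralPlan <- function(R_f = 0.7927e-3, R_0 = 0.01, t_s = 600,
                       v_phi = NULL, plane = c("xy", "xz"), chi = 6.38) {
  plane <- match.arg(plane)
  stopifnot(R_f > 0, R_0 > R_f, t_s > 0)
  if (is.null(v_phi)) v_phi <- tangentialSpeedForDuration(R_f, R_0, t_s)
  stopifnot(v_phi > 0)
  t1 <- pi * ((R_f + R_0)^2 - R_f^2) / (2 * v_phi * R_f)
  t2 <- 2 * pi * R_f / v_phi
  structure(list(R_f = R_f, R_0 = R_0, t_s = t1 + t2, v_phi = v_phi,
                 t1 = t1, t2 = t2, plane = plane, chi = chi),
            class = "spiralPlan")
}

#' @export
print.spiralPlan <- function(x, ...) {
  cat(sprintf(paste0("spiral plan (%s plane): R_f %.4g mm, R_0 %.3g cm, ",
                     "v_phi %.4g mm/s\n  spiral %.2f s + final orbit %.2f s ",
                     "= %.2f s\n"),
              x$plane, x$R_f * 1e3, x$R_0 * 1e2, x$v_phi * 1e3,
              x$t1, x$t2, x$t_s))
  invisible(x)
}

#' Spiral and final-orbit durations
#'
#' @param plan A [spiralPlan()].
#' @return Named vector `c(t1, t2)`: time at which the inward spiral ends and
#'   duration of the final orbit (s).
#' @export
phaseTimes <- function(plan) {
  stopifnot(inherits(plan, "spiralPlan"))
  c(t1 = plan$t1, t2 = plan$t2)
}

#' Trajectory parameter of the inward spiral
#'
#' s(t) solves constant-tangential-speed motion along the spiral:
#' \eqn{s(t) = [(R_f+R_0) - \sqrt{(R_f+R_0)^2 - 2 v_\phi R_f t / \pi}] / R_0},
#' with s(0) = 0 and s(t1) = 1 (focus edge touches the target centre).
#'
#' @param t Times (s) in `[0, t1]`.
#' @param plan A [spiralPlan()].
#' @return Trajectory parameter values in `[0, 1]`.
#' @export
trajectoryParameter <- function(t, plan) {
  stopifnot(inherits(plan, "spiralPlan"))
  if (any(t < -1e-12) || any(t > plan$t1 * (1 + 1e-12)))
    stop("t must lie within the spiral phase [0, t1]")
  a <- plan$R_f + plan$R_0
  disc <- pmax(a^2 - 2 * plan$v_phi * plan$R_f * t / pi, plan$R_f^2)
  pmin((a - sqrt(disc)) / plan$R_0, 1)
}

#' Phase angle of the focus
#'
#' During the spiral \eqn{\phi_f(t) = (\pi R_0 / R_f) s(t)} (so that one
#' revolution advances the radius by 2 R_f); during the final orbit the phase
#' advances linearly, \eqn{\phi_f(t) = \pi R_0/R_f + (v_\phi/R_f)(t - t_1)}.
#' The phase is continuous at t1 and left unwrapped.
#'
#' @param t Times (s) in `[0, t_s]`.
#' @param plan A [spiralPlan()].
#' @return Phase angles (rad).
#' @export
spiralPhase <- function(t, plan) {
  stopifnot(inherits(plan, "spiralPlan"))
  if (any(t < -1e-12) || any(t > plan$t_s * (1 + 1e-9)))
    stop("t must lie within the run duration [0, t_s]")
  out <- numeric(length(t))
  sp <- t <= plan$t1
  out[sp] <- (pi * plan$R_0 / plan$R_f) * trajectoryParameter(t[sp], plan)
  out[!sp] <- pi * plan$R_0 / plan$R_f +
    (plan$v_phi / plan$R_f) * (t[!sp] - plan$t1)
  out
}

#' In-plane radial coordinate of the focus
#'
#' @param t Times (s) in `[0, t_s]`.
#' @param plan A [spiralPlan()].
#' @return Radial coordinate r_f(t) (m): `R_f + R_0 (1 - s(t))` along the
#'   spiral, `R_f` on the final orbit.
#' @export
focusRadius <- function(t, plan) {
  stopifnot(inherits(plan, "spiralPlan"))
  out <- rep(plan$R_f, length(t))
  sp <- t <= plan$t1
  out[sp] <- plan$R_f + plan$R_0 * (1 - trajectoryParameter(t[sp], plan))
  out
}

#' In-plane focus position
#'
#' In the x-y plane the focus follows \eqn{r_f(t)\,\hat u(\phi_f(t))}.  In the
#' x-z plane the second (z) component is stretched by an additional
#' \eqn{(\chi - 1) R_f \sin\phi_f} term, so that the final orbit is an ellipse
#' with semi-axes (R_f, chi R_f) matching the spheroidal focus.
#'
#' @param t Times (s) in `[0, t_s]`.
#' @param plan A [spiralPlan()].
#' @return Matrix (length(t) x 2) of in-plane focus coordinates (m); columns
#'   are (x, y) for `"xy"` plans and (x, z) for `"xz"` plans.
#' @export
focusPosition <- function(t, plan) {
  stopifnot(inherits(plan, "spiralPlan"))
  r <- focusRadius(t, plan)
  ph <- spiralPhase(t, plan)
  pos <- cbind(r * cos(ph), r * sin(ph))
  if (plan$plane == "xz")
    pos[, 2] <- pos[, 2] + (plan$chi - 1) * plan$R_f * sin(ph)
  colnames(pos) <- if (plan$plane == "xz") c("x", "z") else c("x", "y")
  pos
}

#' Co-rotating magnetic field
#'
#' The homogeneous field has constant magnitude and always points from the
#' centre of the ultrasound focus towards the target at the origin.
#'
#' @param t Times (s) in `[0, t_s]`.
#' @param plan A [spiralPlan()].
#' @param B Flux density magnitude (T).
#' @return An object of class `magneticField`: list with `B` (T), `direction`
#'   (matrix of in-plane unit vectors) and `angle` (rad, field direction).
#' @export
magneticFlux <- function(t, plan, B = 1e-3) {
  stopifnot(B > 0)
  pos <- focusPosition(t, plan)
  nrm <- sqrt(rowSums(pos^2))
  if (any(nrm == 0)) stop("focus coincides with the target")
  dir <- -pos / nrm
  structure(list(B = B, direction = dir, angle = atan2(dir[, 2], dir[, 1])),
            class = "magneticField")
}
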