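# Focused-ultrasound field of a spherical-cap transducer and its
# spheroidal-Gaussian surrogate.
#
# Geometry convention: the cap lies on a sphere of radius `roc` centred at the
# origin, opening towards +z; the geometric focus (centre of curvature) is the
# origin and the beam propagates towards +z.  Patch coordinates are therefore
# (roc sin(th) cos(ph), roc sin(th) sin(ph), -roc cos(th)) for polar angle th
# measured from the beam axis.

#' Spherical-cap transducer geometry
#'
#' @param radius_of_curvature Radius of curvature of the cap (m).
#' @param aperture_diameter Aperture (chord) diameter of the cap (m); must not
#'   exceed twice the radius of curvature.
#' @param mesh_spacing Target linear size of the discretized surface patches
#'   (m).  `NULL` defers the choice to the evaluation routine, which uses
#'   one sixth of the acoustic wavelength.
#' @return An object of class `transducer`.
#' @examples
#' tr <- transducer()                     # 20 cm ROC, 20 cm aperture
#' @export
transducer <- function(radius_of_curvature = 0.2,
                       aperture_diameter = 0.2,
                       mesh_spacing = NULL) {
  stopifnot(radius_of_curvature > 0, aperture_diameter > 0)
  if (aperture_diameter > 2 * radius_of_curvature)
    stop("aperture_diameter must not exceed 2 * radius_of_curvature")
  if (!is.null(mesh_spacing) && mesh_spacing <= 0)
    stop("mesh_spacing must be positive")
  structure(list(radius_of_curvature = radius_of_curvature,
                 aperture_diameter = aperture_diameter,
                 mesh_spacing = mesh_spacing),
            class = "transducer")
}

#' @export
print.transducer <- function(x, ...) {
  cat(sprintf("spherical-cap transducer: ROC %g m, aperture %g m\n",
              x$radius_of_curvature, x$aperture_diameter))
  invisible(x)
}

#' Acoustic medium constants
#'
#' The attenuation coefficient is an amplitude attenuation per unit length and
#' per MHz; the default corresponds to 1 dB cm^-1 MHz^-1 in soft tissue.  The
#' density and cap velocity amplitude enter only the overall pressure
#' prefactor, which cancels on normalization, and are therefore optional.
#'
#' @param sound_speed Speed of sound (m/s).
#' @param frequency Ultrasound frequency (Hz).
#' @param attenuation Amplitude attenuation coefficient (m^-1 MHz^-1).
#' @param density Optional medium mass density (kg/m^3).
#' @param cap_velocity Optional velocity amplitude of the oscillating cap (m/s).
#' @return An object of class `acousticMedium`.
#' @export
acousticMedium <- function(sound_speed = 1500,
                           frequency = 1e6,
                           attenuation = 5 * log(10),
                           density = NULL,
                           cap_velocity = NULL) {
  stopifnot(sound_speed > 0, frequency > 0, attenuation >= 0)
  structure(list(sound_speed = sound_speed, frequency = frequency,
                 attenuation = attenuation, density = density,
                 cap_velocity = cap_velocity),
            class = "acousticMedium")
}

#' Wave number of an acoustic medium
#'
#' @param medium An [acousticMedium()].
#' @return Wave number \eqn{k = 2\pi f / c} (rad/m).
#' @export
waveNumber <- function(medium) 2 * pi * medium$frequency / medium$sound_speed

#' Acoustic wavelength
#'
#' @param medium An [acousticMedium()].
#' @return Wavelength c/f (m).
#' @export
wavelength <- function(medium) medium$sound_speed / medium$frequency

#' Discretize a spherical cap into near-equal-area patches
#'
#' Rings of equal polar-angle extent are subdivided azimuthally so that patch
#' diameters stay close to `mesh_spacing`; each ring's exact analytic area is
#' distributed evenly over its patches, so the patch areas sum exactly to the
#' analytic cap area.
#'
#' @param tr A [transducer()].
#' @param mesh_spacing Patch size (m); defaults to the transducer's stored
#'   value.
#' @return Matrix with columns `x`, `y`, `z`, `area` (one row per patch).
#' @export
discretizeCap <- function(tr, mesh_spacing = tr$mesh_spacing) {
  stopifnot(inherits(tr, "transducer"))
  if (is.null(mesh_spacing) || mesh_spacing <= 0)
    stop("mesh_spacing must be a positive length")
  R <- tr$radius_of_curvature
  thmax <- asin(tr$aperture_diameter / (2 * R))
  nth <- max(1L, ceiling(R * thmax / mesh_spacing))
  te <- seq(0, thmax, length.out = nth + 1L)
  out <- vector("list", nth)
  for (j in seq_len(nth)) {
    thj <- (te[j] + te[j + 1L]) / 2
    ring_area <- 2 * pi * R^2 * (cos(te[j]) - cos(te[j + 1L]))
    naz <- max(1L, round(2 * pi * R * sin(thj) / mesh_spacing))
    ph <- (seq_len(naz) - 0.5) * 2 * pi / naz
    out[[j]] <- cbind(x = R * sin(thj) * cos(ph),
                      y = R * sin(thj) * sin(ph),
                      z = -R * cos(thj),
                      area = ring_area / naz)
  }
  do.call(rbind, out)
}

#' Analytic area of the cap surface
#'
#' @param tr A [transducer()].
#' @return Cap area \eqn{2\pi R^2 (1 - \cos\theta_{max})} (m^2).
#' @export
capArea <- function(tr) {
  R <- tr$radius_of_curvature
  thmax <- asin(tr$aperture_diameter / (2 * R))
  2 * pi * R^2 * (1 - cos(thmax))
}

#' Complex pressure amplitude of the focused beam
#'
#' Evaluates the attenuated Rayleigh-Sommerfeld integral over the discretized
#' cap: each patch contributes \eqn{\exp((ik - a f_{MHz}) d) / d} times its
#' area, where d is the patch-to-point distance.  The overall prefactor
#' (density, cap velocity) is omitted; it cancels on normalization.
#'
#' @param points Numeric matrix (n x 3) of field points (m), or a length-3
#'   vector for a single point.
#' @param tr A [transducer()].
#' @param medium An [acousticMedium()].
#' @param mesh_spacing Patch size (m); default is wavelength/6.  Values above
#'   wavelength/6 are rejected: coarser meshes under-resolve the phase.
#' @return Complex vector of unnormalized pressures, one per point.
#' @export
pressureAmplitude <- function(points, tr, medium,
                              mesh_spacing = wavelength(medium) / 6) {
  pts <- .asPointMatrix(points, 3L)
  if (mesh_spacing > wavelength(medium) / 6 + 1e-12)
    stop("mesh_spacing must be at most one sixth of the wavelength")
  patches <- discretizeCap(tr, mesh_spacing)
  atten <- medium$attenuation * medium$frequency / 1e6
  rsPressureCpp(pts, patches, waveNumber(medium), atten, mesh_spacing / 2)
}

.asPointMatrix <- function(points, ncolumns) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  if (ncol(points) != ncolumns)
    stop(sprintf("points must have %d columns", ncolumns))
  storage.mode(points) <- "double"
  points
}

#' Normalize squared pressures to a unit-maximum intensity profile
#'
#' Intensity is proportional to the squared pressure amplitude; the profile is
#' normalized so that its maximum is exactly 1, which removes the
#' density/velocity prefactor of the pressure integral.
#'
#' @param pressures Complex (or numeric) pressures on the sample points.
#' @param sample_points Matrix (n x 3) of the corresponding coordinates (m).
#' @return An object of class `intensityProfile` with fields `sample_points`,
#'   `normalized_intensity` and `focus_location` (the sample of maximum
#'   intensity).
#' @export
normalizedIntensity <- function(pressures, sample_points) {
  sample_points <- .asPointMatrix(sample_points, 3L)
  if (length(pressures) != nrow(sample_points))
    stop("pressures and sample_points must have matching lengths")
  I <- Mod(pressures)^2
  if (max(I) == 0) stop("cannot normalize an all-zero pressure field")
  I <- I / max(I)
  structure(list(sample_points = sample_points,
                 normalized_intensity = I,
                 focus_location = sample_points[which.max(I), ]),
            class = "intensityProfile")
}

#' Full width at half maximum of a sampled 1-D profile
#'
#' The half-maximum crossings on both flanks of the (unique) maximum are
#' located by linear interpolation between the bracketing samples.
#'
#' @param coordinate Monotone coordinate values (m).
#' @param intensity Profile values; the profile must fall below half of its
#'   maximum on both sides of the peak.
#' @return Width between the two half-maximum crossings (same unit as
#'   `coordinate`).
#' @export
fwhm <- function(coordinate, intensity) {
  stopifnot(length(coordinate) == length(intensity), length(intensity) >= 3)
  if (is.unsorted(coordinate)) {
    o <- order(coordinate)
    coordinate <- coordinate[o]; intensity <- intensity[o]
  }
  half <- max(intensity) / 2
  im <- which.max(intensity)
  n <- length(intensity)
  if (!any(intensity[seq_len(im)] < half) ||
      !any(intensity[im:n] < half))
    stop("profile does not fall below half maximum on both flanks")
  li <- max(which(intensity[seq_len(im)] < half))
  ri <- im - 1L + min(which(intensity[im:n] < half))
  xl <- coordinate[li] + (half - intensity[li]) *
    (coordinate[li + 1L] - coordinate[li]) /
    (intensity[li + 1L] - intensity[li])
  xr <- coordinate[ri - 1L] + (half - intensity[ri - 1L]) *
    (coordinate[ri] - coordinate[ri - 1L]) /
    (intensity[ri] - intensity[ri - 1L])
  xr - xl
}

#' Locate the on-axis intensity maximum
#'
#' Attenuation shifts the intensity maximum off the geometric centre of
#' curvature towards the transducer; FWHM scans are taken through the actual
#' maximum, found here by a coarse axial scan refined with golden-section
#' search.
#'
#' @param tr A [transducer()].
#' @param medium An [acousticMedium()].
#' @param mesh_spacing Patch size (m) used for the search.
#' @param window Axial search window around the geometric focus (m).
#' @return Axial coordinate (m) of the intensity maximum (geometric focus = 0).
#' @export
findFocus <- function(tr, medium, mesh_spacing = wavelength(medium) / 6,
                      window = c(-0.02, 0.02)) {
  patches <- discretizeCap(tr, mesh_spacing)
  atten <- medium$attenuation * medium$frequency / 1e6
  k <- waveNumber(medium)
  axial <- function(z) {
    p <- rsPressureCpp(cbind(0, 0, z), patches, k, atten, mesh_spacing / 2)
    Mod(p)^2
  }
  zg <- seq(window[1], window[2], length.out = 161L)
  Ig <- axial(zg)
  z0 <- zg[which.max(Ig)]
  dz <- diff(zg[1:2])
  optimize(function(z) -axial(z), interval = c(z0 - dz, z0 + dz))$minimum
}

#' Line scan of the normalized intensity through the focus
#'
#' @param tr A [transducer()].
#' @param medium An [acousticMedium()].
#' @param axis `"lateral"` (x) or `"axial"` (z) scan direction.
#' @param center Length-3 coordinate (m) the scan passes through, typically
#'   the intensity maximum from [findFocus()].
#' @param extent Half-length of the scan (m).
#' @param step Scan step (m).
#' @param mesh_spacing Patch size (m).
#' @return Data frame with columns `coordinate` (m, centred on `center`) and
#'   `intensity` (normalized to the scan maximum).
#' @export
focalScan <- function(tr, medium, axis = c("lateral", "axial"),
                      center = c(0, 0, findFocus(tr, medium)),
                      extent = 3e-3, step = 2e-5,
                      mesh_spacing = wavelength(medium) / 6) {
  axis <- match.arg(axis)
  s <- seq(-extent, extent, by = step)
  pts <- matrix(rep(center, each = length(s)), ncol = 3L)
  pts[, if (axis == "lateral") 1L else 3L] <-
    pts[, if (axis == "lateral") 1L else 3L] + s
  p <- pressureAmplitude(pts, tr, medium, mesh_spacing)
  I <- Mod(p)^2
  data.frame(coordinate = s, intensity = I / max(I))
}

#' Spheroidal-Gaussian surrogate of the focal intensity
#'
#' @param b_xy Lateral 1/e half-width (m).
#' @param b_z Axial 1/e half-width (m); must exceed `b_xy`.
#' @param center Length-3 focus centre (m).
#' @return An object of class `gaussianFocus`.  The aspect ratio
#'   \eqn{\chi = b_z / b_{xy}} is stored alongside.
#' @export
gaussianFocus <- function(b_xy = 1.790e-3, b_z = 11.408e-3,
                          center = c(0, 0, 0)) {
  stopifnot(b_xy > 0, b_z > b_xy, length(center) == 3)
  structure(list(b_xy = b_xy, b_z = b_z, center = as.numeric(center),
                 chi = b_z / b_xy),
            class = "gaussianFocus")
}

#' @export
print.gaussianFocus <- function(x, ...) {
  cat(sprintf("Gaussian focus: b_xy %.4g mm, b_z %.4g mm, chi %.3f\n",
              x$b_xy * 1e3, x$b_z * 1e3, x$chi))
  invisible(x)
}

#' Evaluate the Gaussian surrogate intensity
#'
#' \eqn{I_n(r) = \exp(-((x-x_0)^2+(y-y_0)^2)/b_{xy}^2 - (z-z_0)^2/b_z^2)}.
#'
#' @param points Matrix (n x 3) of coordinates (m) or a length-3 vector.
#' @param focus A [gaussianFocus()].
#' @return Normalized intensities in `[0, 1]`.
#' @export
gaussianIntensity <- function(points, focus) {
  stopifnot(inherits(focus, "gaussianFocus"))
  pts <- .asPointMatrix(points, 3L)
  dx <- pts[, 1] - focus$center[1]
  dy <- pts[, 2] - focus$center[2]
  dz <- pts[, 3] - focus$center[3]
  exp(-(dx^2 + dy^2) / focus$b_xy^2 - dz^2 / focus$b_z^2)
}

#' In-plane Gaussian widths for a planar simulation
#'
#' In x-y runs the beam cross-section through the focus centre is isotropic
#' with width `b_xy`; in x-z runs the cross-section is anisotropic with widths
#' (`b_xy`, `b_z`).
#'
#' @param focus A [gaussianFocus()].
#' @param plane `"xy"` or `"xz"`.
#' @return Length-2 vector of widths (m) along the two in-plane axes.
#' @export
focusWidthsInPlane <- function(focus, plane = c("xy", "xz")) {
  plane <- match.arg(plane)
  if (plane == "xy") c(focus$b_xy, focus$b_xy) else c(focus$b_xy, focus$b_z)
}

#' Least-squares fit of the Gaussian surrogate to an intensity profile
#'
#' Fits \eqn{\exp(-((x-x_0)^2+(y-y_0)^2)/b_{xy}^2-(z-z_0)^2/b_z^2)} to the
#' samples by Levenberg-Marquardt.  The default fit window follows the choice
#' documented in the methods vignette: lateral offsets up to 3 mm and axial
#' offsets up to 20 mm around the profile maximum (main lobe plus near tails).
#'
#' @param profile An `intensityProfile` from [normalizedIntensity()].
#' @param lateral_window,axial_window Half-widths (m) of the fit region
#'   around the profile maximum; `Inf` uses all samples.
#' @param fit_center Fit the focus centre coordinates as free parameters
#'   (default) or pin them to the profile maximum.
#' @return A [gaussianFocus()] with attributes `residual_norm` (L2 norm of
#'   the fit residuals) and `fit` (the underlying `nls.lm` object).  A
#'   non-converged fit raises an error carrying the residual-norm history.
#' @export
fitGaussianSurrogate <- function(profile, lateral_window = 3e-3,
                                 axial_window = 20e-3, fit_center = TRUE) {
  stopifnot(inherits(profile, "intensityProfile"))
  pts <- profile$sample_points
  I <- profile$normalized_intensity
  fl <- profile$focus_location
  sel <- abs(pts[, 1] - fl[1]) <= lateral_window &
         abs(pts[, 2] - fl[2]) <= lateral_window &
         abs(pts[, 3] - fl[3]) <= axial_window
  if (sum(sel) < 8L) stop("fit window contains too few samples")
  # fit in coordinates centred on the profile maximum (centre starts exactly
  # at 0, which keeps the Levenberg-Marquardt parameter scaling well behaved)
  xs <- pts[sel, 1] - fl[1]
  ys <- pts[sel, 2] - fl[2]
  zs <- pts[sel, 3] - fl[3]
  Is <- I[sel]
  # centre offsets are only identifiable along sampled directions
  free <- fit_center & c(length(unique(xs)) > 1L, length(unique(ys)) > 1L,
                         length(unique(zs)) > 1L)
  resid_fn <- function(p) {
    off <- c(0, 0, 0)
    off[free] <- p[-(1:2)]
    Is - exp(-((xs - off[1])^2 + (ys - off[2])^2) / p[1]^2 -
             (zs - off[3])^2 / p[2]^2)
  }
  start <- c(max(diff(range(xs)), diff(range(ys)), 1e-4) / 3,
             max(diff(range(zs)), 1e-3) / 3, rep(0, sum(free)))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = c(1e-6, 1e-5, rep(-0.1, sum(free))),
                            upper = c(0.1, 0.5, rep(0.1, sum(free))),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, nprint = 0))
  if (!fit$info %in% 1:4)
    stop("Gaussian surrogate fit failed to converge: ", fit$message,
         "; residual-norm history: ",
         paste(signif(sqrt(fit$rsstrace), 6), collapse = ", "))
  cf <- fit$par
  ctr <- fl
  ctr[free] <- fl[free] + cf[-(1:2)]
  names(cf)[1:2] <- c("bxy", "bz")
  out <- gaussianFocus(b_xy = unname(abs(cf["bxy"])),
                       b_z = unname(abs(cf["bz"])), center = unname(ctr))
  attr(out, "residual_norm") <- sqrt(fit$deviance)
  attr(out, "fit") <- fit
  out
}

#' Acoustic energy density from intensity
#'
#' For a travelling wave the energy density is the intensity divided by the
#' sound speed; e.g. the diagnostic-ultrasound exposure limit of 720 mW/cm^2
#' corresponds to 4.8 J/m^3 at c = 1500 m/s.
#'
#' @param intensity Sound intensity (W/m^2).
#' @param sound_speed Speed of sound (m/s).
#' @return Energy density (J/m^3).
#' @export
energyDensityFromIntensity <- function(intensity, sound_speed) {
  stopifnot(sound_speed > 0)
  intensity / sound_speed
}

#' Continuous-equivalent energy density of pulsed ultrasound
#'
#' Converts an energy density measured under pulsed operation to the
#' continuous-wave equivalent at the same drive by dividing by the duty cycle.
#'
#' @param energy_density Energy density under pulsed operation (J/m^3).
#' @param duty_cycle Fraction of time the ultrasound is on, in (0, 1].
#' @return Continuous-equivalent energy density (J/m^3).
#' @export
dutyCycleRescale <- function(energy_density, duty_cycle) {
  if (any(duty_cycle <= 0) || any(duty_cycle > 1))
    stop("duty_cycle must lie in (0, 1]")
  energy_density / duty_cycle
}
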