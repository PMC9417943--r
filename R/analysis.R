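# Observables: radial packing density, target fraction, distance quantiles,
# ensemble statistics.

#' Radial packing-density histogram
#'
#' Bins particle distances from the target (origin) into half-open annuli
#' `[r, r + bin_width)` and converts counts to mean packing densities: the
#' particle cross-section area in an annulus divided by the annulus area.
#'
#' @param positions n x 2 matrix of in-plane positions (m).
#' @param sigma Particle diameter (m).
#' @param bin_width Annulus width (m).
#' @param r_max Outer radius (m); defaults to cover the farthest particle.
#' @return Object of class `radialHistogram`: data frame with columns `r_lo`,
#'   `r_hi`, `count`, `density`.
#' @export
radialDistribution <- function(positions, sigma = 1e-7, bin_width = 50e-6,
                               r_max = NULL) {
  pts <- .asPointMatrix(positions, 2L)
  stopifnot(bin_width > 0, sigma > 0)
  r <- sqrt(rowSums(pts^2))
  if (is.null(r_max)) r_max <- max(r, bin_width)
  nb <- max(1L, ceiling(r_max / bin_width - 1e-9))
  edges <- (0:nb) * bin_width
  idx <- pmin(floor(r / bin_width), nb - 1L) + 1L
  count <- tabulate(idx, nbins = nb)
  annulus <- pi * (edges[-1]^2 - edges[-(nb + 1)]^2)
  out <- data.frame(r_lo = edges[-(nb + 1)], r_hi = edges[-1],
                    count = count,
                    density = count * pi * (sigma / 2)^2 / annulus)
  class(out) <- c("radialHistogram", class(out))
  out
}

#' Fraction of particles inside the target
#'
#' @param positions n x 2 matrix of in-plane positions (m).
#' @param target_radius Target radius (m); particle centres within this
#'   distance of the origin count as inside.
#' @return Fraction in `[0, 1]`.
#' @export
targetFraction <- function(positions, target_radius = 1.5e-3) {
  pts <- .asPointMatrix(positions, 2L)
  stopifnot(target_radius > 0)
  if (nrow(pts) == 0) stop("target fraction undefined for an empty ensemble")
  mean(rowSums(pts^2) <= target_radius^2)
}

#' 70% quantile of particle distances
#'
#' Lower empirical quantile: the smallest distance r such that at least 70%
#' of the particles are within r of the target.
#'
#' @param distances Particle distances from the target (m).
#' @return The 70% quantile (m).
#' @export
quantile70 <- function(distances) {
  if (length(distances) == 0) stop("quantile undefined for empty input")
  s <- sort(distances)
  s[ceiling(0.7 * length(s))]
}

#' Mean and standard error over an ensemble of runs
#'
#' @param per_run_values One value per simulation run.
#' @return Named vector `c(mean, sem, sd, runs)`; for a single run the
#'   standard error is 0 by convention and flagged with a warning.
#' @export
ensembleStatistics <- function(per_run_values) {
  v <- as.numeric(per_run_values)
  if (length(v) < 1) stop("at least one run is required")
  if (length(v) == 1) {
    warning("single run: standard error reported as 0 by convention")
    return(c(mean = v, sem = 0, sd = 0, runs = 1))
  }
  c(mean = mean(v), sem = sd(v) / sqrt(length(v)), sd = sd(v),
    runs = length(v))
}

#' Areal packing density
#'
#' Total particle cross-section area over the area of the square simulation
#' domain of side `l`: \eqn{N_p \pi (\sigma/2)^2 / l^2}.
#'
#' @param N_p Number of particles.
#' @param sigma Particle diameter (m).
#' @param l Domain side length (m).
#' @return Dimensionless packing density.
#' @export
arealPackingDensity <- function(N_p, sigma = 1e-7, l = 0.02) {
  stopifnot(N_p >= 0, sigma > 0, l > 0)
  N_p * pi * (sigma / 2)^2 / l^2
}

#' Guiding observables over a recorded trajectory
#'
#' Computes the target fraction and 70% distance quantile at every recorded
#' snapshot of a run.
#'
#' @param record A `trajectoryRecord` from [runSimulation()].
#' @param target_radius Target radius (m).
#' @return Object of class `guidingSummary`: data frame with columns `time`,
#'   `phi` (target fraction) and `q70` (m).
#' @export
guidingSummary <- function(record, target_radius = 1.5e-3) {
  stopifnot(inherits(record, "trajectoryRecord"))
  nt <- length(record$times)
  phi <- numeric(nt)
  q70 <- numeric(nt)
  for (ti in seq_len(nt)) {
    pos <- record$positions[ti, , ]
    if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2L)
    d <- sqrt(rowSums(pos^2))
    phi[ti] <- mean(d <= target_radius)
    q70[ti] <- quantile70(d)
  }
  out <- data.frame(time = record$times, phi = phi, q70 = q70)
  class(out) <- c("guidingSummary", class(out))
  out
}
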