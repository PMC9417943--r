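# Euler-Maruyama integration of the overdamped Langevin equations and the
# orchestration of full guiding runs.
#
# Presets:
#   paper_faithful - dt = 0.3 us, WCA particle interactions on, explicit
#     orientation Langevin dynamics.  Resolves the pair interaction; intended
#     for cluster-scale runs.
#   desk_fine      - dt = 5 us, interactions off (the areal packing density of
#     1.96e-8 makes encounters negligible), explicit orientation dynamics.
#   desk_coarse    - dt = 10 ms, interactions off, orientation treated
#     quasi-statically: the alignment time gamma_r/(mu B) ~ 0.2 ms is far
#     below dt, so each step draws the orientation from the stationary von
#     Mises distribution around the field angle.  Wall confinement at this dt
#     is enforced by bounce-back (the WCA wall range of ~0.1 um cannot be
#     resolved by ~10 um steps).

#' Simulation configuration
#'
#' @param preset One of `"desk_coarse"`, `"desk_fine"`, `"paper_faithful"`;
#'   fixes defaults for the remaining arguments, each of which can be
#'   overridden.
#' @param dt Time step (s).
#' @param t_s Simulated duration (s).
#' @param seed Integer seed for the run's random-number stream.
#' @param N_p Number of particles.
#' @param domain_half_width Half-width (m) of the square stop domain; a
#'   particle leaving it flags the run as invalid.
#' @param interactions Enable WCA particle-particle interactions.
#' @param record_interval Interval (s) between recorded snapshots; must be at
#'   least `dt`.
#' @param orientation `"langevin"` (explicit Euler-Maruyama orientation
#'   update) or `"quasistatic"` (stationary von Mises draw each step).
#' @param wall_model `"wca"` (WCA wall force plus bounce-back safety) or
#'   `"reject"` (bounce-back only).
#' @param field_update_interval Interval (s) at which the focus position and
#'   field angle are refreshed; the focus moves ~0.4 um per ms, far below the
#'   focal width, so 1 ms is ample.
#' @return Object of class `simulationConfig`.
#' @export
simulationConfig <- function(preset = c("desk_coarse", "desk_fine",
                                        "paper_faithful"),
                             dt = NULL, t_s = 600, seed = 1L, N_p = 100L,
                             domain_half_width = 0.012,
                             interactions = NULL, record_interval = 10,
                             orientation = NULL, wall_model = NULL,
                             field_update_interval = 1e-3) {
  preset <- match.arg(preset)
  def <- switch(preset,
    desk_coarse    = list(dt = 1e-2, interactions = FALSE,
                          orientation = "quasistatic", wall_model = "reject"),
    desk_fine      = list(dt = 5e-6, interactions = FALSE,
                          orientation = "langevin", wall_model = "wca"),
    paper_faithful = list(dt = 0.3e-6, interactions = TRUE,
                          orientation = "langevin", wall_model = "wca"))
  dt <- if (is.null(dt)) def$dt else dt
  interactions <- if (is.null(interactions)) def$interactions else interactions
  orientation <- if (is.null(orientation)) def$orientation else
    match.arg(orientation, c("langevin", "quasistatic"))
  wall_model <- if (is.null(wall_model)) def$wall_model else
    match.arg(wall_model, c("wca", "reject"))
  stopifnot(dt > 0, t_s > 0, record_interval >= dt, N_p >= 0,
            domain_half_width > 0)
  structure(list(preset = preset, dt = dt, t_s = t_s,
                 seed = as.integer(seed), N_p = as.integer(N_p),
                 domain_half_width = domain_half_width,
                 interactions = interactions,
                 record_interval = record_interval,
                 orientation = orientation, wall_model = wall_model,
                 field_update_interval = field_update_interval),
            class = "simulationConfig")
}

#' @export
print.simulationConfig <- function(x, ...) {
  cat(sprintf(paste0("simulation config [%s]: dt %g s, t_s %g s, N_p %d,\n",
                     "  interactions %s, orientation %s, wall model %s, ",
                     "seed %d\n"),
              x$preset, x$dt, x$t_s, x$N_p, x$interactions, x$orientation,
              x$wall_model, x$seed))
  invisible(x)
}

#' One Euler-Maruyama step of the overdamped Langevin equations
#'
#' Positions advance by \eqn{(F/\gamma_t)\Delta t + \sqrt{2 D_t \Delta t}\,
#' \xi}, orientations by \eqn{(T/\gamma_r)\Delta t + \sqrt{2 D_r \Delta t}\,
#' \xi_r}, with independent standard normal draws per particle and channel.
#'
#' @param ensemble A [particleEnsemble()].
#' @param forces n x 2 matrix of total forces (N).
#' @param torques Length-n vector of plane-normal torques (N m).
#' @param params A [particleParams()].
#' @param dt Time step (s).
#' @param noise Set `FALSE` for the deterministic (zero-noise) limit.
#' @return The advanced [particleEnsemble()].
#' @export
eulerMaruyamaStep <- function(ensemble, forces, torques, params, dt,
                              noise = TRUE) {
  stopifnot(inherits(ensemble, "particleEnsemble"),
            inherits(params, "particleParams"), dt > 0)
  n <- nrow(ensemble$positions)
  forces <- .asPointMatrix(forces, 2L)
  stopifnot(nrow(forces) == n, length(torques) == n)
  if (any(!is.finite(forces)) || any(!is.finite(torques))) {
    bad <- which(!is.finite(rowSums(forces)) | !is.finite(torques))
    stop("non-finite force/torque for particle index ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  pos <- ensemble$positions + forces / params$gamma_t * dt
  phi <- ensemble$orientations + torques / params$gamma_r * dt
  if (noise) {
    pos <- pos + sqrt(2 * params$D_t * dt) * matrix(rnorm(2 * n), n, 2L)
    phi <- phi + sqrt(2 * params$D_r * dt) * rnorm(n)
  }
  particleEnsemble(pos, phi, ensemble$plane)
}

#' All particle pairs closer than a cutoff
#'
#' Cell-binning neighbour search returning exactly the pairs with separation
#' below `cutoff` (the brute-force \eqn{O(N^2)} enumeration is the test
#' oracle).
#'
#' @param positions n x 2 matrix of positions (m).
#' @param cutoff Pair-distance cutoff (m).
#' @return Two-column integer matrix of pair indices `(i, j)` with `i < j`;
#'   zero rows when no pair qualifies.
#' @export
neighborPairs <- function(positions, cutoff) {
  pts <- .asPointMatrix(positions, 2L)
  stopifnot(cutoff > 0)
  n <- nrow(pts)
  empty <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j")))
  if (n < 2L) return(empty)
  cx <- floor(pts[, 1] / cutoff)
  cy <- floor(pts[, 2] / cutoff)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  coord <- lapply(strsplit(names(cells), " "), as.numeric)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (ci in seq_along(cells)) assign(names(cells)[ci], ci, envir = lookup)
  out <- list()
  for (ci in seq_along(cells)) {
    cc <- coord[[ci]]
    mine <- cells[[ci]]
    # same cell
    if (length(mine) > 1L) {
      cmb <- utils::combn(mine, 2L)
      out[[length(out) + 1L]] <- t(cmb)
    }
    # half of the neighbouring cells (avoid double counting)
    for (dxy in list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))) {
      nb <- paste(cc[1] + dxy[1], cc[2] + dxy[2])
      cj <- get0(nb, envir = lookup, ifnotfound = NULL)
      if (is.null(cj)) next
      other <- cells[[cj]]
      out[[length(out) + 1L]] <-
        cbind(rep(mine, each = length(other)), rep(other, length(mine)))
    }
  }
  if (length(out) == 0L) return(empty)
  pr <- do.call(rbind, out)
  d2 <- (pts[pr[, 1], 1] - pts[pr[, 2], 1])^2 +
        (pts[pr[, 1], 2] - pts[pr[, 2], 2])^2
  pr <- pr[d2 < cutoff^2, , drop = FALSE]
  pr <- cbind(i = pmin(pr[, 1], pr[, 2]), j = pmax(pr[, 1], pr[, 2]))
  pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
}

#' Run a full guiding simulation
#'
#' Advances the ensemble from t = 0 to t = t_s with the Euler-Maruyama
#' scheme, recomputing the focus position and co-rotating field along the
#' spiral plan, and records snapshots at the configured interval.  Initial
#' positions are uniform over the disk of radius `plan$R_0` (intersected with
#' the channel interior when a network is given); initial orientations are
#' uniform on `[0, 2 pi)`.
#'
#' @param config A [simulationConfig()].
#' @param plan A [spiralPlan()].
#' @param params A [particleParams()].
#' @param environment Optional [buildChannelGeometry()] channel network.
#' @param focus A [gaussianFocus()] supplying the beam widths.
#' @param B Magnetic flux density (T).
#' @param initial Optional list with `positions` (n x 2) and `orientations`
#'   to override the random initial state.
#' @return Object of class `trajectoryRecord`: sample `times`, recorded
#'   `positions` (time x particle x 2 array), `orientations` (time x
#'   particle), the run metadata, and `exited` (`TRUE` if a particle left
#'   the stop domain, which flags the run as invalid).
#' @export
runSimulation <- function(config, plan = spiralPlan(), params = particleParams(),
                          environment = NULL, focus = gaussianFocus(),
                          B = 1e-3, initial = NULL) {
  stopifnot(inherits(config, "simulationConfig"), inherits(plan, "spiralPlan"),
            inherits(params, "particleParams"))
  set.seed(config$seed)
  if (is.null(initial)) {
    pos0 <- sampleInitialPositions(config$N_p, plan$R_0, environment)
    phi0 <- runif(config$N_p, 0, 2 * pi)
  } else {
    pos0 <- .asPointMatrix(initial$positions, 2L)
    phi0 <- as.numeric(initial$orientations)
    stopifnot(length(phi0) == nrow(pos0))
  }
  nsteps <- ceiling(config$t_s / config$dt)
  recordEvery <- max(1L, round(config$record_interval / config$dt))
  focusEvery <- max(1L, floor(config$field_update_interval / config$dt))
  nf <- ceiling(nsteps / focusEvery) + 1L
  tf <- pmin((seq_len(nf) - 1L) * focusEvery * config$dt, plan$t_s)
  fpos <- focusPosition(tf, plan)
  thB <- magneticFlux(tf, plan, B)$angle
  bw <- focusWidthsInPlane(focus, plan$plane)
  kappa <- alignmentStrength(params, B)
  ch <- NULL
  if (!is.null(environment)) {
    stopifnot(inherits(environment, "channelNetwork"))
    g <- environment$grid
    ch <- list(segments = environment$segments, halfw = environment$w / 2,
               xmin = g$xmin, ymin = g$ymin, cell = g$cell,
               nx = g$nx, ny = g$ny, start = g$start, index = g$index,
               wallMode = if (config$wall_model == "wca") 2L else 1L)
  }
  res <- bdRunCpp(pos0, phi0, as.integer(nsteps), config$dt,
                  fpos, thB, as.integer(focusEvery),
                  bw[1], bw[2], params$v0, params$gamma_t, params$gamma_r,
                  params$D_t, params$D_r, params$mu * B, kappa,
                  if (config$orientation == "quasistatic") 1L else 0L,
                  config$interactions, params$sigma, params$eps,
                  ch, config$domain_half_width, as.integer(recordEvery))
  structure(list(times = res$times,
                 positions = res$positions,
                 orientations = res$orientations,
                 exited = res$exited >= 0L,
                 exit_step = if (res$exited >= 0L) res$exited else NA_integer_,
                 config = config, plan = plan, params = params,
                 B = B, focus = focus,
                 channelled = !is.null(environment)),
            class = "trajectoryRecord")
}

#' @export
print.trajectoryRecord <- function(x, ...) {
  cat(sprintf(paste0("trajectory record: %d particles, %d snapshots over ",
                     "%g s (%s plane%s)%s\n"),
              dim(x$positions)[2], length(x$times), max(x$times),
              x$plan$plane, if (x$channelled) ", channel network" else "",
              if (x$exited) " [INVALID: particle left the domain]" else ""))
  invisible(x)
}
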