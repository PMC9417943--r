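# Random channel networks: persistent random walks started from the domain
# boundary, thickened into a union of width-w capsules (spheres at the walk
# points, cylinders along the steps) that confines the particles.

#' Generate persistent random-walk channel axes
#'
#' One walk starts from each of the equally spaced boundary points of the
#' square domain, with its first step perpendicular to the boundary, inward.
#' Each subsequent step deviates from the previous heading by a random angle
#' drawn from a zero-mean Gaussian with standard deviation pi/8; the
#' cumulative deviation from the inward normal is clamped to `[-pi/4, pi/4]`,
#' which increases the persistence length and avoids loops.  A walk stops as
#' soon as it reaches the boundary again.
#'
#' @param l_qd Side length of the square domain (m), centred on the origin.
#' @param d Spacing of the walk starting points along the boundary (m).
#' @param w Step length = channel width (m).
#' @param sd_step Standard deviation of the per-step heading deviation (rad).
#' @param max_steps Safety bound on the number of steps per walk.
#' @return List of paths; each path is a matrix (k x 2) of points (m) with
#'   consecutive points separated by exactly `w`.
#' @export
generatePaths <- function(l_qd = 0.024, d = 1e-3, w = 5e-4,
                          sd_step = pi / 8, max_steps = 10000L) {
  stopifnot(l_qd > 0, d > 0, w > 0)
  half <- l_qd / 2
  perim <- 4 * l_qd
  nstart <- round(perim / d)
  # arc-length positions along the boundary, one per start, side by side
  svals <- (seq_len(nstart) - 0.5) * perim / nstart
  paths <- vector("list", nstart)
  for (i in seq_len(nstart)) {
    s <- svals[i]
    side <- min(floor(s / l_qd), 3)
    u <- s - side * l_qd - half
    # boundary point and inward normal per side (counter-clockwise order)
    start <- switch(side + 1L,
                    c(u, -half), c(half, u), c(-u, half), c(-half, -u))
    normal <- switch(side + 1L,
                     pi / 2, pi, -pi / 2, 0)
    pts <- matrix(NA_real_, nrow = max_steps + 1L, ncol = 2L)
    pts[1L, ] <- start
    alpha <- 0
    heading <- normal
    k <- 1L
    repeat {
      step <- w * c(cos(heading), sin(heading))
      nxt <- pts[k, ] + step
      if ((abs(nxt[1]) >= half || abs(nxt[2]) >= half) && k > 1L) {
        # clip the final step at the boundary crossing and stop
        tx <- if (step[1] != 0)
          max((sign(step[1]) * half - pts[k, 1]) / step[1], 0) else Inf
        ty <- if (step[2] != 0)
          max((sign(step[2]) * half - pts[k, 2]) / step[2], 0) else Inf
        nxt <- pts[k, ] + min(tx, ty, 1) * step
      }
      k <- k + 1L
      pts[k, ] <- nxt
      if (abs(nxt[1]) >= half - 1e-15 || abs(nxt[2]) >= half - 1e-15 ||
          k > max_steps) break
      alpha <- max(-pi / 4, min(pi / 4, alpha + rnorm(1, 0, sd_step)))
      heading <- normal + alpha
    }
    paths[[i]] <- pts[seq_len(k), , drop = FALSE]
  }
  paths
}

#' Build the capsule-union channel geometry
#'
#' The channel interior is the set of points within `w/2` of any walk axis
#' (union of spheres at path points and cylinders along steps, i.e. capsules
#' around the path segments), clipped to the domain.  A cell grid over the
#' segments accelerates distance queries.
#'
#' @param paths List of path matrices from [generatePaths()].
#' @param w Channel width (m).
#' @param l_qd Domain side length (m).
#' @param cell_size Edge length of the acceleration-grid cells (m).
#' @param margin Distance (m) beyond `w/2` up to which grid queries are
#'   guaranteed exact; larger distances are reported as `Inf`.
#' @return Object of class `channelNetwork`.
#' @export
buildChannelGeometry <- function(paths, w = 5e-4, l_qd = 0.024,
                                 cell_size = 5e-4, margin = 1e-4) {
  stopifnot(length(paths) >= 1, w > 0)
  segs <- do.call(rbind, lapply(paths, function(p) {
    k <- nrow(p)
    if (k < 2L) return(NULL)
    cbind(p[-k, 1], p[-k, 2], p[-1, 1], p[-1, 2])
  }))
  if (is.null(segs) || nrow(segs) == 0) stop("paths contain no segments")
  half <- l_qd / 2
  reach <- w / 2 + margin
  xmin <- min(segs[, c(1, 3)]) - reach
  ymin <- min(segs[, c(2, 4)]) - reach
  nx <- max(1L, ceiling((max(segs[, c(1, 3)]) + reach - xmin) / cell_size))
  ny <- max(1L, ceiling((max(segs[, c(2, 4)]) + reach - ymin) / cell_size))
  idx <- buildSegmentGridCpp(segs, reach, xmin, ymin, cell_size,
                             as.integer(nx), as.integer(ny))
  structure(list(paths = paths, segments = segs, w = w, l_qd = l_qd,
                 grid = list(xmin = xmin, ymin = ymin, cell = cell_size,
                             nx = as.integer(nx), ny = as.integer(ny),
                             start = idx$start, index = idx$index,
                             reach = reach)),
            class = "channelNetwork")
}

#' @export
print.channelNetwork <- function(x, ...) {
  cat(sprintf(paste0("channel network: %d paths, %d segments, width %g um, ",
                     "domain %g cm\n"),
              length(x$paths), nrow(x$segments), x$w * 1e6, x$l_qd * 1e2))
  invisible(x)
}

#' Distance from points to the nearest channel axis
#'
#' Minimum point-to-segment distance over all walk segments, evaluated via
#' the network's cell grid.  Distances beyond `w/2 + margin` (outside the
#' grid's guarantee) are reported as `Inf`.
#'
#' @param points n x 2 matrix of in-plane points (m).
#' @param network A [buildChannelGeometry()] network.
#' @return List with `distance` (m) and `nearest` (n x 2 matrix, the nearest
#'   axis points, `NA` where the distance is `Inf`).
#' @export
channelDistance <- function(points, network) {
  stopifnot(inherits(network, "channelNetwork"))
  pts <- .asPointMatrix(points, 2L)
  g <- network$grid
  res <- channelMinDistanceCpp(pts, network$segments, g$xmin, g$ymin, g$cell,
                               g$nx, g$ny, g$start, g$index)
  # the cell grid only guarantees exactness up to `reach`; beyond that the
  # listed candidates need not include the globally nearest segment
  res$distance[res$distance > g$reach] <- Inf
  res$nearest[!is.finite(res$distance), ] <- NA_real_
  res
}

#' Channel interior membership test
#'
#' @param points n x 2 matrix of in-plane points (m).
#' @param network A [buildChannelGeometry()] network.
#' @return Logical vector: within `w/2` of some walk axis.
#' @export
channelContains <- function(points, network) {
  channelDistance(points, network)$distance <= network$w / 2
}

#' Implicit wall force from the channel surface
#'
#' The channel walls are chains of 100 nm wall particles spaced `wall_spacing`
#' apart on the capsule-union surface.  The implicit model evaluates, for a
#' particle at gap g from the nearest wall surface, the WCA force of a locally
#' straight such chain with one wall particle at the nearest surface point:
#' \eqn{F(g) = \sum_n f_{wca}(\sqrt{g^2 + (n\Delta s)^2})\, g/\sqrt{g^2 +
#' (n\Delta s)^2}}, directed from the wall towards the channel axis.  Beyond
#' the WCA cutoff from every wall the force is zero.
#'
#' @param positions n x 2 matrix of in-plane positions (m), inside the
#'   channel interior.
#' @param network A [buildChannelGeometry()] network.
#' @param sigma Particle (and wall-particle) diameter (m).
#' @param eps Interaction energy (J).
#' @param wall_spacing Centre-to-centre wall-particle spacing (m).
#' @return n x 2 matrix of forces (N).
#' @export
wallForce <- function(positions, network, sigma = 1e-7,
                      eps = interactionEnergy(310), wall_spacing = 5e-8) {
  pts <- .asPointMatrix(positions, 2L)
  cd <- channelDistance(pts, network)
  inside <- cd$distance <= network$w / 2
  if (any(!inside))
    stop("particle escaped confinement: position outside the channel interior")
  gap <- network$w / 2 - cd$distance     # distance to the wall surface
  f <- matrix(0, nrow(pts), 2L)
  cut <- wcaCutoff(sigma)
  act <- gap < cut
  if (any(act)) {
    mag <- wallChainForce(gap[act], sigma, eps, wall_spacing)
    # direction from particle towards the nearest axis point (inward normal)
    dvec <- cd$nearest[act, , drop = FALSE] - pts[act, , drop = FALSE]
    nrm <- sqrt(rowSums(dvec^2))
    on_axis <- nrm == 0
    dvec[on_axis, ] <- 0          # exactly on the axis: no defined normal
    nrm[on_axis] <- 1
    f[act, ] <- dvec / nrm * mag
  }
  f
}

#' Normal force of a straight wall-particle chain
#'
#' Registration-averaged net WCA force exerted on a particle at perpendicular
#' gap `g` by an infinite straight chain of wall particles with spacing `ds`:
#' the average over the chain phase of the discrete sum, which equals the
#' continuum line integral \eqn{(1/\Delta s)\int f_{wca}(\sqrt{g^2+s^2})\,
#' g/\sqrt{g^2+s^2}\,ds}.  The wall-particle spacing (50 nm) is comparable to
#' the WCA range, so the instantaneous discrete force oscillates around this
#' mean with the lateral position; the implicit wall model uses the mean,
#' which is what a particle diffusing along the wall samples.
#'
#' @param gap Perpendicular gaps (m), positive.
#' @param sigma Particle diameter (m).
#' @param eps Interaction energy (J).
#' @param ds Wall-particle spacing (m).
#' @return Force magnitudes (N), directed along the inward wall normal.
#' @export
wallChainForce <- function(gap, sigma, eps, ds = 5e-8) {
  cut <- wcaCutoff(sigma)
  gap <- pmax(gap, 0.5 * sigma)   # cap the divergence for robustness
  vapply(gap, function(g) {
    smax <- sqrt(max(cut^2 - g^2, 0))
    if (smax == 0) return(0)
    2 / ds * integrate(function(s) {
      r <- sqrt(g^2 + s^2)
      wcaForceMagnitude(r, sigma, eps) * g / r
    }, 0, smax, rel.tol = 1e-10)$value
  }, numeric(1))
}

#' Explicit wall particles on the channel surface
#'
#' Samples candidate wall-particle positions at spacing `wall_spacing` along
#' both offset curves (and end caps) of every path capsule and keeps those
#' lying on the boundary of the capsule union, i.e. at distance `w/2` from
#' the nearest axis.  Intended as a validation reference for the implicit
#' wall model; the full-network chain is large.
#'
#' @param network A [buildChannelGeometry()] network.
#' @param wall_spacing Centre-to-centre spacing (m).
#' @param tol Tolerance (m) on the surface-membership test.
#' @return Matrix (m x 2) of wall-particle positions.
#' @export
explicitWallParticles <- function(network, wall_spacing = 5e-8, tol = 1e-9) {
  stopifnot(inherits(network, "channelNetwork"))
  hw <- network$w / 2
  cand <- list()
  for (p in network$paths) {
    k <- nrow(p)
    if (k < 2) next
    dirs <- diff(p)
    len <- sqrt(rowSums(dirs^2))
    dirs <- dirs / len
    for (j in seq_len(k - 1L)) {
      nrml <- c(-dirs[j, 2], dirs[j, 1])
      # half-open [0, len): the segment end is supplied by the next segment
      svals <- seq(0, len[j] - wall_spacing / 2, by = wall_spacing)
      base <- cbind(p[j, 1] + svals * dirs[j, 1],
                    p[j, 2] + svals * dirs[j, 2])
      cand[[length(cand) + 1L]] <-
        rbind(base + rep(hw * nrml, each = nrow(base)),
              base - rep(hw * nrml, each = nrow(base)))
    }
    # end caps: semicircular arcs at the two path ends
    for (endpt in list(list(p[1, ], -dirs[1, ]), list(p[k, ], dirs[k - 1, ]))) {
      ang0 <- atan2(endpt[[2]][2], endpt[[2]][1])
      arc <- seq(-pi / 2, pi / 2, by = wall_spacing / hw)
      cand[[length(cand) + 1L]] <-
        cbind(endpt[[1]][1] + hw * cos(ang0 + arc),
              endpt[[1]][2] + hw * sin(ang0 + arc))
    }
  }
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(round(cand / 1e-9)), , drop = FALSE]
  d <- channelDistance(cand, network)$distance
  cand[abs(d - hw) <= tol, , drop = FALSE]
}

#' Wall force by explicit wall-particle summation
#'
#' Reference implementation of the wall interaction: sums WCA pair forces
#' over all wall particles within the cutoff of each position.
#'
#' @param positions n x 2 matrix of positions (m).
#' @param wall_particles Matrix (m x 2) from [explicitWallParticles()].
#' @param sigma Particle diameter (m).
#' @param eps Interaction energy (J).
#' @return n x 2 matrix of forces (N).
#' @export
wallForceExplicit <- function(positions, wall_particles, sigma = 1e-7,
                              eps = interactionEnergy(310)) {
  pts <- .asPointMatrix(positions, 2L)
  wp <- .asPointMatrix(wall_particles, 2L)
  cut <- wcaCutoff(sigma)
  out <- matrix(0, nrow(pts), 2L)
  for (i in seq_len(nrow(pts))) {
    dx <- pts[i, 1] - wp[, 1]
    dy <- pts[i, 2] - wp[, 2]
    r2 <- dx^2 + dy^2
    sel <- r2 < cut^2 & r2 > 0
    if (!any(sel)) next
    r <- sqrt(r2[sel])
    r <- pmax(r, 0.5 * sigma)   # same divergence cap as the implicit model
    mag <- wcaForceMagnitude(r, sigma, eps)
    out[i, ] <- c(sum(mag * dx[sel] / r), sum(mag * dy[sel] / r))
  }
  out
}

#' Sample uniform initial particle positions
#'
#' Positions are uniform over the disk of radius `R_0` centred on the target,
#' intersected with the channel interior when a network is given (rejection
#' sampling).
#'
#' @param N_p Number of particles.
#' @param R_0 Radius of the initial distribution (m).
#' @param network Optional [buildChannelGeometry()] network.
#' @param max_tries Rejection-sampling cap; an acceptance rate below
#'   `N_p / max_tries` aborts with a geometry-mismatch error.
#' @return N_p x 2 matrix of positions (m).
#' @export
sampleInitialPositions <- function(N_p, R_0 = 0.01, network = NULL,
                                   max_tries = 1e6) {
  stopifnot(N_p >= 0, R_0 > 0)
  if (N_p == 0) return(matrix(numeric(0), 0L, 2L))
  out <- matrix(NA_real_, N_p, 2L)
  got <- 0L
  tries <- 0L
  batch <- max(1000L, N_p)
  while (got < N_p) {
    if (tries >= max_tries)
      stop("rejection sampling failed: allowed region appears to have ",
           "vanishing area within the disk")
    r <- R_0 * sqrt(runif(batch))
    th <- runif(batch, 0, 2 * pi)
    cand <- cbind(r * cos(th), r * sin(th))
    ok <- if (is.null(network)) rep(TRUE, batch) else
      channelContains(cand, network)
    take <- min(sum(ok), N_p - got)
    if (take > 0)
      out[got + seq_len(take), ] <- cand[which(ok)[seq_len(take)], ]
    got <- got + take
    tries <- tries + batch
  }
  out
}
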