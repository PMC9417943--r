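# Independent oracles used across the test files.  These deliberately avoid
# the package's own code paths wherever they check one.

# Exact on-axis pressure of the attenuated focused-cap integral: substituting
# u = distance reduces the surface integral to a 1-D integral of exp((ik-a)u)
# with a closed-form antiderivative.
onAxisPressureOracle <- function(z, roc = 0.2, aperture = 0.2,
                                 k = 2 * pi * 1e6 / 1500, atten = 5 * log(10)) {
  thmax <- asin(aperture / (2 * roc))
  g <- complex(imaginary = k) - atten
  vapply(z, function(zz) {
    d0 <- zz + roc                                   # apex distance
    dm <- sqrt(roc^2 + zz^2 + 2 * zz * roc * cos(thmax))
    if (abs(zz) < 1e-12) {
      2 * pi * roc^2 * (1 - cos(thmax)) * exp(g * roc) / roc
    } else {
      (2 * pi * roc / zz) * (exp(g * d0) - exp(g * dm)) / g
    }
  }, complex(1))
}

# Brute-force O(N^2) neighbour enumeration.
brutePairs <- function(positions, cutoff) {
  n <- nrow(positions)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d2 <- sum((positions[i, ] - positions[j, ])^2)
    if (d2 < cutoff^2) out[[length(out) + 1L]] <- c(i, j)
  }
  if (length(out) == 0L)
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  pr <- do.call(rbind, out)
  colnames(pr) <- c("i", "j")
  pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
}

# Brute-force minimum point-to-segment distance (chunk-vectorized).
bruteChannelDist <- function(points, segs) {
  n <- nrow(points)
  out <- numeric(n)
  x1 <- segs[, 1]; y1 <- segs[, 2]
  vx <- segs[, 3] - x1; vy <- segs[, 4] - y1
  L2 <- pmax(vx^2 + vy^2, .Machine$double.xmin)
  for (i in seq_len(n)) {
    t <- pmin(pmax(((points[i, 1] - x1) * vx + (points[i, 2] - y1) * vy) / L2,
                   0), 1)
    dx <- points[i, 1] - (x1 + t * vx)
    dy <- points[i, 2] - (y1 + t * vy)
    out[i] <- sqrt(min(dx^2 + dy^2))
  }
  out
}

# Fixed-step RK4 integration of ds/dt = v_phi R_f / (pi R_0 r(s)) with
# r(s) = R_f + R_0 (1 - s): an ODE oracle for the trajectory parameter.
rk4TrajectoryParameter <- function(t_end, R_f, R_0, v_phi, nstep = 20000L) {
  f <- function(s) v_phi * R_f / (pi * R_0 * (R_f + R_0 * (1 - s)))
  h <- t_end / nstep
  s <- 0
  for (i in seq_len(nstep)) {
    k1 <- f(s); k2 <- f(s + h * k1 / 2)
    k3 <- f(s + h * k2 / 2); k4 <- f(s + h * k3)
    s <- s + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  s
}

# Two-stage grid search for the Gaussian-surrogate widths (centre pinned),
# minimizing the sum of squares.
gridSearchSurrogate <- function(pts, I, center, b1_range, b2_range) {
  ssq <- function(b1, b2) {
    model <- exp(-((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2) / b1^2 -
                 (pts[, 3] - center[3])^2 / b2^2)
    sum((model - I)^2)
  }
  best <- c(NA, NA); bval <- Inf
  for (stage in 1:2) {
    b1s <- seq(b1_range[1], b1_range[2], length.out = 41L)
    b2s <- seq(b2_range[1], b2_range[2], length.out = 41L)
    for (b1 in b1s) for (b2 in b2s) {
      v <- ssq(b1, b2)
      if (v < bval) { bval <- v; best <- c(b1, b2) }
    }
    st1 <- diff(b1s[1:2]); st2 <- diff(b2s[1:2])
    b1_range <- best[1] + c(-1.5, 1.5) * st1
    b2_range <- best[2] + c(-1.5, 1.5) * st2
  }
  best
}

# Paper-scale default parameters used by several tests.
paperPlan <- function(...) spiralPlan(...)
paperParams <- function(...) particleParams(...)
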