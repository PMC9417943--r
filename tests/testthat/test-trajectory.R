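# Spiral focus trajectory and the co-rotating magnetic field.

plan <- spiralPlan()

test_that("tangential speed calibration reproduces the run duration", {
  expect_equal(tangentialSpeedForDuration(0.7927e-3, 0.01, 600) * 1e3,
               0.391, tolerance = 1e-3)
  # degenerate spiral: only the final circle remains
  expect_equal(tangentialSpeedForDuration(2e-3, 0, 100), 2 * pi * 2e-3 / 100)
  expect_error(tangentialSpeedForDuration(-1e-3, 0.01, 600))
  # quadrature oracle: integrating the tangential speed r |dphi/dt| over the
  # whole run with the calibrated v_phi reproduces t_s; the full speed
  # |dr/dt| exceeds v_phi only by the small radial component, so the total
  # arc length overshoots by well under 1%
  for (R_f in c(0.7927e-3, 2e-3)) {
    p <- spiralPlan(R_f = R_f, R_0 = 0.008, t_s = 400)
    tg <- seq(0, p$t_s, length.out = 40001L)
    pos <- focusPosition(tg, p)
    r_mid <- (focusRadius(tg[-1], p) + focusRadius(tg[-length(tg)], p)) / 2
    dphi <- abs(diff(spiralPhase(tg, p)))
    tang_arc <- sum(r_mid * dphi)
    expect_lt(abs(tang_arc / p$v_phi - p$t_s) / p$t_s, 1e-3)
    arc <- sum(sqrt(rowSums(diff(pos)^2)))
    expect_gte(arc / p$v_phi, p$t_s * (1 - 1e-6))
    expect_lt(arc / p$v_phi, p$t_s * 1.01)
  }
})

test_that("phase times satisfy their closed forms and sum to t_s", {
  pt <- phaseTimes(plan)
  expect_equal(sum(pt), 600, tolerance = 1e-12)
  expect_equal(unname(pt["t2"]), 2 * pi * 0.7927e-3 / plan$v_phi,
               tolerance = 1e-12)
  expect_equal(unname(pt["t2"]), 12.74, tolerance = 1e-3)
  expect_equal(unname(pt["t1"]), 587.3, tolerance = 1e-3)
})

test_that("trajectory parameter runs 0 -> 1 and matches an RK4 ODE oracle", {
  expect_equal(trajectoryParameter(0, plan), 0)
  expect_equal(trajectoryParameter(plan$t1, plan), 1, tolerance = 1e-12)
  tg <- seq(0, plan$t1, length.out = 200L)
  s <- trajectoryParameter(tg, plan)
  expect_true(all(diff(s) > 0))
  s_oracle <- rk4TrajectoryParameter(plan$t1 / 2, plan$R_f, plan$R_0,
                                     plan$v_phi)
  expect_lt(abs(trajectoryParameter(plan$t1 / 2, plan) - s_oracle), 1e-6)
  expect_error(trajectoryParameter(plan$t1 * 1.01, plan), "spiral phase")
})

test_that("spiral phase is continuous at t1 and spaces revolutions by 2 R_f", {
  expect_equal(spiralPhase(0, plan), 0)
  expect_equal(spiralPhase(plan$t1, plan), pi * plan$R_0 / plan$R_f,
               tolerance = 1e-9)
  eps <- 1e-9
  expect_lt(abs(spiralPhase(plan$t1 + eps, plan) -
                spiralPhase(plan$t1 - eps, plan)), 1e-6)
  # successive crossings of a fixed ray differ radially by the focus diameter
  phi_target <- 2 * 2 * pi
  t_for_phase <- function(ph) {
    s <- ph * plan$R_f / (pi * plan$R_0)
    r <- plan$R_f + plan$R_0 * (1 - s)
    pi * ((plan$R_f + plan$R_0)^2 - r^2) / (2 * plan$v_phi * plan$R_f)
  }
  r1 <- focusRadius(t_for_phase(phi_target), plan)
  r2 <- focusRadius(t_for_phase(phi_target + 2 * pi), plan)
  expect_equal(r1 - r2, 2 * plan$R_f, tolerance = 1e-9)
})

test_that("focus position respects the spiral, the orbit, and continuity", {
  p0 <- focusPosition(0, plan)
  expect_equal(sqrt(sum(p0^2)), plan$R_f + plan$R_0, tolerance = 1e-12)
  p1 <- focusPosition(plan$t1, plan)
  expect_equal(sqrt(sum(p1^2)), plan$R_f, tolerance = 1e-9)
  t_orbit <- seq(plan$t1, plan$t_s, length.out = 50L)
  r_orbit <- sqrt(rowSums(focusPosition(t_orbit, plan)^2))
  expect_true(all(abs(r_orbit - plan$R_f) < 1e-12))
  eps <- 1e-8
  jump <- sqrt(sum((focusPosition(plan$t1 + eps, plan) -
                    focusPosition(plan$t1 - eps, plan))^2))
  expect_lt(jump, 1e-9)
  # constant speed along the spiral: the tangential component is v_phi by
  # construction; the radial drift R_f v_phi / (pi r) lifts the full speed
  # above v_phi by (1/2)(R_f/(pi r))^2, which stays below 1% until the last
  # couple of revolutions (r < ~2.2 R_f) and below 5% everywhere
  tg <- seq(1, plan$t1 - 1, length.out = 2000L)
  pos <- focusPosition(tg, plan)
  sp <- sqrt(rowSums(diff(pos)^2)) / diff(tg)
  r_mid <- focusRadius((tg[-1] + tg[-length(tg)]) / 2, plan)
  bulk <- r_mid >= 3 * plan$R_f
  expect_lt(max(abs(sp[bulk] - plan$v_phi)) / plan$v_phi, 0.01)
  expect_lt(max(abs(sp - plan$v_phi)) / plan$v_phi, 0.05)
  expect_true(all(sp >= plan$v_phi * (1 - 1e-6)))
})

test_that("x-z plans stretch the orbit into an ellipse with aspect chi", {
  pz <- spiralPlan(plane = "xz")
  t_orbit <- seq(pz$t1, pz$t_s, length.out = 100L)
  pos <- focusPosition(t_orbit, pz)
  ell <- (pos[, 1] / pz$R_f)^2 + (pos[, 2] / (pz$chi * pz$R_f))^2
  expect_true(all(abs(ell - 1) < 1e-9))
  # continuity holds in the stretched plane too
  eps <- 1e-8
  jump <- sqrt(sum((focusPosition(pz$t1 + eps, pz) -
                    focusPosition(pz$t1 - eps, pz))^2))
  expect_lt(jump, 1e-9)
})

test_that("magnetic field points focus -> target at constant magnitude", {
  fld <- magneticFlux(c(0, 100, 300, plan$t1, 595), plan, B = 1e-3)
  expect_true(all(abs(sqrt(rowSums(fld$direction^2)) - 1) < 1e-12))
  pos <- focusPosition(c(0, 100, 300, plan$t1, 595), plan)
  align <- rowSums(fld$direction * (-pos / sqrt(rowSums(pos^2))))
  expect_true(all(abs(align - 1) < 1e-12))
  # single-point convention: focus on +x axis gives a field along -x
  tt <- 0
  expect_equal(unname(magneticFlux(tt, plan)$direction[1, ]), c(-1, 0))
  # the field rotates slower than 0.1 Hz throughout the run
  tg <- seq(0, plan$t_s, length.out = 5000L)
  ang <- magneticFlux(tg, plan)$angle
  dang <- abs(((diff(ang) + pi) %% (2 * pi)) - pi)
  expect_lt(max(dang / diff(tg)), 2 * pi * 0.1)
})
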