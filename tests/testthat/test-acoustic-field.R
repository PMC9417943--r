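# Focused-field module: cap discretization, Rayleigh-Sommerfeld pressures,
# FWHM measurement, Gaussian surrogate, energy conversions.

med <- acousticMedium()
tr <- transducer()

test_that("cap discretization conserves the analytic area and respects mesh size", {
  for (mesh in c(2e-3, 5e-4, 2.5e-4)) {
    patches <- discretizeCap(tr, mesh)
    expect_lt(abs(sum(patches[, "area"]) - capArea(tr)) / capArea(tr), 1e-3)
  }
  expect_error(transducer(aperture_diameter = 0.5, radius_of_curvature = 0.2),
               "aperture")
  expect_error(discretizeCap(tr, -1), "positive")
})

test_that("on-axis pressures match the closed-form oracle", {
  z <- c(-4e-3, -1e-3, 0, 1.5e-3, 5e-3)
  p <- pressureAmplitude(cbind(0, 0, z), tr, med)
  po <- onAxisPressureOracle(z)
  expect_lt(max(Mod(p - po) / Mod(po)), 1e-4)
})

test_that("pressure field is symmetric under in-plane inversion", {
  zf <- -0.6e-3
  pts <- rbind(c(1e-3, 0.5e-3, zf), c(-1e-3, -0.5e-3, zf),
               c(0.3e-3, -0.2e-3, zf), c(-0.3e-3, 0.2e-3, zf))
  p <- pressureAmplitude(pts, tr, med, mesh_spacing = wavelength(med) / 6)
  expect_lt(Mod(p[1] - p[2]) / Mod(p[1]), 1e-6)
  expect_lt(Mod(p[3] - p[4]) / Mod(p[3]), 1e-6)
})

test_that("degenerate evaluation points and coarse meshes are rejected", {
  on_cap <- c(0, 0, -tr$radius_of_curvature)
  expect_error(pressureAmplitude(on_cap, tr, med), "degenerate")
  expect_error(pressureAmplitude(c(0, 0, 0), tr, med,
                                 mesh_spacing = wavelength(med) / 3),
               "mesh_spacing")
})

test_that("normalization maps the maximum to one and drops the prefactor", {
  pts <- cbind(seq(-2e-3, 2e-3, by = 5e-4), 0, -0.6e-3)
  p <- pressureAmplitude(pts, tr, med)
  prof <- normalizedIntensity(p, pts)
  expect_equal(max(prof$normalized_intensity), 1)
  expect_true(all(prof$normalized_intensity >= 0))
  prof2 <- normalizedIntensity(3.7 * p, pts)     # rho * u prefactor change
  expect_equal(prof$normalized_intensity, prof2$normalized_intensity)
  expect_error(normalizedIntensity(complex(5), matrix(0, 5, 3)), "all-zero")
})

test_that("fwhm recovers closed-form widths", {
  x <- seq(-5, 5, by = 0.01)
  b <- 1.3
  expect_lt(abs(fwhm(x, exp(-x^2 / b^2)) - 2 * b * sqrt(log(2))) /
            (2 * b * sqrt(log(2))), 1e-3)
  tri <- pmax(1 - abs(x), 0)
  expect_equal(fwhm(x, tri), 1.0, tolerance = 1e-10)
  expect_error(fwhm(x[x < 0.2], exp(-x[x < 0.2]^2 / 4)), "flanks")
})

test_that("focal intensity maximum sits where the closed form puts it", {
  zf <- findFocus(tr, med)
  oracle <- optimize(function(z) -Mod(onAxisPressureOracle(z))^2,
                     interval = c(-5e-3, 3e-3))$minimum
  expect_lt(abs(zf - oracle), 1e-4)          # within 0.1 mm
  expect_lt(zf, 0)                           # attenuation pulls it backwards
})

test_that("FWHM estimates are mesh-converged and have the spheroidal ratio", {
  zf <- findFocus(tr, med)
  lat6 <- fwhm(seq(-2e-3, 2e-3, by = 2e-5),
               focalScan(tr, med, "lateral", center = c(0, 0, zf),
                         extent = 2e-3, step = 2e-5)$intensity)
  lat12 <- fwhm(seq(-2e-3, 2e-3, by = 2e-5),
                focalScan(tr, med, "lateral", center = c(0, 0, zf),
                          extent = 2e-3, step = 2e-5,
                          mesh_spacing = wavelength(med) / 12)$intensity)
  expect_lt(abs(lat6 - lat12) / lat12, 0.005)
  ax <- fwhm(seq(-9e-3, 9e-3, by = 1e-4),
             focalScan(tr, med, "axial", center = c(0, 0, zf),
                       extent = 9e-3, step = 1e-4)$intensity)
  expect_gt(ax / lat6, 6.0)
  expect_lt(ax / lat6, 6.8)
})

test_that("gaussian surrogate evaluates to its closed form", {
  gf <- gaussianFocus(2e-3, 12e-3, c(0, 0, 0))
  expect_equal(gaussianIntensity(c(0, 0, 0), gf), 1)
  expect_equal(gaussianIntensity(c(2e-3, 0, 0), gf), exp(-1))
  expect_equal(gaussianIntensity(c(0, 0, 12e-3), gf), exp(-1))
  # ellipsoidal level sets: lateral offset b_xy and axial offset b_z match
  expect_equal(gaussianIntensity(c(2e-3, 0, 0), gf),
               gaussianIntensity(c(0, 0, 12e-3), gf))
  expect_error(gaussianFocus(b_xy = 2e-3, b_z = 1e-3), "b_z")
})

test_that("surrogate fit inverts gaussianIntensity and matches a grid search", {
  # centre chosen on the sample grid so the profile maximum is exactly 1
  gf <- gaussianFocus(2e-3, 12e-3, c(3e-4, 0, 1e-3))
  pts <- as.matrix(expand.grid(x = seq(-3e-3, 3e-3, by = 3e-4), y = 0,
                               z = seq(-20e-3, 20e-3, by = 1e-3)))
  I <- gaussianIntensity(pts, gf)
  prof <- normalizedIntensity(complex(modulus = sqrt(I)), pts)
  fit <- fitGaussianSurrogate(prof)
  expect_lt(abs(fit$b_xy - 2e-3) / 2e-3, 1e-3)
  expect_lt(abs(fit$b_z - 12e-3) / 12e-3, 1e-3)
  gs <- gridSearchSurrogate(pts, I, gf$center,
                            c(1e-3, 3e-3), c(8e-3, 16e-3))
  expect_lt(abs(gs[1] - 2e-3) / 2e-3, 0.01)
  expect_lt(abs(gs[2] - 12e-3) / 12e-3, 0.01)
  expect_lt(abs(fit$b_xy - gs[1]) / gs[1], 0.01)
  expect_lt(abs(fit$b_z - gs[2]) / gs[2], 0.01)
})

test_that("energy-density conversions follow their closed forms", {
  expect_equal(energyDensityFromIntensity(7200, 1500), 4.8)
  expect_equal(energyDensityFromIntensity(0, 1500), 0)
  expect_equal(energyDensityFromIntensity(1500, 1500), 1)
  expect_equal(dutyCycleRescale(2.20, 0.04), 55)
  expect_equal(dutyCycleRescale(3.3, 1), 3.3)
  expect_equal(dutyCycleRescale(1.0, 0.5), 2.0)
  expect_error(dutyCycleRescale(1, 0), "duty_cycle")
  expect_error(dutyCycleRescale(1, 1.2), "duty_cycle")
})
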