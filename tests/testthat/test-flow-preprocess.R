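test_that("Mosteller BSA matches its closed form", {
  expect_equal(bsaMosteller(170, 72), sqrt(170 * 72 / 3600), tolerance = 1e-12)
  expect_equal(bsaMosteller(60, 60), 1.0)
  expect_equal(bsaMosteller(180, 80), 2.0)
  expect_error(bsaMosteller(0, 70), "positive")
})

test_that("wrap-then-unwrap recovers smooth traces beyond VENC", {
  spec <- flowPhantomSpec("uniform_pipe", c(16, 16, 16), 2.4, 15, 33.3, 3:13,
                          params = list(speed = 170, radius = 1.2),
                          venc = 150, envelope = "smooth")
  f <- generateFlowPhantom(spec)
  expect_gt(max(velocityValues(f)), 150)  # genuinely aliased
  u <- unwrapVelocity(wrapVelocity(f))
  expect_lt(max(abs(velocityValues(u) - velocityValues(f))), 1e-9)
  # never-aliased trace is untouched
  spec2 <- flowPhantomSpec("uniform_pipe", c(12, 12, 12), 2.4, 10, 33.3, 2:9,
                           params = list(speed = 140, radius = 1.2),
                           venc = 150, envelope = "smooth")
  f2 <- generateFlowPhantom(spec2)
  u2 <- unwrapVelocity(wrapVelocity(f2))
  expect_equal(velocityValues(u2), velocityValues(f2), tolerance = 1e-12)
  # all-zero field unchanged
  z <- constantField(c(0, 0, 0), nFrames = 5)
  expect_identical(velocityValues(unwrapVelocity(z)), velocityValues(z))
})

test_that("unwrap warns and returns single-frame fields unchanged", {
  f1 <- constantField(c(120, 0, 0), nFrames = 1)
  expect_warning(u1 <- unwrapVelocity(f1), "fewer than 3 frames")
  expect_identical(velocityValues(u1), velocityValues(f1))
})

test_that("background phase correction recovers polynomial offsets exactly", {
  spec <- flowPhantomSpec("rigid_rotation", c(16, 16, 16), 2.4, 3, 38.8, 1:3,
                          params = list(omega = 5, support_radius = 1.2))
  f <- generateFlowPhantom(spec)
  co <- vortexatlas:::.coordArrays(c(16, 16, 16), rep(2.4, 3))
  dist <- voxelDistances(c(16, 16, 16), rep(2.4, 3), (c(16, 16, 16) - 1) / 2 * 2.4)
  mask <- array(dist / 10 > 1.3, dim = c(16, 16, 16))
  vals <- velocityValues(f)
  for (t in 1:3) vals[, , , 1, t] <- vals[, , , 1, t] + 2 + 0.1 * co$x
  off <- methods::initialize(f, values = vals)
  corr <- correctBackgroundPhase(off, mask, order = 1)
  expect_lt(mean(abs(velocityValues(corr)[, , , 1, 1][mask])), 1e-6)
  expect_lt(max(abs(velocityValues(corr) - velocityValues(f))), 1e-9)
  # offset-free field is a fixed point
  same <- correctBackgroundPhase(f, mask, order = 1)
  expect_lt(max(abs(velocityValues(same) - velocityValues(f))), 1e-9)
  # order 0 removes a constant exactly
  vals0 <- velocityValues(f)
  for (t in 1:3) vals0[, , , 2, t] <- vals0[, , , 2, t] + 7
  corr0 <- correctBackgroundPhase(methods::initialize(f, values = vals0), mask, order = 0)
  expect_lt(max(abs(velocityValues(corr0) - velocityValues(f))), 1e-9)
  # mask smaller than the number of polynomial terms
  tiny <- array(FALSE, dim = c(16, 16, 16)); tiny[1:2] <- TRUE
  expect_error(correctBackgroundPhase(f, tiny, order = 1), "fewer than")
  expect_error(correctBackgroundPhase(f, array(FALSE, dim = c(16, 16, 16))), "empty")
})

test_that("denoising honors the grid contract and reduces noise", {
  specN <- flowPhantomSpec("rigid_rotation", c(20, 20, 20), 2.4, 2, 38.8, 1:2,
                           params = list(omega = 5, support_radius = 1.6),
                           noise_sd = 10, seed = 5)
  clean <- generateFlowPhantom(flowPhantomSpec("rigid_rotation", c(20, 20, 20), 2.4,
                                               2, 38.8, 1:2,
                                               params = list(omega = 5, support_radius = 1.6)))
  noisy <- generateFlowPhantom(specN)
  expect_identical(denoiseVelocity(noisy, "none"), noisy)
  den <- denoiseVelocity(noisy, "gaussian", sd = 1)
  expect_identical(dim(velocityValues(den)), dim(velocityValues(noisy)))
  expect_identical(voxelSpacing(den), voxelSpacing(noisy))
  rmse <- function(a, b) sqrt(mean((velocityValues(a) - velocityValues(b))^2))
  expect_lt(rmse(den, clean), rmse(noisy, clean))
  expect_error(denoiseVelocity(noisy, "median"), "arg")
})

test_that("gaussian smoothing preserves linear fields away from boundaries", {
  spec <- flowPhantomSpec("rigid_rotation", c(16, 16, 16), 2.4, 1, 38.8, 1,
                          params = list(omega = 5, support_radius = 100))
  f <- generateFlowPhantom(spec)  # globally linear velocity
  den <- denoiseVelocity(f, "gaussian", sd = 1)
  inner <- 6:11  # > 4 sd voxels from every boundary
  expect_lt(max(abs(velocityValues(den)[inner, inner, inner, , 1] -
                      velocityValues(f)[inner, inner, inner, , 1])), 1e-6)
})

test_that("pipe flux integration matches the closed form and its symmetries", {
  spec <- flowPhantomSpec("uniform_pipe", c(32, 32, 32), 2.0, 15, 33.3, 1:15,
                          params = list(speed = 100, radius = 1.6))
  f <- generateFlowPhantom(spec)
  ctr <- (c(32, 32, 32) - 1) / 2 * 2.0
  pl <- valvePlane(ctr, c(0, 0, 1), radius = 10)
  vols <- computeTransvalvularVolumes(f, pl, bsa = 2.0)
  expected <- 100 * pi * 1^2 * (15 * 33.3 / 1000)  # U * A(cm^2) * T(s) in mL
  expect_lt(abs(vols$forward_volume - expected) / expected, 0.02)
  expect_equal(vols$reverse_volume, 0)
  expect_equal(vols$net_volume, vols$forward_volume)
  # reversing the plane normal swaps forward and reverse exactly
  flip <- computeTransvalvularVolumes(f, valvePlane(ctr, c(0, 0, -1), 10), bsa = 2.0)
  expect_equal(flip$reverse_volume, vols$forward_volume, tolerance = 1e-12)
  expect_equal(flip$forward_volume, vols$reverse_volume, tolerance = 1e-12)
  expect_equal(flip$prvi, flip$reverse_volume / 2.0)
  # zero field: all volumes zero
  z <- constantField(c(0, 0, 0), dims = c(16, 16, 16), nFrames = 3)
  zv <- computeTransvalvularVolumes(z, valvePlane(c(18, 18, 18), c(0, 0, 1), 6), bsa = 2)
  expect_equal(zv$forward_volume, 0)
  expect_true(is.na(zv$regurgitant_fraction))
  # raster refinement changes the result by < 0.5%
  fine <- computeTransvalvularVolumes(f, pl, bsa = 2.0, pitch_frac = 0.125)
  expect_lt(abs(fine$forward_volume - vols$forward_volume) / vols$forward_volume, 0.005)
  # aperture outside the grid
  expect_error(computeTransvalvularVolumes(f, valvePlane(c(0, 0, 0), c(0, 0, 1), 20), 2),
               "outside the grid")
})

test_that("regurgitant fraction is invariant to uniform time rescaling", {
  spec <- flowPhantomSpec("uniform_pipe", c(20, 20, 20), 2.4, 8, 40, 1:8,
                          params = list(speed = 80, radius = 1.4))
  f <- generateFlowPhantom(spec)
  vals <- velocityValues(f)
  vals[, , , 3, 6:8] <- -0.5 * vals[, , , 3, 6:8]  # reversed flow in late frames
  f <- methods::initialize(f, values = vals)
  ctr <- (c(20, 20, 20) - 1) / 2 * 2.4
  pl <- valvePlane(ctr, c(0, 0, 1), 8)
  a <- computeTransvalvularVolumes(f, pl, bsa = 1.8)
  b <- computeTransvalvularVolumes(methods::initialize(f, frameDuration = 80), pl, bsa = 1.8)
  expect_gt(a$reverse_volume, 0)
  expect_equal(a$regurgitant_fraction, b$regurgitant_fraction, tolerance = 1e-12)
  expect_equal(b$forward_volume, 2 * a$forward_volume, tolerance = 1e-12)
})

test_that("preprocessing chain preserves grid geometry end to end", {
  spec <- flowPhantomSpec("lamb_oseen", c(14, 14, 14), 2.4, 5, 38.8, 2:4,
                          params = list(gamma = 80, r_c = 1, support_radius = 1.2),
                          noise_sd = 2, seed = 8)
  f <- generateFlowPhantom(spec)
  dist <- voxelDistances(c(14, 14, 14), rep(2.4, 3), (c(14, 14, 14) - 1) / 2 * 2.4)
  mask <- array(dist / 10 > 1.3, dim = c(14, 14, 14))
  g <- denoiseVelocity(correctBackgroundPhase(unwrapVelocity(wrapVelocity(f)), mask, 1),
                       "gaussian", 1)
  expect_identical(dim(velocityValues(g)), dim(velocityValues(f)))
  expect_identical(voxelSpacing(g), voxelSpacing(f))
  expect_identical(nFrames(g), nFrames(f))
  expect_identical(diastoleFrames(g), diastoleFrames(f))
})
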