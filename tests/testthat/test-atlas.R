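test_that("generalized Procrustes removes pose exactly and ES inherits ED transforms", {
  tpl <- getTemplate(80)
  set.seed(11)
  shapes <- lapply(1:6, function(i)
    poseShape(tpl, vortexatlas:::.randomRotation(40), runif(3, -25, 25)))
  gpa <- generalizedProcrustesAlign(shapes)
  eds <- lapply(gpa$shapes, shapePoints, phase = "ED")
  ess <- lapply(gpa$shapes, shapePoints, phase = "ES")
  for (i in 2:6) {
    expect_lt(sqrt(mean((eds[[i]] - eds[[1]])^2)), 1e-8)
    expect_lt(sqrt(mean((ess[[i]] - ess[[1]])^2)), 1e-8)
  }
  # ES inherited the ED transform verbatim
  for (i in 1:6) {
    tr <- gpa$transforms[[i]]
    expect_equal(ess[[i]],
                 sweep(shapePoints(shapes[[i]], "ES") %*% t(tr$R), 2, tr$t, `+`),
                 tolerance = 1e-12)
  }
})

test_that("already-aligned populations get identity transforms", {
  tpl <- getTemplate(80)
  spec <- populationSpec(tpl, 4, mode_variances = c(1e-6, 1e-7, 1e-7, 1e-8),
                         noise_sd = 0, pose_jitter_deg = 0, pose_jitter_mm = 0,
                         seed = 3)
  pop <- generateShapePopulation(spec)
  gpa <- generalizedProcrustesAlign(pop$shapes)
  # rotations are identity; the common translation (centering) is shared
  t0 <- gpa$transforms[[1]]$t
  for (tr in gpa$transforms) {
    expect_lt(max(abs(tr$R - diag(3))), 1e-6)
    expect_lt(max(abs(tr$t - t0)), 1e-4)
    expect_equal(det(tr$R), 1, tolerance = 1e-12)
  }
})

test_that("alignment never applies a reflection even when one fits better", {
  tpl <- getTemplate(80)
  mirror <- methods::new("BiventricularShape",
                         pointsED = shapePoints(tpl, "ED") %*% diag(c(-1, 1, 1)),
                         pointsES = shapePoints(tpl, "ES") %*% diag(c(-1, 1, 1)),
                         labels = pointLabels(tpl), faces = shapeFaces(tpl))
  gpa <- generalizedProcrustesAlign(list(tpl, tpl, mirror))
  for (tr in gpa$transforms) expect_equal(det(tr$R), 1, tolerance = 1e-10)
  # oracle: unconstrained least-squares alignment of the mirrored shape picks a
  # reflection (det -1) with a smaller residual than any rotation
  A <- shapePoints(mirror, "ED"); B <- shapePoints(tpl, "ED")
  H <- crossprod(sweep(A, 2, colMeans(A)), sweep(B, 2, colMeans(B)))
  s <- svd(H)
  expect_lt(det(s$v %*% t(s$u)), 0)
  resid <- sqrt(mean((shapePoints(gpa$shapes[[3]], "ED") -
                        shapePoints(gpa$shapes[[1]], "ED"))^2))
  expect_gt(resid, 1)  # rotation alone cannot undo the mirroring
})

test_that("atlas recovers a planted mode plane exactly in the noiseless case", {
  tpl <- getTemplate(80)
  D <- defaultModeDisplacements(tpl)[, 1:2]
  spec <- populationSpec(tpl, 50, mode_displacements = D, mode_variances = c(9, 4),
                         noise_sd = 0, pose_jitter_deg = 0, pose_jitter_mm = 0,
                         seed = 2)
  pop <- generateShapePopulation(spec)
  atlas <- buildShapeAtlas(pop$shapes)
  ang <- vortexatlas:::.principalAngles(D, atlasModes(atlas)[, 1:2])
  expect_lt(max(ang), 0.5)
  expect_lt(max(atlasVariances(atlas)[-(1:2)]), 1e-10)
  # trace identity: total variance equals the sum of coordinate variances
  X <- do.call(rbind, lapply(pop$shapes, shapeToVector))
  expect_equal(sum(atlasVariances(atlas)), sum(apply(X, 2, var)), tolerance = 1e-8)
})

test_that("a population of identical shapes has zero variance", {
  tpl <- getTemplate(80)
  atlas <- buildShapeAtlas(list(tpl, tpl, tpl))
  expect_lt(max(atlasVariances(atlas)), 1e-12)
  expect_error(buildShapeAtlas(list(tpl, tpl)), "at least 3")
})

test_that("mode count selection applies the cumulative variance rule", {
  P <- 2L
  atl <- methods::new("ShapeAtlas", meanShape = numeric(12),
                      modes = diag(12)[, 1:4], variances = c(9, 4, 1, 0),
                      nModesRetained = 4L, P = P,
                      labels = rep("LV_endo", P), faces = list())
  expect_equal(selectModeCount(atl, 0.9), 2)   # 13/14 = 0.929
  expect_equal(selectModeCount(atl, 1.0), 3)   # nonzero variances
  expect_equal(selectModeCount(atl), selectModeCount(atl, 0.90))
  expect_error(selectModeCount(atl, 1.2), "\\(0, 1]")
  expect_error(nModesRetained(atl) <- 9, "between 1 and")
})

test_that("projection and reconstruction are exact inverses on in-span shapes", {
  tpl <- getTemplate(80)
  spec <- populationSpec(tpl, 40, noise_sd = 0.3, pose_jitter_deg = 0,
                         pose_jitter_mm = 0, seed = 5)
  atlas <- buildShapeAtlas(generateShapePopulation(spec)$shapes)
  nModesRetained(atlas) <- 6L
  # shape = mean + 2 sqrt(lambda_1) phi_1 scores as (2, 0, ...)
  s1 <- reconstructFromScores(c(2), atlas)
  sc1 <- projectToAtlas(s1, atlas, align = FALSE)
  expect_equal(as.numeric(sc1), c(2, rep(0, 5)), tolerance = 1e-8)
  # the mean scores as all zeros
  expect_equal(as.numeric(projectToAtlas(reconstructFromScores(numeric(0), atlas),
                                         atlas, align = FALSE)),
               rep(0, 6), tolerance = 1e-10)
  # random in-span round trip
  set.seed(8)
  z <- rnorm(6)
  sh <- reconstructFromScores(z, atlas)
  z2 <- projectToAtlas(sh, atlas, align = FALSE)
  expect_equal(as.numeric(z2), z, tolerance = 1e-8)
  rt <- reconstructFromScores(z2, atlas)
  err <- pointToPointError(sh, rt)
  expect_lt(err$ed, 1e-8)
  expect_lt(err$es, 1e-8)
  # pose invariance: a rigidly posed copy scores identically under alignment
  posed <- poseShape(sh, vortexatlas:::.randomRotation(30), c(12, -5, 8))
  expect_equal(as.numeric(projectToAtlas(posed, atlas, align = TRUE)),
               as.numeric(projectToAtlas(sh, atlas, align = TRUE)), tolerance = 1e-8)
  expect_error(projectToAtlas(getTemplate(60), atlas), "points")
})

test_that("reconstruction is affine in the scores", {
  tpl <- getTemplate(80)
  spec <- populationSpec(tpl, 30, noise_sd = 0.2, pose_jitter_deg = 0,
                         pose_jitter_mm = 0, seed = 6)
  atlas <- buildShapeAtlas(generateShapePopulation(spec)$shapes)
  a <- c(1, -2, 0.5, 0); b <- c(-0.5, 1, 1, 2)
  lhs <- shapeToVector(reconstructFromScores(a + b, atlas))
  rhs <- shapeToVector(reconstructFromScores(a, atlas)) +
    shapeToVector(reconstructFromScores(b, atlas)) - atlasMean(atlas)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("training scores are SD-normalized under the 1/(n-1) convention", {
  tpl <- getTemplate(80)
  spec <- populationSpec(tpl, 40, noise_sd = 0.1, pose_jitter_deg = 5,
                         pose_jitter_mm = 5, seed = 12)
  pop <- generateShapePopulation(spec)
  gpa <- generalizedProcrustesAlign(pop$shapes)
  atlas <- buildShapeAtlas(gpa$shapes)
  K <- sum(atlasVariances(atlas) > 1e-8 * atlasVariances(atlas)[1])
  sc <- t(vapply(gpa$shapes, function(s) projectToAtlas(s, atlas, K = K, align = FALSE),
                 numeric(K)))
  expect_equal(unname(apply(sc, 2, sd)), rep(1, K), tolerance = 1e-6)
})

test_that("reconstruction error is non-increasing in the mode count", {
  tpl <- getTemplate(80)
  spec <- populationSpec(tpl, 30, noise_sd = 0.5, pose_jitter_deg = 0,
                         pose_jitter_mm = 0, seed = 13)
  pop <- generateShapePopulation(spec)
  atlas <- buildShapeAtlas(pop$shapes)
  target <- pop$shapes[[1]]
  full <- projectToAtlas(target, atlas, K = ncol(atlasModes(atlas)), align = FALSE)
  errs <- vapply(1:12, function(K) {
    rec <- reconstructFromScores(full[seq_len(K)], atlas)
    e <- pointToPointError(target, rec)
    (e$ed + e$es) / 2
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("point-to-point error matches brute-force distance computation", {
  tpl <- getTemplate(80)
  expect_equal(pointToPointError(tpl, tpl), list(ed = 0, es = 0))
  shifted <- poseShape(tpl, diag(3), c(3, 0, 0))
  e <- pointToPointError(tpl, shifted)
  expect_equal(e$ed, 3, tolerance = 1e-12)
  expect_equal(e$es, 3, tolerance = 1e-12)
  set.seed(4)
  noisy <- methods::new("BiventricularShape",
                        pointsED = shapePoints(tpl, "ED") + matrix(rnorm(3 * nPoints(tpl), 0, 0.8), ncol = 3),
                        pointsES = shapePoints(tpl, "ES"),
                        labels = pointLabels(tpl), faces = shapeFaces(tpl))
  brute <- mean(sqrt(rowSums((shapePoints(noisy, "ED") - shapePoints(tpl, "ED"))^2)))
  expect_equal(pointToPointError(tpl, noisy)$ed, brute, tolerance = 1e-12)
})

test_that("atlas variances are invariant under a common rigid motion of the inputs", {
  tpl <- getTemplate(80)
  spec <- populationSpec(tpl, 25, noise_sd = 0.2, pose_jitter_deg = 3,
                         pose_jitter_mm = 3, seed = 14)
  pop <- generateShapePopulation(spec)
  atlas1 <- buildShapeAtlas(generalizedProcrustesAlign(pop$shapes)$shapes)
  R <- vortexatlas:::.rotationMatrix(c(1, 2, 3), 0.7); tsh <- c(30, -12, 5)
  moved <- lapply(pop$shapes, poseShape, R = R, t = tsh)
  atlas2 <- buildShapeAtlas(generalizedProcrustesAlign(moved)$shapes)
  expect_equal(atlasVariances(atlas1), atlasVariances(atlas2), tolerance = 1e-8)
})

test_that("mesh volume matches the sphere closed form and the scaling law", {
  sph <- latLongSphere(radius = 30, nTheta = 60, nPhi = 30)
  v <- enclosedVolume(sph$points, sph$faces)
  expect_lt(abs(v - 4 / 3 * pi * 30^3 / 1000) / (4 / 3 * pi * 30^3 / 1000), 0.01)
  expect_equal(enclosedVolume(2 * sph$points, sph$faces), 8 * v, tolerance = 1e-12)
  expect_error(enclosedVolume(sph$points, sph$faces[-1, ]), "open")
})

test_that("chamber indices follow their defining identities", {
  tpl <- getTemplate(120)
  ci <- chamberVolumeAndMass(tpl, bsa = 2.0)
  expect_equal(ci$sv, ci$edv - ci$esv, tolerance = 1e-12)
  expect_equal(ci$ef, ci$sv / ci$edv, tolerance = 1e-12)
  lvEndo <- enclosedVolume(shapePoints(tpl, "ED"), shapeFaces(tpl)$LV_endo)
  lvEpi <- enclosedVolume(shapePoints(tpl, "ED"), shapeFaces(tpl)$LV_epi)
  expect_equal(ci["LV", "mass"], (lvEpi - lvEndo) * 1.05, tolerance = 1e-12)
  expect_equal(ci$edvi, ci$edv / 2.0, tolerance = 1e-12)
  # ES = ED gives SV = 0, EF = 0
  frozen <- methods::new("BiventricularShape", pointsED = shapePoints(tpl, "ED"),
                         pointsES = shapePoints(tpl, "ED"),
                         labels = pointLabels(tpl), faces = shapeFaces(tpl))
  ci0 <- chamberVolumeAndMass(frozen)
  expect_equal(ci0$sv, c(0, 0))
  expect_equal(ci0$ef, c(0, 0))
  # uniform 2x dilation scales volumes and mass by 8
  big <- methods::new("BiventricularShape", pointsED = 2 * shapePoints(tpl, "ED"),
                      pointsES = 2 * shapePoints(tpl, "ES"),
                      labels = pointLabels(tpl), faces = shapeFaces(tpl))
  cib <- chamberVolumeAndMass(big)
  expect_equal(cib$edv, 8 * ci$edv, tolerance = 1e-12)
  expect_equal(cib$mass, 8 * ci$mass, tolerance = 1e-12)
})
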