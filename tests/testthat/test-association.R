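test_that("univariate associations match hand-computed correlation statistics", {
  set.seed(21)
  n <- 120; K <- 5
  scores <- matrix(rnorm(n * K), n, K)
  v <- 0.5 * scores[, 2] + rnorm(n)
  res <- univariateModeAssociations(scores, v, alpha = 0.05)
  # independent arithmetic oracle
  for (k in 1:K) {
    r <- sum((scores[, k] - mean(scores[, k])) * (v - mean(v))) /
      ((n - 1) * sd(scores[, k]) * sd(v))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(res$table$r[k], r, tolerance = 1e-12)
    expect_equal(res$table$p[k], 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  }
  expect_equal(res$threshold, 0.05 / K)
  expect_equal(res$family_size, K)
  # a variable equal to mode-1 scores: perfect correlation
  perfect <- univariateModeAssociations(scores, scores[, 1])
  expect_equal(perfect$table$r[1], 1, tolerance = 1e-12)
  expect_lt(perfect$table$p[1], 1e-100)
  expect_true(1 %in% perfect$significant_modes)
  expect_error(univariateModeAssociations(scores, rep(2, n)), "zero variance")
})

test_that("associations are invariant to affine rescaling of the variable", {
  set.seed(22)
  scores <- matrix(rnorm(300), 100, 3)
  v <- scores[, 3] + rnorm(100, 0, 2)
  a <- univariateModeAssociations(scores, v)
  b <- univariateModeAssociations(scores, 3.7 * v + 11)
  expect_equal(a$table$r, b$table$r, tolerance = 1e-12)
  expect_equal(a$table$p, b$table$p, tolerance = 1e-12)
  expect_identical(a$significant_modes, b$significant_modes)
})

test_that("a planted single-mode association is flagged reliably after Bonferroni", {
  reps <- 200
  hit3 <- logical(reps); falseFlag <- logical(reps)
  for (r in seq_len(reps)) {
    truth <- makeGroundTruth(500, 10,
                             association_betas = c(0, 0, 0.6, rep(0, 7)),
                             covariate_betas = vortexatlas:::.defaultCovariateBetas(10))
    cv <- generateSubjectCovariates(500, truth, noise_sd = 0.5, seed = 5000 + r)
    res <- univariateModeAssociations(cv$truth$true_scores, cv$covariates$predictor_std)
    hit3[r] <- 3 %in% res$significant_modes
    falseFlag[r] <- length(setdiff(res$significant_modes, 3)) > 0
  }
  expect_gte(mean(hit3), 0.95)
  # expected false-flag rate 1 - (1 - 0.005)^9 ~ 4.4%; allow 3 binomial SEs
  expect_lte(mean(falseFlag), 0.044 + 3 * sqrt(0.044 * 0.956 / reps))
})

test_that("two-group comparison reproduces the pooled-t worked example", {
  g <- compareGroups(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  # equal sizes and variances: Welch equals pooled t = 10 / (1 * sqrt(2/3))
  expect_equal(abs(g$statistic), 10 / sqrt(2 / 3), tolerance = 1e-6)
  expect_lt(g$p, 0.001)
  expect_equal(g$test_used, "t_test")
  expect_equal(g$summaries$mean, c(2, 12))
  expect_error(compareGroups(1:5, c("a", "a", "a", "b", "b")), "at least 3")
})

test_that("the normality gate selects ANOVA or Kruskal-Wallis appropriately", {
  set.seed(23)
  vals <- c(rnorm(50), rnorm(50, 0.3), rnorm(50, -0.2))
  gN <- compareGroups(vals, rep(1:3, each = 50))
  expect_equal(gN$test_used, "anova")
  vals2 <- c(rnorm(50), rnorm(50), rexp(50)^2)  # one strongly non-normal group
  gK <- compareGroups(vals2, rep(1:3, each = 50))
  expect_equal(gK$test_used, "kruskal_wallis")
})

test_that("two-sample p-values are uniform under the null", {
  set.seed(24)
  pvals <- replicate(500, {
    compareGroups(rnorm(400), rep(c("x", "y"), each = 200))$p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("covariate-adjusted regression is calibrated under the null", {
  reps <- 10
  cover <- numeric(reps); maxBeta <- numeric(reps)
  for (r in seq_len(reps)) {
    truth <- makeGroundTruth(500, 10,
                             covariate_betas = vortexatlas:::.defaultCovariateBetas(10))
    cv <- generateSubjectCovariates(500, truth, noise_sd = 0.5, seed = 7000 + r)
    mm <- fitMorphometricMode(cv$truth$true_scores, cv$covariates$predictor_std,
                              cv$covariates[, c("sex", "height", "weight", "age")])
    cover[r] <- mean(mm@betaCI[, 1] <= 0 & mm@betaCI[, 2] >= 0)
    maxBeta[r] <- max(abs(modeBetas(mm)))
  }
  expect_gte(mean(cover), 0.90)
  expect_lt(max(maxBeta), 0.15)
})

test_that("the morphometric mode recovers a planted association and its direction", {
  tpl <- getTemplate(60)
  D <- defaultModeDisplacements(tpl)
  covered <- logical(3); cosines <- numeric(3); estimates <- numeric(3)
  for (r in 1:3) {
    truth <- makeGroundTruth(300, 4, association_betas = c(0, 0, 0.6, 0),
                             covariate_betas = vortexatlas:::.defaultCovariateBetas(4))
    cv <- generateSubjectCovariates(300, truth, noise_sd = 0.5, seed = 800 + r)
    spec <- populationSpec(tpl, 300, mode_displacements = D,
                           noise_sd = 0.1, pose_jitter_deg = 5, pose_jitter_mm = 5,
                           seed = 900 + r)
    pop <- generateShapePopulation(spec, truth = cv$truth)
    gpa <- generalizedProcrustesAlign(pop$shapes)
    atlas <- buildShapeAtlas(gpa$shapes)
    nModesRetained(atlas) <- selectModeCount(atlas, 0.90)
    sc <- t(vapply(gpa$shapes, function(s) projectToAtlas(s, atlas, align = FALSE),
                   numeric(nModesRetained(atlas))))
    mm <- fitMorphometricMode(sc, cv$covariates$predictor_std,
                              cv$covariates[, c("sex", "height", "weight", "age")],
                              atlas)
    disp <- displacementVector(mm)
    cosines[r] <- abs(sum(disp * D[, 3])) / sqrt(sum(disp^2))
    # the planted coefficient appears on whichever atlas mode carries D_3;
    # atlas normalization rescales it by 1/sd(z_3) (scores have unit SD, the
    # planted scores do not)
    carrier <- which.max(abs(crossprod(atlasModes(atlas)[, seq_len(nModesRetained(atlas))], D[, 3])))
    expected <- 0.6 / sd(cv$truth$true_scores[, 3])
    estimates[r] <- abs(modeBetas(mm)[carrier]) / expected
    covered[r] <- (mm@betaCI[carrier, 1] <= expected && mm@betaCI[carrier, 2] >= expected) ||
      (mm@betaCI[carrier, 1] <= -expected && mm@betaCI[carrier, 2] >= -expected)
    # consistency invariant: displacement equals its defining sum bit-for-bit
    K <- nModesRetained(atlas)
    expect_identical(disp,
                     as.numeric(atlasModes(atlas)[, 1:K] %*%
                                  (modeBetas(mm) * sqrt(atlasVariances(atlas)[1:K]))))
  }
  expect_true(all(cosines > 0.95))
  expect_lt(abs(mean(estimates) - 1), 0.15)  # ratio to the rescaled truth
  expect_gte(sum(covered), 2)
})

test_that("rank-deficient designs fail naming the collinear column", {
  set.seed(25)
  scores <- matrix(rnorm(200), 50, 4)
  pred <- rnorm(50)
  covs <- data.frame(sex = rbinom(50, 1, 0.5), height = pred,  # duplicate predictor
                     weight = rnorm(50, 70, 10), age = rnorm(50, 30, 8))
  expect_error(fitMorphometricMode(scores, pred, covs), "collinear.*height")
})

test_that("mode rendering is symmetric about the mean", {
  tpl <- getTemplate(80)
  spec <- populationSpec(tpl, 30, noise_sd = 0.2, pose_jitter_deg = 0,
                         pose_jitter_mm = 0, seed = 31)
  atlas <- buildShapeAtlas(generateShapePopulation(spec)$shapes)
  sh <- renderModeShapes(atlas, 1, alphas = c(-2, 0, 2))
  expect_equal(shapeToVector(sh[["alpha_+0"]]), atlasMean(atlas), tolerance = 1e-12)
  mid <- (shapeToVector(sh[["alpha_-2"]]) + shapeToVector(sh[["alpha_+2"]])) / 2
  expect_equal(mid, atlasMean(atlas), tolerance = 1e-9)
  expect_error(renderModeShapes(atlas, 1, alphas = numeric(0)), "non-empty")
  expect_error(renderModeShapes(atlas, 99, alphas = 1), "out of range")
})
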