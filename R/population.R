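# Synthetic shape populations with planted low-rank mode structure.
#
# The generative model over the concatenated ED+ES coordinate vector is
#   shape_i = template + sum_k z_ik * sqrt(lambda_k) * D_k + eps_i
# with z_ik the planted standardized mode scores, D_k orthonormal
# displacement fields (after centering), eps per-coordinate Gaussian noise,
# followed by a random rigid pose (the same pose for a subject's ED and ES).
# Ground truth records the draws so downstream recovery is testable.

#' Default planted mode displacement fields
#'
#' Four qualitative deformations mirroring the remodeling patterns the shape
#' modes of repaired tetralogy of Fallot populations express: (1) RV dilation
#' with basal bulging, (2) RV apical bulging, (3) tricuspid-annulus tilt, and
#' (4) LV size change. Fields are built geometrically on the template, then
#' projected onto the complement of the rigid-motion tangent space (joint
#' translations and infinitesimal rotations) so that Procrustes alignment
#' cannot absorb any part of them, and finally orthonormalized (QR with a
#' deterministic sign convention): their Gram matrix is the identity to
#' within 1e-10.
#'
#' @param template a [BiventricularShape-class], usually from
#'   [generateTemplateShape()].
#' @return A 6P x 4 orthonormal matrix of displacement fields.
#' @export
defaultModeDisplacements <- function(template) {
  pts <- template@pointsED
  lab <- template@labels
  g <- .templateGeom
  P <- nrow(pts)
  rvSel <- lab %in% c("RV_endo", "RV_epi", "tricuspid_ring", "pulmonary_ring")
  lvSel <- !rvSel
  rvAxis <- g$rv_axis_xy

  radialRV <- matrix(0, P, 3)
  d <- sweep(pts[rvSel, 1:2, drop = FALSE], 2, rvAxis)
  nr <- sqrt(rowSums(d^2)); nr[nr < 1e-9] <- 1
  radialRV[rvSel, 1:2] <- d / nr

  # 1: RV dilation, heavier at the base (z near 0)
  w1 <- exp(-(pts[, 3] - 0)^2 / (2 * 20^2))
  d1 <- radialRV * (0.4 + 0.6 * w1)

  # 2: RV apical bulge: radial + downward push near the apex
  apexZ <- -g$rv_endo$semi[3]
  w2 <- exp(-(pts[, 3] - apexZ)^2 / (2 * 14^2)) * rvSel
  d2 <- radialRV * (0.6 * w2) + cbind(0, 0, -0.8 * w2)

  # 3: tricuspid-annulus tilt: rotation field about an in-plane axis through
  # the ring center, decaying away from the ring
  rc <- g$rings$tricuspid_ring$center
  axis <- c(1, 0, 0)
  rel <- sweep(pts, 2, rc)
  omega <- cbind(axis[2] * rel[, 3] - axis[3] * rel[, 2],
                 axis[3] * rel[, 1] - axis[1] * rel[, 3],
                 axis[1] * rel[, 2] - axis[2] * rel[, 1])
  w3 <- exp(-rowSums(rel^2) / (2 * 22^2)) * rvSel
  d3 <- omega * w3 / 20

  # 4: LV size change: radial expansion of LV points about the LV centroid
  lvC <- c(g$lv_axis_xy, -20)
  rel4 <- sweep(pts, 2, lvC)
  d4 <- rel4 / 40 * lvSel

  pack <- function(dm) c(as.numeric(t(dm)), as.numeric(t(dm)))  # same field at ED and ES
  Draw <- cbind(pack(d1), pack(d2), pack(d3), pack(d4))
  # Remove the rigid-motion component: planted modes must live in shape space
  # proper (orthogonal to joint translations and infinitesimal rotations of
  # the template), otherwise Procrustes alignment absorbs part of them and
  # planted deformations are not recoverable as stated.
  Draw <- .projectOutRigid(Draw, template)
  qrD <- qr(Draw)
  Q <- qr.Q(qrD)
  sgn <- sign(diag(qr.R(qrD)))
  sgn[sgn == 0] <- 1
  sweep(Q, 2, sgn, `*`)
}

# Orthonormal basis of the rigid-motion tangent space at a shape (6 columns:
# 3 joint translations, 3 infinitesimal joint rotations about the overall
# centroid), and projection of displacement columns onto its complement.
.rigidTangentBasis <- function(template) {
  ed <- template@pointsED; es <- template@pointsES
  allp <- rbind(ed, es)
  ctr <- colMeans(allp)
  rel <- sweep(allp, 2, ctr)
  P2 <- nrow(allp)
  B <- matrix(0, 3 * P2, 6)
  for (a in 1:3) {
    tr <- matrix(0, P2, 3); tr[, a] <- 1
    B[, a] <- as.numeric(t(tr))
    e <- c(0, 0, 0); e[a] <- 1
    rot <- cbind(e[2] * rel[, 3] - e[3] * rel[, 2],
                 e[3] * rel[, 1] - e[1] * rel[, 3],
                 e[1] * rel[, 2] - e[2] * rel[, 1])
    B[, 3 + a] <- as.numeric(t(rot))
  }
  qr.Q(qr(B))
}

.projectOutRigid <- function(D, template) {
  Q <- .rigidTangentBasis(template)
  D - Q %*% crossprod(Q, D)
}

#' Specify a synthetic shape population
#'
#' Bundles and validates everything [generateShapePopulation()] needs. Mode
#' displacement fields must be mutually orthonormal after centering (Gram
#' matrix within 1e-10 of identity) and variances strictly positive and
#' non-increasing.
#'
#' @param template a [BiventricularShape-class].
#' @param n_subjects population size.
#' @param mode_displacements 6P x M orthonormal matrix; default
#'   [defaultModeDisplacements()] of the template.
#' @param mode_variances numeric length-M, lambda_1 >= ... >= lambda_M > 0 (mm^2).
#' @param noise_sd per-coordinate independent Gaussian noise sd (mm).
#' @param pose_jitter_deg max random rotation per subject (degrees).
#' @param pose_jitter_mm max random translation per axis (mm).
#' @param seed integer root seed; per-subject substreams are derived from it.
#' @return A validated list of class \code{"PopulationSpec"}.
#' @export
populationSpec <- function(template, n_subjects,
                           mode_displacements = defaultModeDisplacements(template),
                           mode_variances = c(400, 144, 49, 25),
                           noise_sd = 0.2, pose_jitter_deg = 5,
                           pose_jitter_mm = 5, seed = 1) {
  P <- nPoints(template)
  D <- as.matrix(mode_displacements)
  M <- ncol(D)
  if (nrow(D) != 6 * P) .stopf("mode_displacements must have 6P = %d rows", 6 * P)
  if (M > 3 * P) .stopf("more modes (%d) than 3P = %d", M, 3 * P)
  if (length(mode_variances) != M) .stopf("need one variance per mode")
  if (any(mode_variances <= 0)) .stopf("mode variances must be strictly positive")
  if (is.unsorted(rev(mode_variances))) .stopf("mode variances must be non-increasing")
  G <- crossprod(D)
  if (max(abs(G - diag(M))) > 1e-10)
    .stopf("mode_displacements are not orthonormal (max Gram deviation %.2e)",
           max(abs(G - diag(M))))
  if (noise_sd < 0) .stopf("noise_sd must be non-negative")
  if (n_subjects < 1) .stopf("n_subjects must be at least 1")
  structure(list(template = template, n_subjects = as.integer(n_subjects),
                 mode_displacements = D, mode_variances = mode_variances,
                 noise_sd = noise_sd, pose_jitter_deg = pose_jitter_deg,
                 pose_jitter_mm = pose_jitter_mm, seed = as.integer(seed)),
            class = "PopulationSpec")
}

#' Create an empty ground-truth record
#'
#' Ground truth carries the planted standardized mode scores, the per-mode
#' coefficients linking the planted predictor (average vorticity) to the
#' scores, and the covariate effects. Scores start empty; they are filled
#' either by [generateSubjectCovariates()] (the generative direction:
#' predictor and covariates drive the scores) or by
#' [generateShapePopulation()] when called standalone (independent standard
#' normal draws).
#'
#' @param n number of subjects.
#' @param M number of planted modes.
#' @param association_betas numeric length-M predictor coefficients.
#' @param covariate_betas M x 4 matrix of effects for (sex, height, weight,
#'   age), standardized scale. Default zero.
#' @return A list of class \code{"GroundTruth"}.
#' @export
makeGroundTruth <- function(n, M, association_betas = rep(0, M),
                            covariate_betas = matrix(0, M, 4)) {
  if (length(association_betas) != M) .stopf("association_betas must have length M")
  covariate_betas <- as.matrix(covariate_betas)
  if (nrow(covariate_betas) != M || ncol(covariate_betas) != 4)
    .stopf("covariate_betas must be M x 4 (sex, height, weight, age)")
  if (!all(is.finite(association_betas)) || !all(is.finite(covariate_betas)))
    .stopf("betas must be finite")
  structure(list(n = as.integer(n), M = as.integer(M),
                 true_scores = NULL,
                 association_betas = association_betas,
                 covariate_betas = covariate_betas,
                 poses = NULL),
            class = "GroundTruth")
}

#' Generate a synthetic shape population
#'
#' Draws \code{n} shapes from the planted-mode model (see
#' [populationSpec()]): template plus score-weighted orthonormal displacement
#' fields plus coordinate noise, then a random rigid pose per subject (shared
#' by that subject's ED and ES). If \code{truth} supplies planted scores they
#' are used; otherwise scores are drawn i.i.d. standard normal and recorded.
#' Fully reproducible: subject i consumes only its own sub-stream of the root
#' seed.
#'
#' @param spec a \code{"PopulationSpec"} from [populationSpec()].
#' @param truth optional \code{"GroundTruth"} (from [makeGroundTruth()] +
#'   [generateSubjectCovariates()]) whose scores drive the shapes.
#' @return \code{list(shapes = list of [BiventricularShape-class],
#'   truth = "GroundTruth")} with scores and poses filled in.
#' @export
generateShapePopulation <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "PopulationSpec"))
  n <- spec$n_subjects
  M <- ncol(spec$mode_displacements)
  if (is.null(truth)) truth <- makeGroundTruth(n, M)
  stopifnot(inherits(truth, "GroundTruth"))
  if (truth$n != n) .stopf("truth is for %d subjects, spec for %d", truth$n, n)
  if (truth$M != M) .stopf("truth has %d modes, spec %d", truth$M, M)
  drawScores <- is.null(truth$true_scores)
  if (!drawScores && (nrow(truth$true_scores) != n || ncol(truth$true_scores) != M))
    .stopf("truth$true_scores has wrong dimensions")
  tvec <- shapeToVector(spec$template)
  P <- nPoints(spec$template)
  sqrtL <- sqrt(spec$mode_variances)
  shapes <- vector("list", n)
  scores <- if (drawScores) matrix(0, n, M) else truth$true_scores
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subSeed(spec$seed, i))
    z <- if (drawScores) stats::rnorm(M) else scores[i, ]
    if (drawScores) scores[i, ] <- z
    v <- tvec + as.numeric(spec$mode_displacements %*% (z * sqrtL))
    if (spec$noise_sd > 0) v <- v + stats::rnorm(length(v), 0, spec$noise_sd)
    R <- .randomRotation(spec$pose_jitter_deg)
    t <- if (spec$pose_jitter_mm > 0) stats::runif(3, -spec$pose_jitter_mm, spec$pose_jitter_mm) else c(0, 0, 0)
    ed <- .applyRigid(matrix(v[seq_len(3 * P)], ncol = 3, byrow = TRUE), R, t)
    es <- .applyRigid(matrix(v[3 * P + seq_len(3 * P)], ncol = 3, byrow = TRUE), R, t)
    shapes[[i]] <- new("BiventricularShape", pointsED = ed, pointsES = es,
                       labels = spec$template@labels, faces = spec$template@faces)
    poses[[i]] <- list(R = R, t = t)
  }
  truth$true_scores <- scores
  truth$poses <- poses
  truth$noise_sd <- spec$noise_sd
  list(shapes = shapes, truth = truth)
}

#' Generate subject covariates and the planted flow predictor
#'
#' Draws age, sex, height and weight from plausible adult ranges (normal
#' draws around the demographics typical of adult repaired-tetralogy cohorts,
#' clipped to sane bounds), computes BSA by the Mosteller formula, and
#' generates the planted predictor (an average-vorticity-like quantity) plus
#' the planted standardized mode scores
#' \deqn{z_{ik} = \beta_k \, p_i + c_i^\top \gamma_k + e_{ik}, \quad
#'       e_{ik} \sim N(0, \mathrm{noise\_sd}^2)}
#' where \eqn{p} is the sample-standardized predictor and \eqn{c} the
#' standardized covariates. If \code{truth} already carries scores and all
#' association betas are zero, the predictor is drawn independently and the
#' scores are kept (the null case); carrying pre-drawn scores together with
#' nonzero betas is an error because the association would no longer be
#' generative.
#'
#' @param n number of subjects (must match \code{truth$n}).
#' @param truth a \code{"GroundTruth"} from [makeGroundTruth()].
#' @param noise_sd residual sd of the scores around the linear model.
#' @param seed integer seed.
#' @return \code{list(covariates = data.frame(id, age, sex, height, weight,
#'   bsa, vorticity, predictor_std), truth = updated "GroundTruth")}.
#' @export
generateSubjectCovariates <- function(n, truth, noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (truth$n != n) .stopf("truth is for %d subjects, asked for %d", truth$n, n)
  set.seed(subSeed(seed, 900001))
  age <- pmin(pmax(stats::rnorm(n, 32.3, 11.2), 16), 75)
  sex <- stats::rbinom(n, 1, 0.5)
  height <- pmin(pmax(stats::rnorm(n, 168.6, 8.6), 145), 200)
  weight <- pmin(pmax(stats::rnorm(n, 71, 12.2), 40), 130)
  bsa <- bsaMosteller(height, weight)
  vort_raw <- pmax(stats::rnorm(n, 22, 6), 2)
  pred_std <- as.numeric(scale(vort_raw))
  covStd <- scale(cbind(sex = sex, height = height, weight = weight, age = age))
  haveScores <- !is.null(truth$true_scores)
  if (haveScores && any(truth$association_betas != 0))
    .stopf(paste("truth already has scores but nonzero association betas;",
                 "generate covariates before the shape population so the",
                 "planted association is generative"))
  if (!haveScores) {
    e <- matrix(stats::rnorm(n * truth$M, 0, noise_sd), n, truth$M)
    z <- pred_std %o% truth$association_betas +
      covStd %*% t(truth$covariate_betas) + e
    truth$true_scores <- z
  }
  cov <- data.frame(id = sprintf("S%03d", seq_len(n)),
                    age = age, sex = sex, height = height, weight = weight,
                    bsa = bsa, vorticity = vort_raw, predictor_std = pred_std,
                    stringsAsFactors = FALSE)
  list(covariates = cov, truth = truth)
}
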