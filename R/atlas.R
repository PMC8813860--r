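# Statistical shape atlas: generalized Procrustes alignment of the ED point
# sets (transforms inherited by ES), principal component analysis of the
# concatenated ED+ES vectors, projection scoring, reconstruction, and
# chamber volumes/mass by mesh integration.

#' Generalized Procrustes alignment of a shape population
#'
#' Iteratively aligns every subject's end-diastolic point set to the evolving
#' mean by the optimal rigid transform (rotation + translation; no scaling,
#' no reflection — the rotation determinant is constrained to +1), recomputes
#' the mean, and repeats until the mean moves less than \code{tol} (mean
#' point displacement, mm). Each subject's ED transform is then applied
#' verbatim to its ES points, so systolic motion relative to ED is preserved.
#'
#' @param shapes list of [BiventricularShape-class] with identical point
#'   counts and labels (at least 2).
#' @param tol convergence tolerance on mean movement, mm.
#' @param maxIter iteration cap.
#' @return \code{list(shapes = aligned shapes, transforms = list of
#'   list(R, t), iterations, meanShift)}.
#' @export
generalizedProcrustesAlign <- function(shapes, tol = 1e-7, maxIter = 100) {
  if (length(shapes) < 2) .stopf("need at least 2 shapes")
  P <- nPoints(shapes[[1]])
  labs <- pointLabels(shapes[[1]])
  for (s in shapes) {
    if (nPoints(s) != P || !identical(pointLabels(s), labs))
      .stopf("shapes must share point count and labels")
    if (max(apply(shapePoints(s, "ED"), 2, stats::sd)) < 1e-12)
      .stopf("degenerate shape: all ED points coincide")
  }
  eds <- lapply(shapes, shapePoints, phase = "ED")
  meanED <- eds[[1]]
  meanED <- sweep(meanED, 2, colMeans(meanED))
  transforms <- vector("list", length(shapes))
  iter <- 0L; shift <- Inf
  while (iter < maxIter && shift > tol) {
    iter <- iter + 1L
    aligned <- vector("list", length(shapes))
    for (i in seq_along(shapes)) {
      tr <- .kabsch(eds[[i]], meanED)
      transforms[[i]] <- tr
      aligned[[i]] <- .applyRigid(eds[[i]], tr$R, tr$t)
    }
    newMean <- Reduce(`+`, aligned) / length(aligned)
    newMean <- sweep(newMean, 2, colMeans(newMean))
    shift <- mean(sqrt(rowSums((newMean - meanED)^2)))
    meanED <- newMean
  }
  out <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    tr <- transforms[[i]]
    out[[i]] <- new("BiventricularShape",
                    pointsED = .applyRigid(eds[[i]], tr$R, tr$t),
                    pointsES = .applyRigid(shapePoints(shapes[[i]], "ES"), tr$R, tr$t),
                    labels = labs, faces = shapeFaces(shapes[[i]]))
  }
  list(shapes = out, transforms = transforms, iterations = iter, meanShift = shift)
}

#' Build the shape atlas by PCA of concatenated ED+ES vectors
#'
#' Stacks each aligned subject's concatenated coordinate vector (ED xyz then
#' ES xyz, length 6P), centers by the mean, and eigendecomposes the sample
#' covariance via singular value decomposition of the centered matrix.
#' Eigenvalues follow the 1/(n-1) convention; mode signs are fixed
#' deterministically (the largest-magnitude loading of each mode is made
#' positive). All \code{min(n-1, 6P)} modes are kept in the object; use
#' [selectModeCount()] and \code{nModesRetained<-} to truncate for scoring.
#'
#' @param shapes list of aligned [BiventricularShape-class] (n >= 3).
#' @return A [ShapeAtlas-class].
#' @export
buildShapeAtlas <- function(shapes) {
  n <- length(shapes)
  if (n < 3) .stopf("need at least 3 shapes to build an atlas")
  X <- do.call(rbind, lapply(shapes, shapeToVector))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  variances <- sv$d^2 / (n - 1)
  keep <- seq_len(min(n - 1, ncol(X)))
  modes <- sv$v[, keep, drop = FALSE]
  variances <- variances[keep]
  for (k in seq_along(keep)) {
    j <- which.max(abs(modes[, k]))
    if (modes[j, k] < 0) modes[, k] <- -modes[, k]
  }
  new("ShapeAtlas", meanShape = mu, modes = modes, variances = variances,
      nModesRetained = length(keep), P = nPoints(shapes[[1]]),
      labels = pointLabels(shapes[[1]]), faces = shapeFaces(shapes[[1]]))
}

#' Number of modes capturing a variance fraction
#'
#' The smallest K whose cumulative explained variance reaches the given
#' fraction (default 0.90, the conventional atlas truncation). Store the
#' result with \code{nModesRetained(atlas) <- K}.
#'
#' @param atlas a [ShapeAtlas-class].
#' @param fraction target cumulative fraction, in (0, 1].
#' @return Integer K.
#' @export
selectModeCount <- function(atlas, fraction = 0.90) {
  stopifnot(is(atlas, "ShapeAtlas"))
  if (fraction <= 0 || fraction > 1) .stopf("fraction must be in (0, 1]")
  ev <- explainedVariance(atlas)
  if (fraction == 1) return(sum(atlas@variances > 1e-12 * max(atlas@variances, 1)))
  as.integer(which(ev >= fraction - 1e-12)[1])
}

#' Project a shape onto the atlas modes
#'
#' Rigidly aligns the shape's ED points to the atlas mean ED (rotation +
#' translation, no scaling; the transform is applied to ES), subtracts the
#' mean shape, and takes inner products with the first K retained modes.
#' Normalized scores divide each raw score by \code{sqrt(lambda_k)}, so a
#' score of +2 means two population standard deviations from the mean along
#' that mode.
#'
#' @param shape a [BiventricularShape-class] with the atlas's P and labels.
#' @param atlas a [ShapeAtlas-class].
#' @param K number of modes to score on (default \code{nModesRetained}).
#' @param align rigidly align to the atlas mean first (default TRUE; set
#'   FALSE when the shape is already in atlas pose).
#' @return Named numeric vector of K normalized scores, with the raw
#'   (mm-unit) scores in \code{attr(, "raw")}.
#' @export
projectToAtlas <- function(shape, atlas, K = nModesRetained(atlas), align = TRUE) {
  stopifnot(is(shape, "BiventricularShape"), is(atlas, "ShapeAtlas"))
  if (nPoints(shape) != atlas@P) .stopf("shape has %d points, atlas %d", nPoints(shape), atlas@P)
  if (!identical(pointLabels(shape), atlas@labels)) .stopf("shape labels differ from atlas labels")
  K <- as.integer(K)
  if (K < 1 || K > ncol(atlas@modes)) .stopf("K outside 1..%d", ncol(atlas@modes))
  P <- atlas@P
  meanED <- matrix(atlas@meanShape[seq_len(3 * P)], ncol = 3, byrow = TRUE)
  ed <- shape@pointsED; es <- shape@pointsES
  if (align) {
    tr <- .kabsch(ed, meanED)
    ed <- .applyRigid(ed, tr$R, tr$t)
    es <- .applyRigid(es, tr$R, tr$t)
  }
  v <- c(as.numeric(t(ed)), as.numeric(t(es))) - atlas@meanShape
  raw <- as.numeric(crossprod(atlas@modes[, seq_len(K), drop = FALSE], v))
  lam <- atlas@variances[seq_len(K)]
  norm <- raw / sqrt(ifelse(lam > 0, lam, Inf))
  names(norm) <- paste0("mode", seq_len(K))
  attr(norm, "raw") <- raw
  norm
}

#' Reconstruct a shape from atlas mode scores
#'
#' \deqn{\hat{s} = \bar{s} + \sum_k z_k \sqrt{\lambda_k}\, \phi_k}
#' the inverse of [projectToAtlas()] on in-span shapes. Zero scores give the
#' atlas mean.
#'
#' @param scores numeric vector of normalized scores (length <= number of
#'   atlas modes).
#' @param atlas a [ShapeAtlas-class].
#' @return A [BiventricularShape-class].
#' @export
reconstructFromScores <- function(scores, atlas) {
  stopifnot(is(atlas, "ShapeAtlas"))
  k <- length(scores)
  if (k > ncol(atlas@modes)) .stopf("more scores than atlas modes")
  v <- atlas@meanShape
  if (k > 0) {
    lam <- atlas@variances[seq_len(k)]
    v <- v + as.numeric(atlas@modes[, seq_len(k), drop = FALSE] %*%
                          (as.numeric(scores) * sqrt(lam)))
  }
  vectorToShape(v, atlas)
}

#' Mean point-to-point error between corresponded shapes
#'
#' Mean over points of the Euclidean distance between corresponding points,
#' reported separately for ED and ES (mm).
#'
#' @param a,b [BiventricularShape-class] objects with identical P.
#' @return \code{list(ed, es)} mean distances in mm.
#' @export
pointToPointError <- function(a, b) {
  if (nPoints(a) != nPoints(b)) .stopf("point counts differ")
  list(ed = mean(sqrt(rowSums((a@pointsED - b@pointsED)^2))),
       es = mean(sqrt(rowSums((a@pointsES - b@pointsES)^2))))
}

#' Chamber volumes, ejection fraction, and mass
#'
#' Cavity volumes by signed-tetrahedron integration over the endocardial
#' triangles (divergence theorem, mm^3 to mL); myocardial mass as
#' (epicardial volume - endocardial volume) x 1.05 g/mL at ED; SV = EDV -
#' ESV and EF = SV/EDV per chamber. Indexed variants divide by BSA. Requires
#' closed, consistently oriented chamber surfaces.
#'
#' @param shape a [BiventricularShape-class] with \code{LV_endo},
#'   \code{LV_epi}, \code{RV_endo}, \code{RV_epi} face sets.
#' @param bsa body surface area, m^2 (NA to skip indexing).
#' @param density myocardial density, g/mL (default 1.05).
#' @return A data.frame with one row per chamber (LV, RV): \code{edv},
#'   \code{esv}, \code{sv} (mL), \code{ef}, \code{mass} (g) and, when BSA is
#'   given, \code{edvi}, \code{esvi}, \code{svi}, \code{massi}.
#' @export
chamberVolumeAndMass <- function(shape, bsa = NA_real_, density = 1.05) {
  stopifnot(is(shape, "BiventricularShape"))
  need <- c("LV_endo", "LV_epi", "RV_endo", "RV_epi")
  if (!all(need %in% names(shape@faces)))
    .stopf("shape lacks face sets for: %s",
           paste(setdiff(need, names(shape@faces)), collapse = ", "))
  volOf <- function(phase, surf)
    enclosedVolume(shapePoints(shape, phase), shape@faces[[surf]])
  rows <- lapply(c(LV = "LV", RV = "RV"), function(ch) {
    edv <- volOf("ED", paste0(ch, "_endo"))
    esv <- volOf("ES", paste0(ch, "_endo"))
    epiED <- volOf("ED", paste0(ch, "_epi"))
    mass <- (epiED - edv) * density
    sv <- edv - esv
    data.frame(chamber = ch, edv = edv, esv = esv, sv = sv,
               ef = if (edv > 0) sv / edv else NA_real_, mass = mass)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$chamber
  if (!is.na(bsa)) {
    out$edvi <- out$edv / bsa
    out$esvi <- out$esv / bsa
    out$svi <- out$sv / bsa
    out$massi <- out$mass / bsa
  }
  out
}

#' Save / load a shape atlas archive
#'
#' The atlas (mean, modes, variances, truncation, topology) is serialized as
#' a single RDS archive with a small provenance block.
#'
#' @param atlas a [ShapeAtlas-class].
#' @param path file path.
#' @return \code{saveShapeAtlas}: the path, invisibly; \code{readShapeAtlas}:
#'   the [ShapeAtlas-class].
#' @export
saveShapeAtlas <- function(atlas, path) {
  stopifnot(is(atlas, "ShapeAtlas"))
  payload <- list(atlas = atlas,
                  provenance = list(package = "vortexatlas",
                                    version = as.character(utils::packageVersion("vortexatlas")),
                                    created = format(Sys.time(), tz = "UTC")))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveShapeAtlas
#' @export
readShapeAtlas <- function(path) {
  payload <- readRDS(path)
  atlas <- payload$atlas
  validObject(atlas)
  atlas
}
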