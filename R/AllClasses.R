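#' @import methods
NULL

#' VelocityField: a time-resolved 3-component velocity lattice
#'
#' Holds phase-contrast-MRI style velocity data: a regular 3-D lattice of
#' 3-vectors (cm/s) per cardiac frame, with voxel spacing (mm), frame duration
#' (ms), the velocity-encoding limit VENC (cm/s), and the frame range labeled
#' as diastole. Voxel \code{i} (1-based) is centered at \code{(i-1)*spacing} mm.
#'
#' @slot values 5-D numeric array \code{(nx, ny, nz, 3, nFrames)} in cm/s.
#' @slot spacing numeric length-3, voxel size per axis in mm.
#' @slot frameDuration numeric scalar, ms per frame.
#' @slot venc numeric scalar, velocity encoding limit in cm/s.
#' @slot diastoleFrames integer vector of frame indices labeled diastolic.
#' @export
setClass("VelocityField",
  representation(values = "array", spacing = "numeric",
                 frameDuration = "numeric", venc = "numeric",
                 diastoleFrames = "integer"),
  validity = function(object) {
    d <- dim(object@values)
    msg <- character()
    if (length(d) != 5 || d[4] != 3)
      msg <- c(msg, "values must be a (nx, ny, nz, 3, nFrames) array")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(d) == 5 && d[5] < 1) msg <- c(msg, "need at least 1 frame")
    if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
    if (object@venc <= 0) msg <- c(msg, "venc must be positive")
    if (length(d) == 5 && length(object@diastoleFrames) &&
        (min(object@diastoleFrames) < 1 || max(object@diastoleFrames) > d[5]))
      msg <- c(msg, "diastoleFrames outside the frame range")
    if (length(msg)) msg else TRUE
  })

#' VorticityField: the curl of a velocity field at one frame
#'
#' @slot vectors 4-D array \code{(nx, ny, nz, 3)} of curl vectors (1/s).
#' @slot magnitude 3-D array of Euclidean norms of \code{vectors} (1/s).
#' @slot frame integer frame index the curl was computed at.
#' @slot spacing numeric length-3 voxel size (mm), inherited from the velocity
#'   field so ROI geometry can be resolved.
#' @export
setClass("VorticityField",
  representation(vectors = "array", magnitude = "array",
                 frame = "integer", spacing = "numeric"),
  validity = function(object) {
    d <- dim(object@vectors)
    msg <- character()
    if (length(d) != 4 || d[4] != 3)
      msg <- c(msg, "vectors must be (nx, ny, nz, 3)")
    if (!identical(dim(object@magnitude), d[1:3]))
      msg <- c(msg, "magnitude must match the spatial grid")
    if (!all(is.finite(object@vectors)) || !all(is.finite(object@magnitude)))
      msg <- c(msg, "curl values must be finite")
    mag <- sqrt(object@vectors[, , , 1]^2 + object@vectors[, , , 2]^2 +
                  object@vectors[, , , 3]^2)
    if (max(abs(mag - object@magnitude)) > 1e-8 * (1 + max(mag)))
      msg <- c(msg, "magnitude is not the norm of vectors")
    if (length(msg)) msg else TRUE
  })

#' BiventricularShape: corresponded ED and ES surface point sets
#'
#' An ordered, labeled biventricular geometry: the same P points at end
#' diastole and end systole (fixed point order is the correspondence
#' contract), per-point anatomical labels, and a triangle list per closed
#' chamber surface. Annulus rings are bare labeled point loops with no faces.
#'
#' @slot pointsED P x 3 matrix (mm).
#' @slot pointsES P x 3 matrix (mm), same order and labels as ED.
#' @slot labels character length-P with values in
#'   \code{LV_endo, LV_epi, RV_endo, RV_epi, tricuspid_ring, mitral_ring,
#'   pulmonary_ring, aortic_ring}.
#' @slot faces named list of integer (nFace x 3) matrices, one per closed
#'   surface, indices into the global point list, consistently oriented
#'   outward (signed enclosed volume positive).
#' @export
setClass("BiventricularShape",
  representation(pointsED = "matrix", pointsES = "matrix",
                 labels = "character", faces = "list"),
  validity = function(object) {
    msg <- character()
    P <- nrow(object@pointsED)
    if (!identical(dim(object@pointsED), dim(object@pointsES)))
      msg <- c(msg, "pointsED and pointsES must have identical dimensions")
    if (ncol(object@pointsED) != 3) msg <- c(msg, "points must be P x 3")
    if (length(object@labels) != P) msg <- c(msg, "labels must have length P")
    bad <- setdiff(unique(object@labels), .shapeLabelLevels)
    if (length(bad)) msg <- c(msg, paste("unknown labels:", paste(bad, collapse = ", ")))
    if (!all(is.finite(object@pointsED)) || !all(is.finite(object@pointsES)))
      msg <- c(msg, "coordinates must be finite")
    for (nm in names(object@faces)) {
      f <- object@faces[[nm]]
      if (!is.matrix(f) || ncol(f) != 3 || min(f) < 1 || max(f) > P)
        msg <- c(msg, sprintf("faces[[%s]] must be an nFace x 3 index matrix into 1..P", nm))
    }
    if (length(msg)) msg else TRUE
  })

.shapeLabelLevels <- c("LV_endo", "LV_epi", "RV_endo", "RV_epi",
                       "tricuspid_ring", "mitral_ring", "pulmonary_ring",
                       "aortic_ring")

#' ShapeAtlas: mean shape plus orthonormal principal modes
#'
#' The statistical shape atlas: the population mean of the concatenated
#' ED+ES coordinate vector (length 6P: ED xyz then ES xyz), an orthonormal
#' mode matrix, per-mode variances under the 1/(n-1) convention, and the
#' number of modes retained for scoring.
#'
#' @slot meanShape numeric length-6P (mm).
#' @slot modes 6P x M orthonormal matrix.
#' @slot variances numeric length-M, non-increasing eigenvalues (mm^2).
#' @slot nModesRetained integer K, modes used for projection/reconstruction.
#' @slot P integer number of points per phase.
#' @slot labels character length-P label vector of the training shapes.
#' @slot faces list, face topology of the training shapes.
#' @export
setClass("ShapeAtlas",
  representation(meanShape = "numeric", modes = "matrix",
                 variances = "numeric", nModesRetained = "integer",
                 P = "integer", labels = "character", faces = "list"),
  validity = function(object) {
    msg <- character()
    M <- ncol(object@modes)
    if (length(object@meanShape) != nrow(object@modes))
      msg <- c(msg, "meanShape length must match mode rows")
    if (length(object@variances) != M)
      msg <- c(msg, "one variance per mode required")
    if (M && is.unsorted(rev(object@variances)))
      msg <- c(msg, "variances must be non-increasing")
    if (M && any(object@variances < -1e-12))
      msg <- c(msg, "variances must be non-negative")
    if (M) {
      G <- crossprod(object@modes)
      if (max(abs(G - diag(M))) > 1e-8)
        msg <- c(msg, "modes must be orthonormal (within 1e-8)")
    }
    if (object@nModesRetained < 0 || object@nModesRetained > M)
      msg <- c(msg, "nModesRetained out of range")
    if (length(object@meanShape) != 6 * object@P)
      msg <- c(msg, "meanShape must have length 6P")
    if (length(msg)) msg else TRUE
  })

#' MorphometricMode: shape displacement per unit predictor
#'
#' The result of covariate-adjusted per-mode regression: the predictor's
#' coefficient on each retained atlas mode (SD-score units per SD of
#' predictor), covariate coefficients, and the assembled shape-space
#' displacement for +1 SD of the predictor,
#' \code{displacement = sum_k beta_k * sqrt(lambda_k) * mode_k} (mm).
#'
#' @slot betaPerMode numeric length-K predictor coefficients.
#' @slot betaSE numeric length-K standard errors.
#' @slot betaCI K x 2 matrix of 95 percent confidence limits.
#' @slot covariateBetas K x C matrix of covariate coefficients.
#' @slot displacement numeric length-6P shape displacement per +1 SD (mm).
#' @slot predictorName character, name of the predictor variable.
#' @export
setClass("MorphometricMode",
  representation(betaPerMode = "numeric", betaSE = "numeric",
                 betaCI = "matrix", covariateBetas = "matrix",
                 displacement = "numeric", predictorName = "character"),
  validity = function(object) {
    msg <- character()
    K <- length(object@betaPerMode)
    if (length(object@betaSE) != K || nrow(object@betaCI) != K)
      msg <- c(msg, "betaSE/betaCI must match betaPerMode length")
    if (!all(is.finite(object@betaPerMode)) || !all(is.finite(object@displacement)))
      msg <- c(msg, "coefficients and displacement must be finite")
    if (length(msg)) msg else TRUE
  })
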