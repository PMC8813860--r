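# Accessor generics and methods. Slot access stays internal to the package;
# user code goes through these.

#' @name accessors
#' @title Accessors for vortexatlas data classes
#' @description Small accessor functions for the S4 containers: grid and
#'   timing metadata of velocity fields, point sets and labels of shapes, and
#'   the mean/modes/variances of a shape atlas.
#' @param x an object.
#' @param value replacement value.
#' @return The slot content (or the modified object for setters).
NULL

#' @rdname accessors
#' @export
setGeneric("velocityValues", function(x) standardGeneric("velocityValues"))
#' @rdname accessors
#' @export
setMethod("velocityValues", "VelocityField", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VelocityField", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VorticityField", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("frameDuration", function(x) standardGeneric("frameDuration"))
#' @rdname accessors
#' @export
setMethod("frameDuration", "VelocityField", function(x) x@frameDuration)

#' @rdname accessors
#' @export
setGeneric("venc", function(x) standardGeneric("venc"))
#' @rdname accessors
#' @export
setMethod("venc", "VelocityField", function(x) x@venc)

#' @rdname accessors
#' @export
setGeneric("diastoleFrames", function(x) standardGeneric("diastoleFrames"))
#' @rdname accessors
#' @export
setMethod("diastoleFrames", "VelocityField", function(x) x@diastoleFrames)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "VelocityField", function(x) dim(x@values)[5])

#' @rdname accessors
#' @export
setGeneric("curlVectors", function(x) standardGeneric("curlVectors"))
#' @rdname accessors
#' @export
setMethod("curlVectors", "VorticityField", function(x) x@vectors)

#' @rdname accessors
#' @export
setGeneric("curlMagnitude", function(x) standardGeneric("curlMagnitude"))
#' @rdname accessors
#' @export
setMethod("curlMagnitude", "VorticityField", function(x) x@magnitude)

#' @rdname accessors
#' @export
setGeneric("shapePoints", function(x, phase = c("ED", "ES")) standardGeneric("shapePoints"))
#' @rdname accessors
#' @param phase \code{"ED"} or \code{"ES"}.
#' @export
setMethod("shapePoints", "BiventricularShape", function(x, phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  if (phase == "ED") x@pointsED else x@pointsES
})

#' @rdname accessors
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))
#' @rdname accessors
#' @export
setMethod("pointLabels", "BiventricularShape", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("pointLabels", "ShapeAtlas", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("shapeFaces", function(x) standardGeneric("shapeFaces"))
#' @rdname accessors
#' @export
setMethod("shapeFaces", "BiventricularShape", function(x) x@faces)
#' @rdname accessors
#' @export
setMethod("shapeFaces", "ShapeAtlas", function(x) x@faces)

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setMethod("nPoints", "BiventricularShape", function(x) nrow(x@pointsED))
#' @rdname accessors
#' @export
setMethod("nPoints", "ShapeAtlas", function(x) x@P)

#' @rdname accessors
#' @export
setGeneric("atlasMean", function(x) standardGeneric("atlasMean"))
#' @rdname accessors
#' @export
setMethod("atlasMean", "ShapeAtlas", function(x) x@meanShape)

#' @rdname accessors
#' @export
setGeneric("atlasModes", function(x) standardGeneric("atlasModes"))
#' @rdname accessors
#' @export
setMethod("atlasModes", "ShapeAtlas", function(x) x@modes)

#' @rdname accessors
#' @export
setGeneric("atlasVariances", function(x) standardGeneric("atlasVariances"))
#' @rdname accessors
#' @export
setMethod("atlasVariances", "ShapeAtlas", function(x) x@variances)

#' @rdname accessors
#' @export
setGeneric("nModesRetained", function(x) standardGeneric("nModesRetained"))
#' @rdname accessors
#' @export
setMethod("nModesRetained", "ShapeAtlas", function(x) x@nModesRetained)

#' @rdname accessors
#' @export
setGeneric("nModesRetained<-", function(x, value) standardGeneric("nModesRetained<-"))
#' @rdname accessors
#' @export
setMethod("nModesRetained<-", "ShapeAtlas", function(x, value) {
  value <- as.integer(value)
  if (value < 1 || value > ncol(x@modes))
    .stopf("nModesRetained must be between 1 and %d", ncol(x@modes))
  x@nModesRetained <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @description \code{explainedVariance} returns the cumulative fraction of
#'   total variance captured by the first k modes, k = 1..M.
#' @export
setMethod("explainedVariance", "ShapeAtlas", function(x) {
  tot <- sum(x@variances)
  if (tot <= 0) return(rep(0, length(x@variances)))
  cumsum(x@variances) / tot
})

#' @rdname accessors
#' @export
setGeneric("modeBetas", function(x) standardGeneric("modeBetas"))
#' @rdname accessors
#' @export
setMethod("modeBetas", "MorphometricMode", function(x) x@betaPerMode)

#' @rdname accessors
#' @export
setGeneric("displacementVector", function(x) standardGeneric("displacementVector"))
#' @rdname accessors
#' @export
setMethod("displacementVector", "MorphometricMode", function(x) x@displacement)

setMethod("show", "VelocityField", function(object) {
  d <- dim(object@values)
  cat(sprintf("VelocityField: %d x %d x %d grid, %d frame(s)\n", d[1], d[2], d[3], d[5]))
  cat(sprintf("  spacing %s mm | frame %.1f ms | VENC %.0f cm/s\n",
              paste(format(object@spacing, digits = 3), collapse = " x "),
              object@frameDuration, object@venc))
  if (length(object@diastoleFrames))
    cat(sprintf("  diastole frames: %d..%d\n",
                min(object@diastoleFrames), max(object@diastoleFrames)))
})

setMethod("show", "VorticityField", function(object) {
  d <- dim(object@vectors)
  cat(sprintf("VorticityField: %d x %d x %d grid, frame %d\n",
              d[1], d[2], d[3], object@frame))
  cat(sprintf("  |curl| range %.3g .. %.3g 1/s\n",
              min(object@magnitude), max(object@magnitude)))
})

setMethod("show", "BiventricularShape", function(object) {
  cat(sprintf("BiventricularShape: %d corresponded points (ED + ES)\n",
              nrow(object@pointsED)))
  tb <- table(object@labels)
  cat("  ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n", sep = "")
  cat(sprintf("  %d closed surface(s): %s\n", length(object@faces),
              paste(names(object@faces), collapse = ", ")))
})

setMethod("show", "ShapeAtlas", function(object) {
  cat(sprintf("ShapeAtlas: P=%d points, %d mode(s), K=%d retained\n",
              object@P, ncol(object@modes), object@nModesRetained))
  if (ncol(object@modes)) {
    ev <- explainedVariance(object)
    k <- max(1L, object@nModesRetained)
    cat(sprintf("  first %d mode(s) explain %.1f%% of variance\n",
                k, 100 * ev[min(k, length(ev))]))
  }
})

setMethod("show", "MorphometricMode", function(object) {
  cat(sprintf("MorphometricMode for predictor '%s' (%d modes)\n",
              object@predictorName, length(object@betaPerMode)))
  cat(sprintf("  |displacement| = %.2f mm per +1 SD of predictor\n",
              sqrt(sum(object@displacement^2))))
})
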