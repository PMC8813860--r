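# Vorticity quantification: curl of the velocity field, spherical-ROI
# summaries over diastolic windows, BSA indexing, and ROI boundary
# sensitivity.
#
# Difference stencil: central differences on interior voxels (exact for
# linear velocity fields), one-sided first differences on the boundary
# slabs. Spacing is converted mm -> cm so that cm/s velocities give 1/s
# vorticity.

#' Compute the curl (vorticity) field at one frame
#'
#' \deqn{\omega = \nabla \times v}
#' evaluated by finite differences (central in the interior, one-sided at
#' the grid boundary). Returns both the curl vectors and their magnitudes.
#'
#' @param field a [VelocityField-class].
#' @param frame frame index.
#' @return A [VorticityField-class].
#' @export
computeCurlField <- function(field, frame) {
  stopifnot(is(field, "VelocityField"))
  d <- dim(field@values)
  if (frame < 1 || frame > d[5]) .stopf("frame %d outside 1..%d", frame, d[5])
  if (any(d[1:3] < 3)) .stopf("every axis needs at least 3 voxels for curl")
  h <- field@spacing / 10  # mm -> cm
  vx <- field@values[, , , 1, frame]
  vy <- field@values[, , , 2, frame]
  vz <- field@values[, , , 3, frame]
  wx <- .ddAxis(vz, 2, h[2]) - .ddAxis(vy, 3, h[3])
  wy <- .ddAxis(vx, 3, h[3]) - .ddAxis(vz, 1, h[1])
  wz <- .ddAxis(vy, 1, h[1]) - .ddAxis(vx, 2, h[2])
  vec <- array(c(wx, wy, wz), dim = c(d[1:3], 3))
  mag <- sqrt(wx^2 + wy^2 + wz^2)
  new("VorticityField", vectors = vec, magnitude = mag,
      frame = as.integer(frame), spacing = field@spacing)
}

#' Define a spherical region of interest
#'
#' @param center mm point (grid coordinates: voxel i sits at (i-1)*spacing).
#' @param radius mm (> 0).
#' @param region one of \code{"RV_cavity"}, \code{"tricuspid_inflow"},
#'   \code{"RVOT"}.
#' @return A list of class \code{"SphericalROI"}.
#' @export
sphericalROI <- function(center, radius,
                         region = c("RV_cavity", "tricuspid_inflow", "RVOT")) {
  region <- match.arg(region)
  if (radius <= 0) .stopf("radius must be positive")
  structure(list(center = as.numeric(center), radius = radius, region = region),
            class = "SphericalROI")
}

# Linear indices of voxels whose centers lie within the ROI sphere.
.roiVoxels <- function(dims, spacing, roi, extra_mm = 0) {
  co <- .coordArrays(dims, spacing)
  d2 <- (co$x - roi$center[1])^2 + (co$y - roi$center[2])^2 +
    (co$z - roi$center[3])^2
  which(d2 <= (roi$radius + extra_mm)^2)
}

#' Summarize vorticity magnitude over a spherical ROI
#'
#' A voxel belongs to the ROI iff its center lies within the sphere (no
#' partial-volume weighting). Per frame, the vorticity magnitudes of the ROI
#' voxels are summed and averaged; the mean is the sum divided by the ROI
#' voxel count, exactly.
#'
#' @param fields a list of [VorticityField-class] objects (one per frame),
#'   or a single one.
#' @param roi a \code{"SphericalROI"}.
#' @return A list of class \code{"VorticitySummary"}: \code{frames},
#'   \code{per_frame_sum}, \code{per_frame_mean} (1/s), \code{n_voxels},
#'   \code{roi}.
#' @export
summarizeRoiVorticity <- function(fields, roi) {
  if (is(fields, "VorticityField")) fields <- list(fields)
  stopifnot(length(fields) >= 1, inherits(roi, "SphericalROI"))
  dims <- dim(fields[[1]]@magnitude)
  spacing <- fields[[1]]@spacing
  vox <- .roiVoxels(dims, spacing, roi)
  if (!length(vox)) .stopf("ROI contains no voxel centers")
  sums <- vapply(fields, function(f) {
    if (!identical(dim(f@magnitude), dims)) .stopf("fields have differing grids")
    sum(f@magnitude[vox])
  }, numeric(1))
  frames <- vapply(fields, function(f) f@frame, integer(1))
  structure(list(frames = frames, per_frame_sum = sums,
                 per_frame_mean = sums / length(vox),
                 n_voxels = length(vox), roi = roi),
            class = "VorticitySummary")
}

#' Windowed diastolic average of per-frame vorticity
#'
#' Averages (and maximizes) per-frame values over the overlapping-timeframe
#' window \code{[central - half_width, central + half_width]} intersected
#' with the declared diastolic frames; the window truncates at the diastole
#' edges. The maximum is taken over the per-frame values inside the window.
#'
#' @param summary a \code{"VorticitySummary"} (its \code{per_frame_mean} is
#'   used) or a plain numeric vector of per-frame values.
#' @param central_frame central frame index (must be diastolic).
#' @param half_width frames on each side (default 2).
#' @param diastole_frames diastolic frame indices; required when
#'   \code{summary} is a plain vector without frame bookkeeping.
#' @param frames frame indices matching \code{summary} when it is a plain
#'   vector (default \code{seq_along(summary)}).
#' @return \code{list(windowed_mean, windowed_max, frames_used)}.
#' @export
windowedDiastolicAverage <- function(summary, central_frame, half_width = 2,
                                     diastole_frames = NULL, frames = NULL) {
  if (inherits(summary, "VorticitySummary")) {
    values <- summary$per_frame_mean
    frames <- summary$frames
  } else {
    values <- as.numeric(summary)
    frames <- frames %||% seq_along(values)
  }
  diastole_frames <- diastole_frames %||% frames
  if (!central_frame %in% diastole_frames)
    .stopf("central_frame %d is not within the diastolic frames", central_frame)
  window <- (central_frame - half_width):(central_frame + half_width)
  use <- frames[frames %in% intersect(window, diastole_frames)]
  if (!length(use)) .stopf("empty diastolic window")
  v <- values[match(use, frames)]
  list(windowed_mean = mean(v), windowed_max = max(v), frames_used = use)
}

#' Index a vorticity value by body surface area
#'
#' The reporting convention for vorticity divides by BSA and by 100, i.e.
#' values are in (1/s)/100 per m^2.
#'
#' @param value vorticity in 1/s.
#' @param bsa body surface area, m^2 (> 0).
#' @return Indexed value, (1/s)/100 per m^2.
#' @examples
#' indexVorticity(10, 2)  # 0.05
#' @export
indexVorticity <- function(value, bsa) {
  if (any(bsa <= 0)) .stopf("bsa must be positive")
  value / bsa / 100
}

#' ROI boundary sensitivity (leakage check)
#'
#' Recomputes the ROI vorticity sum (accumulated over the supplied frames)
#' with the sphere radius dilated by \code{dilation_mm}, and returns the
#' percent difference \code{100 * |sum_dilated - sum| / sum}. Validates that
#' flow outside the nominal boundary contributes negligibly. Returns NA with
#' a warning when the baseline sum is zero.
#'
#' @param fields list of [VorticityField-class] objects (or one).
#' @param roi a \code{"SphericalROI"}.
#' @param dilation_mm non-negative dilation of the radius, mm.
#' @return Percent difference (non-negative scalar), or NA.
#' @export
roiBoundarySensitivity <- function(fields, roi, dilation_mm) {
  if (dilation_mm < 0) .stopf("dilation_mm must be non-negative")
  if (is(fields, "VorticityField")) fields <- list(fields)
  dims <- dim(fields[[1]]@magnitude)
  spacing <- fields[[1]]@spacing
  v0 <- .roiVoxels(dims, spacing, roi)
  v1 <- .roiVoxels(dims, spacing, roi, extra_mm = dilation_mm)
  s0 <- sum(vapply(fields, function(f) sum(f@magnitude[v0]), numeric(1)))
  s1 <- sum(vapply(fields, function(f) sum(f@magnitude[v1]), numeric(1)))
  if (s0 == 0) {
    .warnf("baseline ROI vorticity sum is zero; sensitivity undefined")
    return(NA_real_)
  }
  100 * abs(s1 - s0) / s0
}
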