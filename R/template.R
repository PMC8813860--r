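# Parametric biventricular template.
#
# The template is a two-chamber idealization: LV endo/epi as capped half
# ellipsoids (apex down, base plane z = 0), RV endo/epi as capped half
# ellipsoids with an azimuthal radius modulation producing a crescent-like
# cross section wrapped around the LV, and the four valve annuli as labeled
# point loops. Correspondence (fixed point ordering) holds by construction,
# and the closed-form ellipsoid volume gives an analytic check on the mesh
# volume integrator.

# --- triangulation helpers --------------------------------------------------

# Stitch two closed rings of (possibly different) sizes into a triangle band.
# idxA/idxB are global vertex indices in ring order. Advances the pointer on
# whichever ring lags in fractional arc position; yields nA + nB triangles.
.stitchRings <- function(idxA, idxB) {
  nA <- length(idxA); nB <- length(idxB)
  tris <- matrix(0L, nA + nB, 3)
  i <- 0L; j <- 0L; t <- 0L
  while (i < nA || j < nB) {
    t <- t + 1L
    advanceA <- i < nA && (j >= nB || (i + 1) / nA <= (j + 1) / nB)
    a0 <- idxA[(i %% nA) + 1L]; b0 <- idxB[(j %% nB) + 1L]
    if (advanceA) {
      a1 <- idxA[((i + 1L) %% nA) + 1L]
      tris[t, ] <- c(a0, a1, b0)
      i <- i + 1L
    } else {
      b1 <- idxB[((j + 1L) %% nB) + 1L]
      tris[t, ] <- c(a0, b1, b0)
      j <- j + 1L
    }
  }
  tris
}

# Signed volume (mm^3) of a triangle mesh via the divergence theorem
# (sum of signed tetrahedra against the origin).
.signedMeshVolume <- function(points, faces) {
  p1 <- points[faces[, 1], , drop = FALSE]
  p2 <- points[faces[, 2], , drop = FALSE]
  p3 <- points[faces[, 3], , drop = FALSE]
  det3 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  sum(det3) / 6
}

# TRUE iff every undirected edge is shared by exactly two faces with opposite
# directions (closed, consistently oriented 2-manifold).
.isClosedOriented <- function(faces) {
  he <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  rkey <- paste(he[, 2], he[, 1])
  if (anyDuplicated(key)) return(FALSE)
  all(key %in% rkey)
}

# Capped half-ellipsoid surface with exactly n points.
# center (mm), semi = c(a, b, c): apex at z = center_z - c, base rim in the
# plane z = center_z, closed by a flat cap fan. radiusMod(theta) scales the
# in-plane radius azimuthally (crescent modulation). Returns points (n x 3)
# and locally-indexed faces, oriented outward.
.cappedHalfEllipsoid <- function(n, center, semi, radiusMod = function(theta) rep(1, length(theta))) {
  if (n < 8) .stopf("surface needs at least 8 points")
  nRows <- max(3L, as.integer(round(sqrt((n - 2) / 2))))
  base <- (n - 2L) %/% nRows
  extra <- (n - 2L) %% nRows
  counts <- rep(base, nRows) + c(rep(1L, extra), rep(0L, nRows - extra))
  apex <- center + c(0, 0, -semi[3])
  pts <- matrix(0, n, 3)
  pts[1, ] <- apex
  ringIdx <- vector("list", nRows)
  row <- 1L
  for (r in seq_len(nRows)) {
    phi <- r * (pi / 2) / nRows
    m <- counts[r]
    th <- 2 * pi * (seq_len(m) - 1) / m
    f <- radiusMod(th)
    ringIdx[[r]] <- (row + 1L):(row + m)
    pts[ringIdx[[r]], ] <- cbind(center[1] + semi[1] * f * sin(phi) * cos(th),
                                 center[2] + semi[2] * f * sin(phi) * sin(th),
                                 center[3] - semi[3] * cos(phi))
    row <- row + m
  }
  baseCenterIdx <- n
  pts[baseCenterIdx, ] <- center
  faces <- list()
  m1 <- counts[1]
  faces[[1]] <- cbind(1L, ringIdx[[1]][(seq_len(m1) %% m1) + 1L], ringIdx[[1]])
  for (r in seq_len(nRows - 1L))
    faces[[r + 1L]] <- .stitchRings(ringIdx[[r]], ringIdx[[r + 1L]])
  mL <- counts[nRows]
  faces[[nRows + 1L]] <- cbind(ringIdx[[nRows]],
                               ringIdx[[nRows]][(seq_len(mL) %% mL) + 1L],
                               baseCenterIdx)
  faces <- do.call(rbind, faces)
  # Orient outward: signed volume about the surface centroid must be positive.
  centered <- sweep(pts, 2, colMeans(pts))
  if (.signedMeshVolume(centered, faces) < 0) faces <- faces[, c(1, 3, 2)]
  list(points = pts, faces = faces)
}

# Closed loop of m points: circle of given radius about `center` in the plane
# with unit normal `normal`.
.ringLoop <- function(m, center, radius, normal = c(0, 0, 1)) {
  nrm <- normal / sqrt(sum(normal^2))
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  th <- 2 * pi * (seq_len(m) - 1) / m
  sweep(radius * (cos(th) %o% e1 + sin(th) %o% e2), 2, center, `+`)
}

# Template geometry constants (mm). LV long axis along z through the origin;
# RV crescent centered at x = +50 wrapped toward the LV.
.templateGeom <- list(
  lv_endo = list(center = c(0, 0, 0), semi = c(25, 25, 45)),
  lv_epi  = list(center = c(0, 0, 0), semi = c(33, 33, 53)),
  rv_endo = list(center = c(50, 0, 0), semi = c(26, 36, 42), crescent = 0.35),
  rv_epi  = list(center = c(50, 0, 0), semi = c(30, 40, 46), crescent = 0.35),
  rings = list(
    mitral_ring    = list(center = c(-8, 0, 0),   radius = 14, normal = c(0, 0, 1)),
    aortic_ring    = list(center = c(12, 8, 2),   radius = 10, normal = c(0.2, 0, 1)),
    tricuspid_ring = list(center = c(50, 14, 0),  radius = 15, normal = c(0, 0.15, 1)),
    pulmonary_ring = list(center = c(50, -20, 2), radius = 10, normal = c(0, -0.2, 1))
  ),
  lv_axis_xy = c(0, 0), rv_axis_xy = c(50, 0),
  lv_contraction = 0.65, rv_contraction = 0.78
)

#' Generate the deterministic biventricular template shape
#'
#' Builds a parametric two-chamber template: LV endocardial and epicardial
#' surfaces as capped half ellipsoids, RV surfaces as crescent-modulated
#' half ellipsoids wrapped around the LV, and the four valve annuli as
#' labeled point loops. End systole is a uniform radial contraction of each
#' chamber's points toward its long axis (distinct contraction per chamber),
#' so correspondence holds by construction and chamber volumes have closed
#' forms. Two calls with the same arguments are bit-identical.
#'
#' @param points_per_surface points on each of the four chamber surfaces
#'   (minimum 50). Total point count is
#'   \code{4 * points_per_surface + 4 * ring_size}.
#' @param ring_size points per annulus loop.
#' @return A [BiventricularShape-class] object.
#' @examples
#' tpl <- generateTemplateShape(120)
#' nPoints(tpl)
#' @export
generateTemplateShape <- function(points_per_surface = 120, ring_size = 24) {
  if (points_per_surface < 50)
    .stopf("points_per_surface must be at least 50 (got %d)", points_per_surface)
  if (ring_size < 6) .stopf("ring_size must be at least 6")
  g <- .templateGeom
  crescent <- function(amp) function(th) 1 + amp * cos(th)  # smaller toward -x (LV side at theta = pi)
  surf <- list(
    LV_endo = .cappedHalfEllipsoid(points_per_surface, g$lv_endo$center, g$lv_endo$semi),
    LV_epi  = .cappedHalfEllipsoid(points_per_surface, g$lv_epi$center,  g$lv_epi$semi),
    RV_endo = .cappedHalfEllipsoid(points_per_surface, g$rv_endo$center, g$rv_endo$semi,
                                   crescent(g$rv_endo$crescent)),
    RV_epi  = .cappedHalfEllipsoid(points_per_surface, g$rv_epi$center,  g$rv_epi$semi,
                                   crescent(g$rv_epi$crescent))
  )
  pts <- do.call(rbind, lapply(surf, `[[`, "points"))
  labels <- rep(names(surf), each = points_per_surface)
  faces <- list()
  offset <- 0L
  for (nm in names(surf)) {
    f <- surf[[nm]]$faces + offset
    storage.mode(f) <- "integer"
    dimnames(f) <- NULL
    faces[[nm]] <- f
    offset <- offset + as.integer(points_per_surface)
  }
  for (nm in c("tricuspid_ring", "mitral_ring", "pulmonary_ring", "aortic_ring")) {
    r <- g$rings[[nm]]
    pts <- rbind(pts, .ringLoop(ring_size, r$center, r$radius, r$normal))
    labels <- c(labels, rep(nm, ring_size))
  }
  rownames(pts) <- NULL
  # ES: uniform radial contraction toward each chamber's long axis.
  lvPart <- labels %in% c("LV_endo", "LV_epi", "mitral_ring", "aortic_ring")
  es <- pts
  es[lvPart, 1:2] <- sweep(sweep(pts[lvPart, 1:2, drop = FALSE], 2, g$lv_axis_xy) *
                             g$lv_contraction, 2, g$lv_axis_xy, `+`)
  es[!lvPart, 1:2] <- sweep(sweep(pts[!lvPart, 1:2, drop = FALSE], 2, g$rv_axis_xy) *
                              g$rv_contraction, 2, g$rv_axis_xy, `+`)
  shape <- new("BiventricularShape", pointsED = pts, pointsES = es,
               labels = labels, faces = faces)
  stopifnot(all(vapply(faces, .isClosedOriented, logical(1))))
  shape
}

#' Enclosed volume of a closed triangle surface
#'
#' Volume by the divergence theorem: the sum of signed tetrahedra over the
#' triangle list, converted mm^3 to mL. The surface must be closed and
#' consistently oriented; an open surface (a boundary edge) is an error.
#'
#' @param points P x 3 coordinate matrix (mm).
#' @param faces nFace x 3 integer index matrix.
#' @return Enclosed volume in mL (positive for outward orientation).
#' @export
enclosedVolume <- function(points, faces) {
  if (!.isClosedOriented(faces))
    .stopf("surface is open or inconsistently oriented (boundary edges present)")
  .signedMeshVolume(points, faces) / 1000
}

#' Flatten / rebuild the concatenated shape vector
#'
#' `shapeToVector` packs a shape into the length-6P vector used by the atlas:
#' ED coordinates (x1 y1 z1 x2 ...) followed by ES coordinates.
#' `vectorToShape` is its inverse given the topology (labels and faces) of a
#' reference shape.
#'
#' @param shape a [BiventricularShape-class].
#' @return `shapeToVector`: numeric length-6P; `vectorToShape`: a
#'   [BiventricularShape-class].
#' @export
shapeToVector <- function(shape) {
  c(as.numeric(t(shape@pointsED)), as.numeric(t(shape@pointsES)))
}

#' @rdname shapeToVector
#' @param v numeric length-6P concatenated coordinate vector.
#' @param reference a [BiventricularShape-class] or [ShapeAtlas-class]
#'   supplying labels and faces.
#' @export
vectorToShape <- function(v, reference) {
  labels <- pointLabels(reference)
  faces <- shapeFaces(reference)
  P <- length(labels)
  if (length(v) != 6 * P) .stopf("vector length %d does not match 6P = %d", length(v), 6 * P)
  ed <- matrix(v[seq_len(3 * P)], ncol = 3, byrow = TRUE)
  es <- matrix(v[3 * P + seq_len(3 * P)], ncol = 3, byrow = TRUE)
  new("BiventricularShape", pointsED = ed, pointsES = es,
      labels = labels, faces = faces)
}
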