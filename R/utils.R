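# Internal helpers shared across modules.
#
# Conventions (units contract):
#   positions/spacings  mm
#   velocities          cm/s
#   vorticity           1/s   (spacing is converted mm -> cm inside curl)
#   volumes             mL
#   frame duration      ms

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible sub-stream seed
#'
#' One root seed drives every generator; per-subject / per-frame substreams are
#' derived so that subsetting a population does not reshuffle the remaining
#' draws. The derived seed always fits a 32-bit integer.
#'
#' @param root integer root seed.
#' @param stream non-negative integer stream index.
#' @return An integer seed.
#' @export
subSeed <- function(root, stream) {
  root <- as.numeric(root); stream <- as.numeric(stream)
  as.integer((abs(root) * 48271 + stream * 92821 + 1) %% 2147483647)
}

# Axis coordinates of voxel centers: voxel i (1-based) sits at (i-1)*spacing mm.
.axisCoords <- function(n, spacing) (seq_len(n) - 1) * spacing

# Grid center in mm for a (nx,ny,nz) lattice.
.gridCenter <- function(dims, spacing) (dims - 1) / 2 * spacing

# Full coordinate arrays (mm) for a lattice; returns list of 3 arrays.
.coordArrays <- function(dims, spacing) {
  cx <- .axisCoords(dims[1], spacing[1])
  cy <- .axisCoords(dims[2], spacing[2])
  cz <- .axisCoords(dims[3], spacing[3])
  list(
    x = array(rep(cx, times = dims[2] * dims[3]), dim = dims),
    y = array(rep(rep(cy, each = dims[1]), times = dims[3]), dim = dims),
    z = array(rep(cz, each = dims[1] * dims[2]), dim = dims)
  )
}

# Rotation matrix about a unit axis (Rodrigues), angle in radians.
.rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Random rotation with angle uniform in [0, maxDeg] about a uniform axis.
.randomRotation <- function(maxDeg) {
  if (maxDeg <= 0) return(diag(3))
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, 0, maxDeg) * pi / 180
  .rotationMatrix(ax, ang)
}

# Principal angles (degrees) between the column spaces of A and B.
# Standard cosine-of-singular-values formulation on orthonormalized bases.
.principalAngles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

# Optimal rigid transform (rotation + translation, det(R) = +1, no scaling)
# mapping point set A onto B: B ~ A %*% t(R) + t. Kabsch with reflection guard.
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cb - R %*% ca))
}

.applyRigid <- function(points, R, t) {
  sweep(points %*% t(R), 2, t, `+`)
}

# Trilinear interpolation of a 3-D array at continuous 1-based index positions.
# pts: m x 3 matrix of (i, j, k) index coordinates. Positions must lie within
# [1, dim] on every axis.
.trilinear <- function(arr, pts) {
  d <- dim(arr)
  if (any(pts < 1) || any(sweep(pts, 2, d, `>`)))
    .stopf("interpolation point outside the grid")
  i0 <- pmin(floor(pts[, 1]), d[1] - 1); fi <- pts[, 1] - i0
  j0 <- pmin(floor(pts[, 2]), d[2] - 1); fj <- pts[, 2] - j0
  k0 <- pmin(floor(pts[, 3]), d[3] - 1); fk <- pts[, 3] - k0
  idx <- function(i, j, k) arr[cbind(i, j, k)]
  v000 <- idx(i0,     j0,     k0);     v100 <- idx(i0 + 1, j0,     k0)
  v010 <- idx(i0,     j0 + 1, k0);     v110 <- idx(i0 + 1, j0 + 1, k0)
  v001 <- idx(i0,     j0,     k0 + 1); v101 <- idx(i0 + 1, j0,     k0 + 1)
  v011 <- idx(i0,     j0 + 1, k0 + 1); v111 <- idx(i0 + 1, j0 + 1, k0 + 1)
  (v000 * (1 - fi) + v100 * fi) * (1 - fj) * (1 - fk) +
    (v010 * (1 - fi) + v110 * fi) * fj * (1 - fk) +
    (v001 * (1 - fi) + v101 * fi) * (1 - fj) * fk +
    (v011 * (1 - fi) + v111 * fi) * fj * fk
}

# Dense 1-D Gaussian convolution matrix (n x n), rows renormalized so that the
# truncated kernel sums to one at the boundaries (preserves constants exactly,
# and linear ramps in the interior).
.gaussConvMatrix <- function(n, sd) {
  half <- max(1L, ceiling(4 * sd))
  offs <- (-half):half
  w <- exp(-offs^2 / (2 * sd^2))
  M <- matrix(0, n, n)
  for (r in seq_len(n)) {
    cols <- r + offs
    ok <- cols >= 1 & cols <= n
    M[r, cols[ok]] <- w[ok] / sum(w[ok])
  }
  M
}

# Apply a matrix along one axis of a 3-D array: out = M applied to vectors
# taken along `axis`.
.applyAlongAxis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- M %*% m
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

# Partial derivative of a 3-D scalar array along an axis: central differences
# in the interior, one-sided first differences on the two boundary slabs.
# h is the grid step in the units the caller wants (cm for curl).
.ddAxis <- function(arr, axis, h) {
  n <- dim(arr)[axis]
  if (n < 3) .stopf("axis %d has fewer than 3 voxels; cannot differentiate", axis)
  sl <- function(i) {
    switch(axis,
           `1` = arr[i, , , drop = FALSE],
           `2` = arr[, i, , drop = FALSE],
           `3` = arr[, , i, drop = FALSE])
  }
  out <- array(0, dim = dim(arr))
  mid <- 2:(n - 1)
  assign_ <- function(i, val) {
    if (axis == 1) out[i, , ] <<- val
    else if (axis == 2) out[, i, ] <<- val
    else out[, , i] <<- val
  }
  assign_(mid, (sl(3:n) - sl(1:(n - 2))) / (2 * h))
  assign_(1, (sl(2) - sl(1)) / h)
  assign_(n, (sl(n) - sl(n - 1)) / h)
  out
}
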