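# Shared fixtures, built in code and cached for the run.

.fx <- new.env()

getTemplate <- function(pps = 80, ring = 24) {
  key <- sprintf("tpl_%d_%d", pps, ring)
  if (is.null(.fx[[key]])) .fx[[key]] <- generateTemplateShape(pps, ring)
  .fx[[key]]
}

# Apply a rigid pose to a shape (same pose for ED and ES).
poseShape <- function(shape, R, t) {
  methods::new("BiventricularShape",
               pointsED = sweep(shapePoints(shape, "ED") %*% t(R), 2, t, `+`),
               pointsES = sweep(shapePoints(shape, "ES") %*% t(R), 2, t, `+`),
               labels = pointLabels(shape), faces = shapeFaces(shape))
}

# Independent latitude/longitude sphere mesh (oracle geometry for the volume
# integrator): nPhi interior rings of nTheta points plus two pole vertices.
latLongSphere <- function(radius = 30, nTheta = 60, nPhi = 30, center = c(0, 0, 0)) {
  phi <- seq_len(nPhi) * pi / (nPhi + 1)
  pts <- matrix(0, nPhi * nTheta + 2, 3)
  pts[1, ] <- center + c(0, 0, radius)
  row <- 1L
  for (i in seq_len(nPhi)) {
    th <- 2 * pi * (seq_len(nTheta) - 1) / nTheta
    idx <- (row + 1L):(row + nTheta)
    pts[idx, ] <- cbind(center[1] + radius * sin(phi[i]) * cos(th),
                        center[2] + radius * sin(phi[i]) * sin(th),
                        center[3] + radius * cos(phi[i]))
    row <- row + nTheta
  }
  south <- nPhi * nTheta + 2L
  pts[south, ] <- center + c(0, 0, -radius)
  ringIdx <- function(i) 1L + (i - 1L) * nTheta + seq_len(nTheta)
  faces <- list()
  r1 <- ringIdx(1)
  faces[[1]] <- cbind(1L, r1, r1[c(2:nTheta, 1)])
  for (i in seq_len(nPhi - 1)) {
    a <- ringIdx(i); b <- ringIdx(i + 1)
    a2 <- a[c(2:nTheta, 1)]; b2 <- b[c(2:nTheta, 1)]
    faces[[length(faces) + 1]] <- rbind(cbind(a, b, a2), cbind(a2, b, b2))
  }
  rl <- ringIdx(nPhi)
  faces[[length(faces) + 1]] <- cbind(rl, south, rl[c(2:nTheta, 1)])
  faces <- do.call(rbind, faces)
  storage.mode(faces) <- "integer"
  list(points = pts, faces = faces)
}

# A constant velocity field (for curl-of-constant checks).
constantField <- function(v3, dims = c(12, 12, 12), spacing = 2.4, nFrames = 1) {
  vals <- array(0, dim = c(dims, 3, nFrames))
  for (c_ in 1:3) vals[, , , c_, ] <- v3[c_]
  methods::new("VelocityField", values = vals, spacing = rep(spacing, 3),
               frameDuration = 38.8, venc = 150,
               diastoleFrames = seq_len(nFrames))
}

# Voxel-center distances from a point, in mm, as a flat vector (independent
# bookkeeping for ROI membership oracles).
voxelDistances <- function(dims, spacing, center) {
  cx <- (seq_len(dims[1]) - 1) * spacing[1]
  cy <- (seq_len(dims[2]) - 1) * spacing[2]
  cz <- (seq_len(dims[3]) - 1) * spacing[3]
  g <- expand.grid(x = cx, y = cy, z = cz)
  sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2)
}
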