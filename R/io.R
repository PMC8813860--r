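# File interchange. Point order in mesh files is the correspondence
# contract: writers and readers preserve it exactly.
#
# Shapes: ASCII PLY per phase (vertex x/y/z plus an integer label property,
# triangle faces) with a JSON sidecar mapping label codes to anatomical
# names and face blocks to surfaces. Velocity fields: one NIfTI volume
# (x, y, z, frame, component) plus a JSON sidecar with spacing, frame
# duration, VENC, and the diastolic frame range.

#' Write / read a biventricular shape
#'
#' Writes \code{<id>_ed.ply}, \code{<id>_es.ply}, and \code{<id>_meta.json}
#' (label map and per-surface face ranges) into \code{dir}. The reader
#' reconstructs the shape with the identical point order.
#'
#' @param shape a [BiventricularShape-class].
#' @param dir output directory (created if missing).
#' @param id file stem.
#' @return \code{writeShape}: the file stem path, invisibly;
#'   \code{readShape}: a [BiventricularShape-class].
#' @export
writeShape <- function(shape, dir, id) {
  stopifnot(is(shape, "BiventricularShape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labLevels <- unique(shape@labels)
  labCode <- match(shape@labels, labLevels) - 1L
  allFaces <- do.call(rbind, unname(shape@faces))
  surfaceOf <- rep(names(shape@faces), vapply(shape@faces, nrow, integer(1)))
  writePly <- function(points, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(points)),
                 "property double x", "property double y", "property double z",
                 "property int label",
                 sprintf("element face %d", nrow(allFaces)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(paste(format(points[, 1], digits = 17, scientific = TRUE, trim = TRUE),
                     format(points[, 2], digits = 17, scientific = TRUE, trim = TRUE),
                     format(points[, 3], digits = 17, scientific = TRUE, trim = TRUE),
                     labCode), con)
    writeLines(paste(3L, allFaces[, 1] - 1L, allFaces[, 2] - 1L, allFaces[, 3] - 1L), con)
  }
  writePly(shape@pointsED, file.path(dir, paste0(id, "_ed.ply")))
  writePly(shape@pointsES, file.path(dir, paste0(id, "_es.ply")))
  meta <- list(label_map = as.list(stats::setNames(seq_along(labLevels) - 1L, labLevels)),
               face_surfaces = surfaceOf)
  jsonlite::write_json(meta, file.path(dir, paste0(id, "_meta.json")), auto_unbox = TRUE)
  invisible(file.path(dir, id))
}

#' @rdname writeShape
#' @export
readShape <- function(dir, id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(id, "_meta.json")),
                              simplifyVector = TRUE)
  readPly <- function(path) {
    lines <- readLines(path)
    endHdr <- which(lines == "end_header")
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
    vtx <- utils::read.table(text = lines[(endHdr + 1):(endHdr + nv)])
    fc <- utils::read.table(text = lines[(endHdr + nv + 1):(endHdr + nv + nf)])
    list(points = as.matrix(vtx[, 1:3]), labelCode = vtx[, 4],
         faces = as.matrix(fc[, 2:4]) + 1L)
  }
  ed <- readPly(file.path(dir, paste0(id, "_ed.ply")))
  es <- readPly(file.path(dir, paste0(id, "_es.ply")))
  codeToLabel <- names(meta$label_map)[order(unlist(meta$label_map))]
  labels <- codeToLabel[ed$labelCode + 1L]
  surfaceOf <- meta$face_surfaces
  faces <- lapply(split(seq_len(nrow(ed$faces)), surfaceOf),
                  function(i) {
                    m <- ed$faces[i, , drop = FALSE]
                    storage.mode(m) <- "integer"
                    dimnames(m) <- NULL
                    m
                  })
  faces <- faces[unique(surfaceOf)]
  pe <- ed$points; dimnames(pe) <- NULL
  ps <- es$points; dimnames(ps) <- NULL
  new("BiventricularShape", pointsED = pe, pointsES = ps,
      labels = labels, faces = faces)
}

#' Write / read a velocity field
#'
#' Stores the lattice as a 5-D NIfTI volume (x, y, z, frame, component) in
#' double precision with the voxel spacing in the header, plus a JSON
#' sidecar \code{{spacing_mm, frame_duration_ms, venc_cms, diastole_frames}}.
#'
#' @param field a [VelocityField-class].
#' @param path NIfTI file path (e.g. \code{flow.nii.gz}); the sidecar is
#'   written next to it with a \code{.json} suffix.
#' @return \code{writeVelocityField}: the path, invisibly;
#'   \code{readVelocityField}: a [VelocityField-class].
#' @export
writeVelocityField <- function(field, path) {
  stopifnot(is(field, "VelocityField"))
  arr <- aperm(field@values, c(1, 2, 3, 5, 4))  # components last (NIfTI 5th dim)
  img <- RNifti::asNifti(arr, pixdim = c(field@spacing, 1, 1), datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  sidecar <- list(spacing_mm = field@spacing,
                  frame_duration_ms = field@frameDuration,
                  venc_cms = field@venc,
                  diastole_frames = field@diastoleFrames)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeVelocityField
#' @export
readVelocityField <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- aperm(array(as.numeric(img), dim = dim(img)), c(1, 2, 3, 5, 4))
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("VelocityField", values = arr, spacing = as.numeric(sc$spacing_mm),
      frameDuration = as.numeric(sc$frame_duration_ms),
      venc = as.numeric(sc$venc_cms),
      diastoleFrames = as.integer(sc$diastole_frames))
}
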