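#' Read a NIfTI volume
#'
#' @param path NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @param intensityScale Tag to attach (`"raw"` default).
#' @return An [MRAVolume-class] with spacing taken from the header.
#' @export
readVolume <- function(path, intensityScale = "raw") {
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  if (length(pix) < 3 || any(!is.finite(pix[1:3])) || any(pix[1:3] <= 0))
    stop("NIfTI header has invalid pixdim (voxel spacing)")
  dat <- array(as.numeric(img), dim = dim(img))
  if (length(dim(dat)) != 3) stop("expected a 3D NIfTI volume")
  MRAVolume(dat, pix[1:3], intensityScale = intensityScale)
}

#' Write a volume or mask as NIfTI
#'
#' Volumes are stored as 64-bit float (bit-exact round trip); masks as
#' unsigned 8-bit with values 0/1.
#'
#' @param v An [MRAVolume-class] or [VesselMask-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(v, path) {
  isMask <- is(v, "VesselMask")
  dat <- if (isMask) array(as.integer(imgData(v)), dim = dim(imgData(v)))
         else imgData(v)
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- spacing(v)
  RNifti::writeNifti(img, path,
                     datatype = if (isMask) "uint8" else "double")
  invisible(path)
}

#' Write branch tracks as JSON
#'
#' @param branchList List of [BranchTrack-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeBranchesJSON <- function(branchList, path) {
  payload <- lapply(branchList, function(b) {
    x <- list(id = b@id, order = b@order,
              parent = if (is.na(b@parent)) NULL else b@parent,
              parentPoint = if (is.na(b@parentPoint)) NULL else b@parentPoint,
              provenance = b@provenance,
              points = unname(apply(b@points, 1, as.numeric,
                                    simplify = FALSE)),
              radii = b@radii)
    Filter(Negate(is.null), x)   # absent key, not {}
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read branch tracks from JSON
#'
#' @param path JSON file written by [writeBranchesJSON()].
#' @return List of [BranchTrack-class].
#' @export
readBranchesJSON <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(x) {
    BranchTrack(do.call(rbind, lapply(x$points, unlist)),
                unlist(x$radii),
                parent = x$parent %||% NA_integer_,
                parentPoint = x$parentPoint %||% NA_integer_,
                order = x$order, id = x$id, provenance = x$provenance)
  })
}

#' Write centerlines as VTK legacy polylines
#'
#' @param branchList List of [BranchTrack-class] (polylines from the raw
#'   points) or a [VesselModel-class] (polylines from sampled Beziers).
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
writeCenterlinesVTK <- function(branchList, path) {
  if (is(branchList, "VesselModel")) {
    lines <- lapply(branchList@centerlines,
                    function(cl) sampleCenterline(cl, 16L)$points)
  } else {
    lines <- lapply(branchList, function(b) b@points)
  }
  allPts <- do.call(rbind, lines)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel centerlines", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(allPts))), con)
  writeLines(apply(allPts, 1, function(p) paste(signif(p, 8), collapse = " ")),
             con)
  sizes <- vapply(lines, nrow, integer(1))
  writeLines(sprintf("LINES %d %d", length(lines),
                     sum(sizes) + length(lines)), con)
  off <- 0L
  for (s in sizes) {
    writeLines(paste(c(s, off:(off + s - 1)), collapse = " "), con)
    off <- off + s
  }
  invisible(path)
}

#' Write tube meshes as VTK legacy PolyData
#'
#' @param meshes Mesh list from [exportTubeMesh()].
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
writeMeshVTK <- function(meshes, path) {
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  scal <- unlist(lapply(meshes, `[[`, "scalars"))
  offs <- cumsum(c(0, head(vapply(meshes, function(m) nrow(m$vertices),
                                  integer(1)), -1)))
  tris <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$triangles + offs[i]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel tubes", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(verts))), con)
  writeLines(apply(verts, 1, function(p) paste(signif(p, 8), collapse = " ")),
             con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tris), 4L * nrow(tris)), con)
  writeLines(apply(tris - 1L, 1, function(t) paste(c(3L, t), collapse = " ")),
             con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(verts)),
               "SCALARS diameter float 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(signif(scal, 8)), con)
  invisible(path)
}

#' Maximum-intensity projection with optional overlay
#'
#' @param v An [MRAVolume-class].
#' @param axis Projection axis, 1-3 or `"x"`, `"y"`, `"z"`.
#' @param overlay Optional [VesselMask-class] to overlay in red.
#' @return Either a matrix (no overlay) normalized to [0, 1], or an
#'   H x W x 3 RGB array.
#' @export
renderMIP <- function(v, axis = 3, overlay = NULL) {
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  stopifnot(axis %in% 1:3)
  mip <- apply(imgData(v), setdiff(1:3, axis), max)
  rng <- range(mip)
  mipN <- if (diff(rng) > 0) (mip - rng[1]) / diff(rng) else mip * 0
  if (is.null(overlay)) return(mipN)
  om <- apply(imgData(overlay), setdiff(1:3, axis), max) > 0
  rgb <- array(rep(mipN, 3), dim = c(dim(mipN), 3))
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  r[om] <- 1; g[om] <- 0.2 * g[om]; b[om] <- 0.2 * b[om]
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  rgb
}

#' Write a MIP image as PNG
#'
#' @param mip Output of [renderMIP()].
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
writeMIP <- function(mip, path) {
  png::writePNG(clamp(mip, 0, 1), path)
  invisible(path)
}

#' Write segmentation metrics as JSON
#'
#' @param m A [SegMetrics-class].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
writeSegMetricsJSON <- function(m, path) {
  jsonlite::write_json(list(tp = m@tp, fp = m@fp, fn = m@fn, tn = m@tn,
                            dsc = m@dsc, hd = m@hd, fpRate = m@fpRate,
                            fnRate = m@fnRate),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write tube meshes as ASCII PLY
#'
#' The per-vertex diameter is stored in a `diameter` property.
#'
#' @param meshes Mesh list from [exportTubeMesh()].
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
writeMeshPLY <- function(meshes, path) {
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  scal <- unlist(lapply(meshes, `[[`, "scalars"))
  offs <- cumsum(c(0, head(vapply(meshes, function(m) nrow(m$vertices),
                                  integer(1)), -1)))
  tris <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$triangles + offs[i]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(verts)),
               "property float x", "property float y", "property float z",
               "property float diameter",
               sprintf("element face %d", nrow(tris)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(signif(verts[, 1], 8), signif(verts[, 2], 8),
                   signif(verts[, 3], 8), signif(scal, 8)), con)
  writeLines(paste(3L, tris[, 1] - 1L, tris[, 2] - 1L, tris[, 3] - 1L), con)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; every recognized key is passed through the
#' validating constructors.
#'
#' @param path YAML file path.
#' @return A [pipelineConfig()].
#' @export
pipelineConfigFromYAML <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "workingResolution", "probThreshold", "patchSize",
             "preprocess", "interval", "spcnn", "tracking", "forest",
             "screening", "cnnCheckpoint", "forestCheckpoint")
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("unknown pipeline config keys: ", paste(extra, collapse = ", "))
  args <- list()
  for (nm in c("seed", "workingResolution", "probThreshold", "patchSize",
               "cnnCheckpoint", "forestCheckpoint"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$preprocess))
    args$preprocess <- do.call(preprocessConfig, y$preprocess)
  if (!is.null(y$interval)) args$interval <- do.call(intensityInterval,
                                                     y$interval)
  if (!is.null(y$spcnn)) args$spcnn <- do.call(spcnnConfig, y$spcnn)
  if (!is.null(y$tracking)) args$tracking <- do.call(trackingConfig,
                                                     y$tracking)
  if (!is.null(y$forest)) args$forest <- do.call(stepForestConfig, y$forest)
  if (!is.null(y$screening)) args$screening <- do.call(screeningConfig,
                                                       y$screening)
  do.call(pipelineConfig, args)
}

#' Write the morphometry table as CSV
#'
#' @param tab Data frame from [morphometry()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeMorphometryCSV <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
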