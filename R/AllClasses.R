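#' MRAVolume: a 3D scalar image with voxel spacing
#'
#' The universal raster carrier of the package: a 3D array of intensities plus
#' per-axis voxel spacing (mm), a physical origin (mm), and a tag recording
#' whether intensities are on the raw acquisition scale or the standardized
#' 0-255 scale on which the pre-screening thresholds (80, 120) are defined.
#'
#' Physical coordinates follow `origin + (index - 1) * spacing` with 1-based
#' voxel indices and no direction cosines (axis-aligned grids only).
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @slot origin Numeric length-3, mm offset of voxel (1,1,1).
#' @slot intensityScale `"raw"` or `"standardized"`.
#' @export
setClass("MRAVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 intensityScale = "character"),
  validity = function(object) {
    if (length(dim(object@data)) != 3) return("data must be a 3D array")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    if (length(object@origin) != 3) return("origin must have length 3")
    if (!all(is.finite(object@data))) return("data must be finite")
    if (!object@intensityScale %in% c("raw", "standardized"))
      return("intensityScale must be 'raw' or 'standardized'")
    TRUE
  })

#' Construct an MRAVolume
#'
#' @param data 3D numeric array.
#' @param spacing Voxel spacing in mm (length 1 recycled or length 3).
#' @param origin Physical origin in mm.
#' @param intensityScale `"raw"` (default) or `"standardized"`.
#' @return An [MRAVolume-class] object.
#' @export
MRAVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      intensityScale = "raw") {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  new("MRAVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), intensityScale = intensityScale)
}

#' VesselMask: a binary grid aligned to a volume
#'
#' @slot mask 3D logical array (TRUE = vessel).
#' @slot spacing Numeric length-3, mm.
#' @slot origin Numeric length-3, mm.
#' @export
setClass("VesselMask",
  representation(mask = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@mask)) != 3) return("mask must be a 3D array")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    TRUE
  })

#' Construct a VesselMask
#'
#' @param mask 3D logical (or coercible) array.
#' @param spacing Voxel spacing in mm.
#' @param origin Physical origin in mm.
#' @return A [VesselMask-class] object.
#' @export
VesselMask <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  m <- array(as.logical(mask), dim = dim(mask))
  new("VesselMask", mask = m, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' BranchTrack: an ordered traced centerline with radii and tree linkage
#'
#' @slot points n x 3 matrix of centerline samples (mm).
#' @slot radii Numeric length n, local radii (mm), all > 0.
#' @slot parent Integer id of the parent branch (NA for a root).
#' @slot parentPoint Integer index into the parent's points at the attachment
#'   (NA for a root).
#' @slot order Branch generation: 1 = primary (stem), incremented at each
#'   bifurcation.
#' @slot id Integer branch id, unique within a traced tree.
#' @slot provenance Character tag recording the seed or bifurcation origin.
#' @export
setClass("BranchTrack",
  representation(points = "matrix", radii = "numeric", parent = "integer",
                 parentPoint = "integer", order = "integer", id = "integer",
                 provenance = "character"),
  validity = function(object) {
    if (nrow(object@points) < 2) return("a branch needs at least 2 points")
    if (ncol(object@points) != 3) return("points must be n x 3")
    if (length(object@radii) != nrow(object@points))
      return("radii must match points")
    if (any(object@radii <= 0)) return("radii must be > 0")
    TRUE
  })

#' Construct a BranchTrack
#'
#' @param points n x 3 matrix of mm coordinates.
#' @param radii Per-point radii in mm.
#' @param parent,parentPoint Parent branch id and attachment point index
#'   (`NA` for roots).
#' @param order Branch generation (1 = primary).
#' @param id Branch id.
#' @param provenance Free-text origin tag.
#' @return A [BranchTrack-class] object.
#' @export
BranchTrack <- function(points, radii, parent = NA_integer_,
                        parentPoint = NA_integer_, order = 1L, id = 1L,
                        provenance = "seed") {
  new("BranchTrack", points = as.matrix(points), radii = as.numeric(radii),
      parent = as.integer(parent), parentPoint = as.integer(parentPoint),
      order = as.integer(order), id = as.integer(id),
      provenance = provenance)
}

#' BezierCenterline: a C1 piecewise cubic Bezier curve through tracked points
#'
#' @slot segments List of 4 x 3 control-point matrices (mm), one per cubic
#'   segment; consecutive segments share their joint point.
#' @slot knots The interpolated input points, m x 3 (mm).
#' @export
setClass("BezierCenterline",
  representation(segments = "list", knots = "matrix"),
  validity = function(object) {
    for (s in object@segments) {
      if (!is.matrix(s) || nrow(s) != 4 || ncol(s) != 3)
        return("each segment must be a 4 x 3 control-point matrix")
    }
    if (length(object@segments) >= 2) {
      for (i in seq_len(length(object@segments) - 1)) {
        if (max(abs(object@segments[[i]][4, ] -
                    object@segments[[i + 1]][1, ])) > 1e-9)
          return("segment joints must coincide")
      }
    }
    TRUE
  })

#' VesselModel: the screened, smoothed vascular tree
#'
#' Branches carry their fitted Bezier centerline, a per-sample diameter
#' profile, the branch order, and parent linkage.
#'
#' @slot branches List of [BranchTrack-class] (screened tracks).
#' @slot centerlines List of [BezierCenterline-class], parallel to branches.
#' @slot diameters List of per-sample diameter profiles (mm) with the sample
#'   points stored in `attr(, "samples")`.
#' @slot bifurcations k x 3 matrix of bifurcation points (mm).
#' @slot spacing Voxel spacing (mm) of the grid the model was built on.
#' @export
setClass("VesselModel",
  representation(branches = "list", centerlines = "list", diameters = "list",
                 bifurcations = "matrix", spacing = "numeric"))

#' SegMetrics: voxelwise segmentation agreement metrics
#'
#' Holds TP/FP/FN/TN counts, the Dice similarity coefficient
#' DSC = 2TP / (2TP + FP + FN), the symmetric Hausdorff distance in mm, and
#' the false-positive / false-negative rates with the denominators this
#' framework reports (FP over ground-truth vessel voxels, FN over ground-truth
#' background voxels).
#'
#' @slot tp,fp,fn,tn Voxel counts.
#' @slot dsc Dice similarity coefficient in [0, 1].
#' @slot hd Hausdorff distance in mm.
#' @slot fpRate,fnRate Rates as defined above.
#' @export
setClass("SegMetrics",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric", dsc = "numeric", hd = "numeric",
                 fpRate = "numeric", fnRate = "numeric"),
  validity = function(object) {
    if (any(c(object@tp, object@fp, object@fn, object@tn) < 0))
      return("counts must be >= 0")
    if (object@dsc < 0 || object@dsc > 1) return("dsc must be in [0, 1]")
    TRUE
  })

#' SPCNN: the small-patch 3D convolutional network
#'
#' A binary classifier over cubic patches: stacked (3D convolution, kernel 3,
#' stride 2, zero padding 1 -> batch normalization -> ReLU) blocks with one
#' 2x2x2 max-pool after the first block, feature-map count held constant
#' through the downsampling steps, then dense layers to a single sigmoid
#' output trained with summed cross-entropy.
#'
#' @slot config The [spcnnConfig()] list.
#' @slot params Named list of weight arrays.
#' @slot state Batch-norm running statistics and layer shape bookkeeping.
#' @slot patchSize Integer side length of the input cube.
#' @slot trained Logical.
#' @slot history Data frame of per-epoch train/test loss and accuracy.
#' @export
setClass("SPCNN",
  representation(config = "list", params = "list", state = "list",
                 patchSize = "integer", trained = "logical",
                 history = "data.frame"))

# ---- generics & accessors ----

#' @describeIn MRAVolume-class voxel spacing in mm
#' @param x object
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @export
setMethod("spacing", "MRAVolume", function(x) x@spacing)
#' @export
setMethod("spacing", "VesselMask", function(x) x@spacing)

#' @describeIn MRAVolume-class the raw 3D array
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @export
setMethod("imgData", "MRAVolume", function(x) x@data)
#' @export
setMethod("imgData", "VesselMask", function(x) x@mask)

#' @describeIn MRAVolume-class physical origin in mm
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @export
setMethod("origin", "MRAVolume", function(x) x@origin)
#' @export
setMethod("origin", "VesselMask", function(x) x@origin)

#' @describeIn MRAVolume-class `"raw"` or `"standardized"`
#' @export
setGeneric("intensityScale", function(x) standardGeneric("intensityScale"))
#' @export
setMethod("intensityScale", "MRAVolume", function(x) x@intensityScale)

#' Branches of a vessel model
#' @param x a [VesselModel-class]
#' @return list of [BranchTrack-class]
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))
#' @export
setMethod("branches", "VesselModel", function(x) x@branches)

#' @describeIn BranchTrack-class branch generation (1 = primary)
#' @param x object
#' @export
setGeneric("branchOrder", function(x) standardGeneric("branchOrder"))
#' @export
setMethod("branchOrder", "BranchTrack", function(x) x@order)

setMethod("show", "MRAVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MRAVolume %d x %d x %d, spacing %.3g x %.3g x %.3g mm, %s\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], object@intensityScale))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "VesselMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("VesselMask %d x %d x %d, %d vessel voxels (%.3g%%)\n",
              d[1], d[2], d[3], sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "BranchTrack", function(object) {
  cat(sprintf(
    "BranchTrack id %d, order %d, %d points, length %.2f mm, parent %s\n",
    object@id, object@order, nrow(object@points),
    polylineLength(object@points),
    ifelse(is.na(object@parent), "none", as.character(object@parent))))
})

setMethod("show", "VesselModel", function(object) {
  ord <- vapply(object@branches, function(b) b@order, integer(1))
  cat(sprintf("VesselModel with %d branches (orders: %s)\n",
              length(object@branches),
              paste(names(table(ord)), table(ord), sep = ":", collapse = " ")))
})

setMethod("show", "SegMetrics", function(object) {
  cat(sprintf(
    "SegMetrics: DSC %.4f, HD %.3f mm, FP rate %.4f, FN rate %.5f\n",
    object@dsc, object@hd, object@fpRate, object@fnRate))
  cat(sprintf("  TP %d FP %d FN %d TN %d\n", object@tp, object@fp,
              object@fn, object@tn))
})

setMethod("show", "SPCNN", function(object) {
  cat(sprintf(
    "SPCNN: patch %d^3, %d conv blocks, %d feature maps, %s (%d parameters)\n",
    object@patchSize, object@config$n_blocks, object@config$feature_maps,
    if (object@trained) "trained" else "untrained",
    spcnnParameterCount(object)))
})
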