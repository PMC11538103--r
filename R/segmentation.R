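#' Pre-screening intensity interval
#'
#' On the standardized 0-255 scale, the signal intensity of large vessels
#' (upper bound, default 120) and of background tissue (lower bound, default
#' 80) bracket the grayscale band in which small-vessel voxels live; only
#' voxels strictly inside the band are passed to the patch classifier.
#'
#' @param tBg Background threshold (lower bound, default 80).
#' @param tV Large-vessel threshold (upper bound, default 120).
#' @return An `intensityInterval` list.
#' @export
intensityInterval <- function(tBg = 80, tV = 120) {
  if (tBg >= tV) stop("tBg must be < tV")
  structure(list(tBg = tBg, tV = tV), class = "intensityInterval")
}

#' Partition a standardized volume by the pre-screening interval
#'
#' Voxels at or above `tV` form the large-vessel mask, voxels at or below
#' `tBg` the background mask, and voxels strictly inside the interval are the
#' candidates submitted to the patch classifier. The three sets partition the
#' grid.
#'
#' @param v A standardized [MRAVolume-class].
#' @param interval An [intensityInterval()].
#' @return List with `candidates` (integer linear voxel indices),
#'   `largeVesselMask` and `backgroundMask` ([VesselMask-class]).
#' @export
prescreenCandidates <- function(v, interval = intensityInterval()) {
  stopifnot(is(v, "MRAVolume"))
  if (intensityScale(v) != "standardized")
    stop("pre-screening requires a standardized volume")
  x <- imgData(v)
  large <- x >= interval$tV
  bg <- x <= interval$tBg
  cand <- which(!large & !bg)
  list(candidates = cand,
       largeVesselMask = VesselMask(large, spacing(v), origin(v)),
       backgroundMask = VesselMask(bg, spacing(v), origin(v)))
}

## extract raw (unnormalized) patches around integer center rows;
## out-of-grid voxels filled by edge replication; chunked for memory
extractPatchMatrix <- function(v, centers, patchSize, chunk = 512L) {
  x <- imgData(v)
  d <- dim(x)
  h <- (patchSize - 1L) %/% 2L
  rel <- as.matrix(expand.grid(-h:h, -h:h, -h:h))
  n <- nrow(centers)
  out <- matrix(0, n, patchSize^3)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    cs <- centers[s:e, , drop = FALSE]
    m <- nrow(cs)
    ii <- clamp(rep(cs[, 1], each = nrow(rel)) + rep(rel[, 1], m), 1L, d[1])
    jj <- clamp(rep(cs[, 2], each = nrow(rel)) + rep(rel[, 2], m), 1L, d[2])
    kk <- clamp(rep(cs[, 3], each = nrow(rel)) + rep(rel[, 3], m), 1L, d[3])
    vals <- x[cbind(ii, jj, kk)]
    out[s:e, ] <- matrix(vals, nrow = m, byrow = TRUE)
  }
  out
}

#' Extract one normalized cubic patch
#'
#' The cube of side `size` voxels centered on `center` is extracted with
#' edge replication outside the grid and mapped by
#' `(x - normMin) / (normMax - normMin)`, clipped to [0, 1].
#'
#' @param v An [MRAVolume-class].
#' @param center Integer voxel index (1-based, length 3).
#' @param size Odd patch side in voxels (default 25).
#' @param normMin,normMax Normalization bounds (defaults: volume min/max).
#' @return List with `values` (a `size^3` array) and `center`.
#' @export
extractPatch <- function(v, center, size = 25,
                         normMin = min(imgData(v)),
                         normMax = max(imgData(v))) {
  if (size %% 2 == 0) stop("patch size must be odd")
  d <- dim(imgData(v))
  if (any(center < 1) || any(center > d))
    stop("patch center lies outside the grid")
  raw <- extractPatchMatrix(v, matrix(as.integer(center), 1, 3), size)
  vals <- clamp((raw - normMin) / max(normMax - normMin, 1e-12), 0, 1)
  list(values = array(vals, dim = rep(size, 3)), center = center)
}

## voxel point sets (mm) of a mask
maskPointsMM <- function(m) {
  idx <- which(imgData(m))
  indexToMM(arrIndex(idx, dim(imgData(m))), spacing(m), origin(m))
}

checkSameGrid <- function(pred, gt) {
  if (!identical(dim(imgData(pred)), dim(imgData(gt))))
    stop("masks are on different grids")
}

#' Dice similarity coefficient
#'
#' `DSC = 2 TP / (2 TP + FP + FN)` over voxels; 1 when both masks are empty.
#'
#' @param pred,gt [VesselMask-class] objects on the same grid.
#' @return DSC in [0, 1].
#' @export
diceCoefficient <- function(pred, gt) {
  checkSameGrid(pred, gt)
  p <- imgData(pred); g <- imgData(gt)
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Symmetric Hausdorff distance between two masks (mm)
#'
#' `HD(P, G) = max(h(P, G), h(G, P))` with the directed distance
#' `h(P, G) = max over p of min over g of ||p - g||`, computed over the voxel
#' center point sets in physical mm.
#'
#' @param pred,gt Non-empty [VesselMask-class] objects on the same grid.
#' @return Hausdorff distance in mm.
#' @export
hausdorffDistance <- function(pred, gt) {
  checkSameGrid(pred, gt)
  P <- maskPointsMM(pred); G <- maskPointsMM(gt)
  if (nrow(P) == 0 || nrow(G) == 0)
    stop("Hausdorff distance is undefined for an empty mask")
  max(max(pairwiseMinDist(P, G)), max(pairwiseMinDist(G, P)))
}

#' False-positive and false-negative rates
#'
#' Implements the printed definitions of this framework verbatim: the FP rate
#' is the proportion of voxels incorrectly classified as vessel out of the
#' total number of (ground-truth) vessel voxels, and the FN rate the
#' proportion incorrectly classified as background out of the total number of
#' background voxels. Note both denominators differ from the sensitivity /
#' specificity convention; see [conventionalRates()] for those.
#'
#' @param pred,gt [VesselMask-class] objects on the same grid; `gt` must
#'   contain at least one vessel and one background voxel.
#' @return List with `fpRate` and `fnRate`.
#' @export
fpFnRates <- function(pred, gt) {
  checkSameGrid(pred, gt)
  p <- imgData(pred); g <- imgData(gt)
  nVessel <- sum(g); nBg <- sum(!g)
  if (nVessel == 0 || nBg == 0)
    stop("ground truth must contain both vessel and background voxels")
  fp <- sum(p & !g); fn <- sum(!p & g)
  list(fpRate = fp / nVessel, fnRate = fn / nBg)
}

#' Conventional false-positive/false-negative fractions
#'
#' The textbook variants: FP over background voxels (1 - specificity) and FN
#' over vessel voxels (1 - sensitivity).
#'
#' @inheritParams fpFnRates
#' @return List with `fpOverBackground` and `fnOverVessel`.
#' @export
conventionalRates <- function(pred, gt) {
  checkSameGrid(pred, gt)
  p <- imgData(pred); g <- imgData(gt)
  list(fpOverBackground = sum(p & !g) / sum(!g),
       fnOverVessel = sum(!p & g) / sum(g))
}

#' Full segmentation metrics
#'
#' @param pred,gt [VesselMask-class] objects on the same grid.
#' @return A [SegMetrics-class].
#' @export
segMetrics <- function(pred, gt) {
  checkSameGrid(pred, gt)
  p <- imgData(pred); g <- imgData(gt)
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  rates <- fpFnRates(pred, gt)
  hd <- if (sum(p) > 0 && sum(g) > 0) hausdorffDistance(pred, gt) else NA_real_
  new("SegMetrics", tp = tp, fp = fp, fn = fn, tn = tn,
      dsc = diceCoefficient(pred, gt), hd = hd,
      fpRate = rates$fpRate, fnRate = rates$fnRate)
}

#' Segment a volume with the patch classifier
#'
#' Pre-screens voxels by the intensity interval, classifies each candidate's
#' centered patch with the network, and returns the union of the large-vessel
#' mask and candidates at or above the probability threshold (or, with
#' `smallVesselsOnly = TRUE`, the accepted candidates alone).
#'
#' @param v A standardized [MRAVolume-class].
#' @param classifier A trained [SPCNN-class], or any function mapping an
#'   n x patchSize^3 matrix of normalized patches to n probabilities.
#' @param interval [intensityInterval()].
#' @param threshold Probability cutoff (default 0.5).
#' @param smallVesselsOnly Exclude the large-vessel mask from the output.
#' @param normBounds Length-2 normalization bounds used at training time
#'   (defaults to the classifier's stored bounds, else the volume range).
#' @param chunk Candidates classified per batch.
#' @return A [VesselMask-class].
#' @export
segmentVolume <- function(v, classifier, interval = intensityInterval(),
                          threshold = 0.5, smallVesselsOnly = FALSE,
                          normBounds = NULL, chunk = 2048L) {
  pre <- prescreenCandidates(v, interval)
  d <- dim(imgData(v))
  out <- array(FALSE, dim = d)
  if (is(classifier, "SPCNN")) {
    ps <- classifier@patchSize
    nb <- normBounds %||% classifier@state$normBounds %||%
      c(min(imgData(v)), max(imgData(v)))
    predictFun <- function(X) predictSPCNN(classifier, X)
  } else {
    ps <- attr(classifier, "patchSize") %||% 25L
    nb <- normBounds %||% c(min(imgData(v)), max(imgData(v)))
    predictFun <- classifier
  }
  cand <- pre$candidates
  if (length(cand)) {
    ctrs <- arrIndex(cand, d)
    for (s in seq(1, length(cand), by = chunk)) {
      e <- min(s + chunk - 1L, length(cand))
      raw <- extractPatchMatrix(v, ctrs[s:e, , drop = FALSE], ps)
      X <- clamp((raw - nb[1]) / max(nb[2] - nb[1], 1e-12), 0, 1)
      p <- predictFun(X)
      out[cand[s:e][p >= threshold]] <- TRUE
    }
  }
  if (!smallVesselsOnly) out <- out | imgData(pre$largeVesselMask)
  VesselMask(out, spacing(v), origin(v))
}
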