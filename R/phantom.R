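#' PatchSet: labeled training patches for the small-patch CNN
#'
#' Patches are cubes of side `patchSize` voxels, flattened row-per-patch and
#' normalized to [0, 1] by the global minimum and maximum over the training
#' split, as the network's training protocol prescribes.
#'
#' @slot patches n x patchSize^3 numeric matrix, values in [0, 1].
#' @slot labels Integer 0/1: 1 if the patch center voxel is vessel.
#' @slot split Character `"train"`/`"test"` per patch.
#' @slot directions n x 3 local tube direction at positive centers (NA rows
#'   for negatives).
#' @slot patchSize Integer cube side.
#' @slot normMin,normMax Global normalization bounds.
#' @slot flags Character vector of data-quality flags (e.g. `"negatives-only"`).
#' @export
setClass("PatchSet",
  representation(patches = "matrix", labels = "integer", split = "character",
                 directions = "matrix", patchSize = "integer",
                 normMin = "numeric", normMax = "numeric",
                 flags = "character"),
  validity = function(object) {
    if (length(object@labels) != nrow(object@patches))
      return("labels must match patches")
    if (length(object@split) != nrow(object@patches))
      return("split must match patches")
    if (object@normMin >= object@normMax) return("normMin must be < normMax")
    if (ncol(object@patches) != object@patchSize^3)
      return("patch width must equal patchSize^3")
    TRUE
  })

setMethod("show", "PatchSet", function(object) {
  cat(sprintf(
    "PatchSet: %d patches (%d pos / %d neg), %d train / %d test, patch %d^3\n",
    nrow(object@patches), sum(object@labels == 1L), sum(object@labels == 0L),
    sum(object@split == "train"), sum(object@split == "test"),
    object@patchSize))
})

#' Specify a tube (one vessel segment chain) for the phantom generator
#'
#' @param points m x 3 matrix of centerline control points in mm; consecutive
#'   points are joined by straight segments, so curvature is encoded by
#'   supplying more points.
#' @param radii Radius in mm at each control point (length 1 recycled);
#'   linearly interpolated along each segment, so tubes may taper.
#' @param intensity Tube brightness on the standardized 0-255 scale.
#' @return A `tubeSpec` list.
#' @export
tubeSpec <- function(points, radii, intensity = 100) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a tube needs at least 2 control points")
  if (length(radii) == 1) radii <- rep(radii, nrow(points))
  if (length(radii) != nrow(points))
    stop("radii must have one value per control point")
  if (any(radii <= 0)) stop("all radii must be > 0")
  if (intensity < 0 || intensity > 255)
    stop("intensity must lie within [0, 255]")
  structure(list(points = points, radii = as.numeric(radii),
                 intensity = intensity), class = "tubeSpec")
}

#' Specify a synthetic vascular phantom
#'
#' Describes a 3D grid containing bright tubular structures on a darker noisy
#' background, optionally modulated by a smooth multiplicative bias field and
#' accompanied by a bright large-vessel structure. Default intensities place
#' the background (60) below and the large vessel (200) above the
#' pre-screening interval (80, 120), with small tubes (100) inside it.
#'
#' @param gridShape Integer length-3, voxels per axis.
#' @param spacing Voxel spacing in mm (scalar or length 3), all > 0.
#' @param tubes List of [tubeSpec()] objects (the small vessels).
#' @param topology Integer vector, parent tube index per tube (NA = root);
#'   encodes which tubes are bifurcation children of which.
#' @param backgroundLevel Mean background intensity (default 60).
#' @param noiseSd Additive Gaussian noise standard deviation (>= 0).
#' @param biasCoeffs Optional named numeric of low-order polynomial
#'   coefficients over normalized coordinates in [-1, 1]; names among
#'   `x, y, z, xx, yy, zz, xy, xz, yz`. `NULL` disables the bias field.
#' @param largeVessel Optional [tubeSpec()] for a bright large vessel
#'   (intensity should be >= the large-vessel threshold, default 200).
#' @param seed Random seed controlling the noise realization.
#' @return A `phantomSpec` list.
#' @export
phantomSpec <- function(gridShape, spacing, tubes, topology = NULL,
                        backgroundLevel = 60, noiseSd = 0, biasCoeffs = NULL,
                        largeVessel = NULL, seed = 1L) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("spacing must be > 0 on all axes")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  ints <- vapply(tubes, function(t) t$intensity, numeric(1))
  if (length(ints) && any(ints <= backgroundLevel))
    stop("background level must be below all tube intensities")
  if (is.null(topology)) topology <- rep(NA_integer_, length(tubes))
  structure(list(gridShape = as.integer(gridShape),
                 spacing = as.numeric(spacing), tubes = tubes,
                 topology = as.integer(topology),
                 backgroundLevel = backgroundLevel, noiseSd = noiseSd,
                 biasCoeffs = biasCoeffs, largeVessel = largeVessel,
                 seed = as.integer(seed)),
            class = "phantomSpec")
}

## evaluate the multiplicative bias field on the grid (normalized coords)
evalBiasField <- function(coeffs, dims) {
  if (is.null(coeffs)) return(array(1, dim = dims))
  u <- lapply(1:3, function(a) {
    if (dims[a] == 1) 0 else seq(-1, 1, length.out = dims[a])
  })
  X <- array(rep(u[[1]], times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(u[[2]], each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(u[[3]], each = dims[1] * dims[2]), dim = dims)
  terms <- list(x = X, y = Y, z = Z, xx = X * X, yy = Y * Y, zz = Z * Z,
                xy = X * Y, xz = X * Z, yz = Y * Z)
  f <- array(1, dim = dims)
  for (nm in names(coeffs)) {
    if (!nm %in% names(terms)) stop("unknown bias term: ", nm)
    f <- f + coeffs[[nm]] * terms[[nm]]
  }
  pmax(f, 0.2)
}

## densely resample a tube's control polyline; returns points, radii and the
## local unit direction at each sample
densifyTube <- function(tube, step) {
  pts <- tube$points; rad <- tube$radii
  out <- list(); ro <- list(); dirs <- list()
  for (i in seq_len(nrow(pts) - 1)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1, ]
    len <- sqrt(sum((p1 - p0)^2))
    if (len < 1e-12) next
    n <- max(2L, ceiling(len / step) + 1L)
    tt <- seq(0, 1, length.out = n)
    if (i < nrow(pts) - 1) tt <- tt[-n]  # avoid duplicating joints
    seg <- outer(rep(1, length(tt)), p0) + outer(tt, p1 - p0)
    out[[i]] <- seg
    ro[[i]] <- rad[i] + tt * (rad[i + 1] - rad[i])
    d <- unitVector(p1 - p0)
    dirs[[i]] <- matrix(d, nrow = length(tt), ncol = 3, byrow = TRUE)
  }
  list(points = do.call(rbind, out), radii = unlist(ro),
       dirs = do.call(rbind, dirs))
}

## mark voxels whose (possibly offset) centers fall inside a tube; works on
## a logical accumulator of the given dims
markTube <- function(inside, tube, spacing, dims, offset = c(0, 0, 0)) {
  pts <- tube$points; rad <- tube$radii
  for (i in seq_len(nrow(pts) - 1)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1, ]
    d <- p1 - p0; L2 <- sum(d^2)
    rmax <- max(rad[i], rad[i + 1])
    lo <- pmin(p0, p1) - rmax; hi <- pmax(p0, p1) + rmax
    i0 <- pmax(1L, floor(lo / spacing - offset) + 1L)
    i1 <- pmin(dims, ceiling(hi / spacing - offset) + 1L)
    if (any(i0 > i1)) next
    ii <- i0[1]:i1[1]; jj <- i0[2]:i1[2]; kk <- i0[3]:i1[3]
    g <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    xyz <- sweep(sweep(g - 1, 2, offset, `+`), 2, spacing, `*`)
    rel <- sweep(xyz, 2, p0, `-`)
    tt <- if (L2 > 0) clamp(as.vector(rel %*% d) / L2, 0, 1) else 0
    closest <- outer(tt, d)
    dist2 <- rowSums((rel - closest)^2)
    rloc <- rad[i] + tt * (rad[i + 1] - rad[i])
    hit <- dist2 <= rloc^2
    if (any(hit)) {
      lin <- linIndex(g[hit, , drop = FALSE], dims)
      inside[lin] <- TRUE
    }
  }
  inside
}

#' Render a phantom specification into a volume and its exact ground truth
#'
#' A voxel is labeled vessel in the ground-truth mask iff its center lies
#' within the (linearly interpolated) radius of some tube's centerline;
#' intensities are `bias x (tube or background level) + noise`, with tube
#' boundaries antialiased by 2x-per-axis supersampling when `antialias` is
#' `TRUE`. Identical spec + seed gives bit-identical output.
#'
#' The returned volume is tagged `"standardized"` when no bias field is
#' present (the generator works directly on the standardized 0-255 scale),
#' and `"raw"` otherwise, since a bias field invalidates that scale.
#'
#' @param spec A [phantomSpec()].
#' @param antialias Logical; supersample intensities 2x per axis (mask
#'   labeling is always the hard center-in test).
#' @return A list with `volume` ([MRAVolume-class]) and `truth`, a ground
#'   truth list with elements `mask`, `largeMask` ([VesselMask-class]),
#'   `centerlines`, `radii`, `dirs` (per-tube dense samples),
#'   `bifurcations` (k x 3 matrix, mm), `branchOrders`, and `bias`.
#' @export
renderPhantom <- function(spec, antialias = TRUE) {
  dims <- spec$gridShape; sp <- spec$spacing
  extent <- (dims - 1) * sp
  allTubes <- spec$tubes
  if (!is.null(spec$largeVessel)) allTubes <- c(allTubes, list(spec$largeVessel))
  for (tb in allTubes) {
    dt <- densifyTube(tb, min(sp) / 2)
    insideAny <- dt$points[, 1] >= 0 & dt$points[, 1] <= extent[1] &
      dt$points[, 2] >= 0 & dt$points[, 2] <= extent[2] &
      dt$points[, 3] >= 0 & dt$points[, 3] <= extent[3]
    if (!any(insideAny))
      stop("tube extends fully outside the grid; rejecting spec")
  }

  mask <- array(FALSE, dim = dims)
  centerlines <- list(); radii <- list(); dirs <- list()
  for (t in seq_along(spec$tubes)) {
    mask <- markTube(mask, spec$tubes[[t]], sp, dims)
    dt <- densifyTube(spec$tubes[[t]], min(sp) / 2)
    centerlines[[t]] <- dt$points; radii[[t]] <- dt$radii; dirs[[t]] <- dt$dirs
  }
  largeMask <- array(FALSE, dim = dims)
  if (!is.null(spec$largeVessel))
    largeMask <- markTube(largeMask, spec$largeVessel, sp, dims)

  ## intensity image: per-tube coverage fraction blended over the background
  img <- array(spec$backgroundLevel, dim = dims)
  offsets <- if (antialias) {
    as.matrix(expand.grid(c(-0.25, 0.25), c(-0.25, 0.25), c(-0.25, 0.25)))
  } else matrix(0, 1, 3)
  for (tb in allTubes) {
    cover <- array(0, dim = dims)
    for (o in seq_len(nrow(offsets))) {
      ins <- array(FALSE, dim = dims)
      ins <- markTube(ins, tb, sp, dims, offset = offsets[o, ])
      cover <- cover + ins
    }
    cover <- cover / nrow(offsets)
    val <- spec$backgroundLevel + cover * (tb$intensity - spec$backgroundLevel)
    img <- pmax(img, val)
  }

  bias <- evalBiasField(spec$biasCoeffs, dims)
  img <- bias * img
  if (spec$noiseSd > 0) {
    set.seed(deriveSeed(spec$seed, "render-noise"))
    img <- img + array(rnorm(prod(dims), 0, spec$noiseSd), dim = dims)
  }

  ## bifurcations: first point of each child tube (it starts on its parent)
  bif <- NULL
  ord <- rep(1L, length(spec$tubes))
  topo <- spec$topology
  if (length(topo)) {
    for (t in seq_along(topo)) {
      if (!is.na(topo[t])) {
        bif <- rbind(bif, spec$tubes[[t]]$points[1, ])
      }
    }
    ## branch order by walking parent links
    for (t in seq_along(topo)) {
      o <- 1L; p <- topo[t]
      while (!is.na(p)) { o <- o + 1L; p <- topo[p] }
      ord[t] <- o
    }
  }
  if (is.null(bif)) bif <- matrix(numeric(0), 0, 3)

  scaleTag <- if (is.null(spec$biasCoeffs)) "standardized" else "raw"
  vol <- MRAVolume(img, sp, intensityScale = scaleTag)
  truth <- list(mask = VesselMask(mask, sp), largeMask = VesselMask(largeMask, sp),
                centerlines = centerlines, radii = radii, dirs = dirs,
                bifurcations = bif, branchOrders = ord, bias = bias,
                topology = topo)
  list(volume = vol, truth = truth)
}

#' Generate a random lenticulostriate-like tree specification
#'
#' Builds a stem tube plus bifurcating children with branching angles drawn
#' uniformly in `angleRange` (degrees), child radii shrinking by
#' `radiusShrink` per generation, and gentle curvature from perturbed
#' intermediate control points. Optionally adds a thick bright large vessel
#' along one grid edge from which the stem emerges.
#'
#' @param seed Integer seed.
#' @param gridShape Grid size in voxels (default 64^3).
#' @param spacing Voxel spacing in mm (default 0.1, the working resolution).
#' @param nLevels Number of branch generations (default 2; 3 gives tertiary
#'   branches).
#' @param stemRadius Stem radius in mm (default 0.4; LSA-scale).
#' @param radiusShrink Per-generation radius factor (default 0.75).
#' @param angleRange Branching angle range in degrees (default c(30, 70)).
#' @param tubeIntensity Small-vessel intensity (default 100).
#' @param largeVessel Logical; include a large vessel (default FALSE).
#' @param noiseSd Noise standard deviation (default 0).
#' @return A [phantomSpec()].
#' @export
randomTreeSpec <- function(seed = 1L, gridShape = c(64, 64, 64),
                           spacing = 0.1, nLevels = 2, stemRadius = 0.4,
                           radiusShrink = 0.75, angleRange = c(30, 70),
                           tubeIntensity = 100, largeVessel = FALSE,
                           noiseSd = 0) {
  set.seed(deriveSeed(seed, "tree-topology"))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  extent <- (gridShape - 1) * spacing
  ctr <- extent / 2

  start <- c(extent[1] * 0.15, ctr[2], ctr[3])
  stemDir <- unitVector(c(1, runif(1, -0.2, 0.2), runif(1, -0.2, 0.2)))
  stemLen <- extent[1] * 0.5
  mid <- start + stemDir * stemLen * 0.5 +
    c(0, runif(1, -0.05, 0.05), runif(1, -0.05, 0.05)) * extent[2]
  stemEnd <- start + stemDir * stemLen
  tubes <- list(tubeSpec(rbind(start, mid, stemEnd),
                         c(stemRadius, stemRadius * 0.9, stemRadius * 0.8),
                         tubeIntensity))
  topo <- NA_integer_
  frontier <- list(list(idx = 1L, end = stemEnd,
                        dir = unitVector(stemEnd - mid), r = stemRadius * 0.8))

  for (lvl in seq_len(nLevels - 1)) {
    newFrontier <- list()
    for (f in frontier) {
      basis <- planeBasis(f$dir)
      phi0 <- runif(1, 0, 2 * pi)
      for (c_i in 1:2) {
        ang <- runif(1, angleRange[1], angleRange[2]) * pi / 180
        phi <- phi0 + (c_i - 1) * pi + runif(1, -0.4, 0.4)
        cdir <- unitVector(cos(ang) * f$dir +
                           sin(ang) * (cos(phi) * basis$u + sin(phi) * basis$v))
        clen <- max(1.0, 0.3 * min(extent))
        r0 <- f$r * radiusShrink
        cEnd <- f$end + cdir * clen
        cEnd <- clamp(cEnd, 0.05 * extent, 0.95 * extent)
        cMid <- f$end + cdir * clen * 0.5
        tubes[[length(tubes) + 1]] <-
          tubeSpec(rbind(f$end, cMid, cEnd), c(r0, r0 * 0.9, r0 * 0.8),
                   tubeIntensity)
        topo <- c(topo, f$idx)
        newFrontier[[length(newFrontier) + 1]] <-
          list(idx = length(tubes), end = cEnd,
               dir = unitVector(cEnd - cMid), r = r0 * 0.8)
      }
    }
    frontier <- newFrontier
  }

  lv <- NULL
  if (largeVessel) {
    lv <- tubeSpec(rbind(c(start[1] - spacing[1], 0.05 * extent[2], ctr[3]),
                         c(start[1] - spacing[1], 0.95 * extent[2], ctr[3])),
                   1.0, 200)
  }
  phantomSpec(gridShape, spacing, tubes, topo, noiseSd = noiseSd,
              largeVessel = lv, seed = seed)
}

#' Phantom with straight tubes spanning many orientations
#'
#' Places `nTubes` straight tubes through the grid center region with
#' directions drawn from a hemispheric Fibonacci lattice, guaranteeing
#' coverage of distinct local trajectory orientations for patch training.
#'
#' @param seed Integer seed.
#' @param nTubes Number of tubes (default 18, one per orientation bin).
#' @param gridShape,spacing Grid geometry.
#' @param radius Tube radius in mm.
#' @param noiseSd Noise standard deviation.
#' @return A [phantomSpec()].
#' @export
orientationPhantomSpec <- function(seed = 1L, nTubes = 18,
                                   gridShape = c(60, 60, 60), spacing = 0.1,
                                   radius = 0.3, noiseSd = 0) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  extent <- (gridShape - 1) * spacing
  dirs <- hemisphereLattice(nTubes)
  set.seed(deriveSeed(seed, "orientation-phantom"))
  tubes <- vector("list", nTubes)
  for (i in seq_len(nTubes)) {
    d <- dirs[i, ]
    ctr <- extent * runif(3, 0.35, 0.65)
    halfLen <- 0.35 * min(extent)
    tubes[[i]] <- tubeSpec(rbind(ctr - d * halfLen, ctr + d * halfLen),
                           radius, 100)
  }
  phantomSpec(gridShape, spacing, tubes, noiseSd = noiseSd, seed = seed)
}

## n roughly uniform unit directions on the upper hemisphere
hemisphereLattice <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                    # cos(theta) in (0, 1): upper hemisphere
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Assign a direction to one of n hemispheric orientation bins
#'
#' Directions are axial (d and -d are the same trajectory orientation); each
#' direction is assigned to the lattice bin maximizing `|d . bin|`.
#'
#' @param dirs m x 3 matrix of direction vectors.
#' @param nBins Number of orientation bins (default 18).
#' @return Integer bin labels in 1..nBins.
#' @export
orientationBin <- function(dirs, nBins = 18) {
  lat <- hemisphereLattice(nBins)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sim <- abs(tcrossprod(dirs, lat))
  max.col(sim, ties.method = "first")
}

#' Build a labeled patch dataset from rendered phantoms
#'
#' Positive patches are centered on ground-truth vessel voxels (optionally
#' subsampled with `stride`), negatives on non-vessel voxels whose intensity
#' lies strictly inside the pre-screening interval — exactly the voxels the
#' classifier must decide on at segmentation time. The local tube direction
#' at each positive center is recorded and binned into `nOrientations`
#' hemispheric orientation bins. Patches are normalized to [0, 1] by the
#' global min/max over the training split.
#'
#' @param phantoms List of rendered phantoms (each a list with `volume`,
#'   `truth`) from [renderPhantom()].
#' @param nPos,nNeg Requested positive / negative patch counts.
#' @param patchSize Patch cube side in voxels (odd; default 25).
#' @param nOrientations Number of orientation bins positives must cover
#'   (default 18).
#' @param splitRatio Training fraction (default 0.8, i.e. an 8:2 split).
#' @param stride Subsampling stride along the vessel-voxel candidate list
#'   (default 1 = every voxel eligible).
#' @param interval [intensityInterval()] defining the negative sampling band.
#' @param negMarginVox Exclude negatives within this many voxels of the
#'   vessel mask (default 0 = the plain pre-screen band). A margin of 2
#'   yields flat-noise negatives without the ambiguous partial-volume rim.
#' @param posCoreVox Restrict positives to voxels at least this many voxels
#'   inside the tube (mask erosion; default 0 = any vessel voxel). Together
#'   with `negMarginVox` this constructs a separable bright-tube versus
#'   flat-noise dataset.
#' @param normBounds Optional fixed normalization bounds (length 2). An
#'   evaluation set must be normalized with the bounds of the training set
#'   the classifier was fitted on; pass them here.
#' @param seed Integer seed.
#' @return A [PatchSet-class].
#' @export
makeTrainingPatches <- function(phantoms, nPos, nNeg, patchSize = 25,
                                nOrientations = 18, splitRatio = 0.8,
                                stride = 1L, interval = intensityInterval(),
                                negMarginVox = 0L, posCoreVox = 0L,
                                normBounds = NULL, seed = 1L) {
  if (patchSize %% 2 == 0) stop("patchSize must be odd")
  posList <- list(); negList <- list(); dirList <- list()
  for (ph in phantoms) {
    v <- ph$volume; tr <- ph$truth
    dims <- dim(imgData(v))
    m <- imgData(tr$mask)
    posSel <- m
    if (posCoreVox > 0) {
      off <- neighborOffsets26()
      for (it in seq_len(posCoreVox)) {
        lin <- which(posSel)
        if (!length(lin)) break
        ijk <- arrIndex(lin, dims)
        keepV <- rep(TRUE, length(lin))
        for (o in seq_len(26)) {
          nb <- sweep(ijk, 2, off[o, ], `+`)
          ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
          keepV <- keepV & ok
          keepV[ok] <- keepV[ok] & posSel[linIndex(nb[ok, , drop = FALSE],
                                                   dims)]
        }
        posSel <- array(FALSE, dim = dims)
        posSel[lin[keepV]] <- TRUE
      }
    }
    posIdx <- which(posSel)
    if (stride > 1 && length(posIdx))
      posIdx <- posIdx[seq(1, length(posIdx), by = stride)]
    img <- imgData(v)
    excl <- m | imgData(tr$largeMask)
    if (negMarginVox > 0) {
      off <- neighborOffsets26()
      for (it in seq_len(negMarginVox)) {
        lin <- which(excl)
        ijk <- arrIndex(lin, dims)
        cand <- ijk[rep(seq_len(nrow(ijk)), each = 26), , drop = FALSE] +
          off[rep(1:26, nrow(ijk)), , drop = FALSE]
        ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
          cand[, 2] >= 1 & cand[, 2] <= dims[2] &
          cand[, 3] >= 1 & cand[, 3] <= dims[3]
        excl[unique(linIndex(cand[ok, , drop = FALSE], dims))] <- TRUE
      }
    }
    negIdx <- which(!excl & img > interval$tBg & img < interval$tV)
    ## local direction at each positive voxel: nearest dense centerline sample
    if (length(posIdx)) {
      cl <- do.call(rbind, tr$centerlines)
      dd <- do.call(rbind, tr$dirs)
      pts <- indexToMM(arrIndex(posIdx, dims), spacing(v))
      nn <- nearestRowIndex(pts, cl)
      dirList[[length(dirList) + 1]] <- dd[nn, , drop = FALSE]
    }
    posList[[length(posList) + 1]] <- list(v = v, idx = posIdx)
    negList[[length(negList) + 1]] <- list(v = v, idx = negIdx)
  }
  nPosAvail <- sum(vapply(posList, function(x) length(x$idx), numeric(1)))
  nNegAvail <- sum(vapply(negList, function(x) length(x$idx), numeric(1)))
  if (nPos > nPosAvail)
    stop(sprintf("requested %d positives but only %d available", nPos, nPosAvail))
  if (nNeg > nNegAvail)
    stop(sprintf("requested %d negatives but only %d available", nNeg, nNegAvail))

  set.seed(deriveSeed(seed, "patch-sampling"))
  samplePer <- function(lst, total) {
    avail <- vapply(lst, function(x) length(x$idx), numeric(1))
    take <- floor(total * avail / sum(pmax(avail, 1e-9)))
    while (sum(take) < total) {           # distribute rounding remainder
      k <- which.max(avail - take)
      take[k] <- take[k] + 1
    }
    lapply(seq_along(lst), function(i) {
      if (take[i] == 0) return(integer(0))
      sample(lst[[i]]$idx, take[i])
    })
  }
  posTake <- if (nPos > 0) samplePer(posList, nPos) else
    lapply(posList, function(x) integer(0))
  negTake <- samplePer(negList, nNeg)

  extractAll <- function(take, lst) {
    out <- list()
    for (i in seq_along(lst)) {
      if (!length(take[[i]])) next
      v <- lst[[i]]$v
      ctrs <- arrIndex(take[[i]], dim(imgData(v)))
      out[[length(out) + 1]] <- extractPatchMatrix(v, ctrs, patchSize)
    }
    if (!length(out)) return(matrix(numeric(0), 0, patchSize^3))
    do.call(rbind, out)
  }
  posRaw <- extractAll(posTake, posList)
  negRaw <- extractAll(negTake, negList)

  ## direction labels for the sampled positives
  posDirs <- matrix(NA_real_, nrow(posRaw), 3)
  if (nPos > 0) {
    row0 <- 0
    for (i in seq_along(posList)) {
      n_i <- length(posTake[[i]])
      if (!n_i) next
      match_i <- match(posTake[[i]], posList[[i]]$idx)
      posDirs[row0 + seq_len(n_i), ] <- dirList[[i]][match_i, , drop = FALSE]
      row0 <- row0 + n_i
    }
  }

  raw <- rbind(posRaw, negRaw)
  labels <- c(rep(1L, nrow(posRaw)), rep(0L, nrow(negRaw)))
  dirsAll <- rbind(posDirs, matrix(NA_real_, nrow(negRaw), 3))

  ## stratified train/test split at splitRatio
  split <- character(nrow(raw))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    nTrain <- round(length(idx) * splitRatio)
    tr_i <- sample(idx, nTrain)
    split[tr_i] <- "train"
    split[setdiff(idx, tr_i)] <- "test"
  }

  if (!is.null(normBounds)) {
    normMin <- normBounds[1]; normMax <- normBounds[2]
  } else {
    trainRows <- split == "train"
    normMin <- min(raw[trainRows, , drop = FALSE])
    normMax <- max(raw[trainRows, , drop = FALSE])
    if (!is.finite(normMin) || normMin >= normMax) {
      normMin <- min(raw); normMax <- max(raw)
      if (normMin >= normMax) { normMin <- 0; normMax <- 1 }
    }
  }
  patches <- clamp((raw - normMin) / (normMax - normMin), 0, 1)

  flags <- character(0)
  if (nPos == 0) flags <- c(flags, "negatives-only")
  if (nPos > 0) {
    bins <- orientationBin(posDirs, nOrientations)
    if (length(unique(bins)) < nOrientations)
      flags <- c(flags, sprintf("orientation-coverage:%d/%d",
                                length(unique(bins)), nOrientations))
  }
  new("PatchSet", patches = patches, labels = labels, split = split,
      directions = dirsAll, patchSize = as.integer(patchSize),
      normMin = normMin, normMax = normMax, flags = flags)
}

## index of nearest row of b for each row of a (blockwise)
nearestRowIndex <- function(a, b, block = 2000L) {
  n <- nrow(a)
  out <- integer(n)
  b2 <- rowSums(b^2)
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1L, n)
    ab <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ab^2), b2, `+`) - 2 * tcrossprod(ab, b)
    out[s:e] <- apply(d2, 1, which.min)
  }
  out
}
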