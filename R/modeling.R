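#' Estimate the diameter profile along a centerline
#'
#' At each arc-length station the mask cross-section in the plane
#' perpendicular to the local tangent is sampled (nearest-neighbor, at
#' half-voxel resolution), the connected region containing the centerline
#' point is measured, and the equivalent-circle diameter `2 * sqrt(A / pi)`
#' is recorded; the profile is median-filtered with window 3. Stations that
#' fall outside the mask inherit the nearest in-mask station's diameter and
#' are flagged.
#'
#' @param c A [BezierCenterline-class].
#' @param mask A [VesselMask-class].
#' @param ds Station spacing in mm (default half the voxel size).
#' @param maxRadius Largest radius searched, mm (default 1.5).
#' @return Numeric diameter profile (mm) with attributes `samples` (station
#'   points) and `flagged` (logical, outside-mask stations).
#' @export
estimateDiameters <- function(c, mask, ds = NULL, maxRadius = 1.5) {
  sp <- min(spacing(mask))
  if (is.null(ds)) ds <- 0.5 * sp
  st <- sampleUniform(c, ds)
  n <- nrow(st$points)
  step <- sp / 2
  rr <- symmetricGrid(maxRadius, step)
  g2 <- as.matrix(expand.grid(u = rr, v = rr))
  gridDim <- length(rr)
  ctrCell <- which(g2[, 1] == 0 & g2[, 2] == 0)
  diam <- numeric(n); flagged <- logical(n)
  for (i in seq_len(n)) {
    tangent <- st$tangents[i, ]
    if (sum(tangent^2) < 1e-12) { flagged[i] <- TRUE; next }
    basis <- planeBasis(unitVector(tangent))
    pts <- outer(rep(1, nrow(g2)), st$points[i, ]) +
      outer(g2[, 1], basis$u) + outer(g2[, 2], basis$v)
    inside <- maskAtMM(mask, pts)
    if (!inside[ctrCell]) { flagged[i] <- TRUE; next }
    ## 4-connected flood fill from the center cell on the sampled plane
    img <- matrix(inside, gridDim, gridDim)
    lab <- floodFill2(img, ((ctrCell - 1) %% gridDim) + 1,
                      ((ctrCell - 1) %/% gridDim) + 1)
    A <- sum(lab) * step^2
    diam[i] <- 2 * sqrt(A / pi)
  }
  if (all(flagged)) stop("centerline lies entirely outside the mask")
  if (any(flagged)) {
    okIdx <- which(!flagged)
    for (i in which(flagged)) diam[i] <- diam[okIdx[which.min(abs(okIdx - i))]]
  }
  if (n >= 3) {
    sm <- diam
    for (i in 2:(n - 1)) sm[i] <- median(diam[(i - 1):(i + 1)])
    diam <- sm
  }
  attr(diam, "samples") <- st$points
  attr(diam, "flagged") <- flagged
  diam
}

## 4-connected flood fill on a logical matrix from (r0, c0)
floodFill2 <- function(img, r0, c0) {
  n <- nrow(img)
  lab <- matrix(FALSE, n, ncol(img))
  stack <- matrix(c(r0, c0), 1, 2)
  lab[r0, c0] <- TRUE
  while (nrow(stack)) {
    cur <- stack
    stack <- matrix(integer(0), 0, 2)
    for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- cbind(cur[, 1] + dd[1], cur[, 2] + dd[2])
      ok <- nb[, 1] >= 1 & nb[, 1] <= n & nb[, 2] >= 1 & nb[, 2] <= ncol(img)
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) next
      hit <- img[nb] & !lab[nb]
      nb <- nb[hit, , drop = FALSE]
      if (nrow(nb)) {
        lab[nb] <- TRUE
        stack <- rbind(stack, nb)
      }
    }
    stack <- unique(stack)
  }
  lab
}

#' Build a vessel model from screened branch tracks
#'
#' Fits an interpolating Bezier centerline and a diameter profile to every
#' screened branch.
#'
#' @param branchList Screened list of [BranchTrack-class].
#' @param mask A [VesselMask-class].
#' @param ds Diameter station spacing in mm.
#' @return A [VesselModel-class].
#' @export
buildVesselModel <- function(branchList, mask, ds = NULL) {
  centerlines <- lapply(branchList, function(b) fitCenterline(b@points))
  diameters <- lapply(centerlines, function(cl)
    estimateDiameters(cl, mask, ds))
  ids <- vapply(branchList, function(b) b@id, integer(1))
  bif <- matrix(numeric(0), 0, 3)
  for (b in branchList) {
    if (!is.na(b@parent) && b@parent %in% ids)
      bif <- rbind(bif, b@points[1, ])
  }
  new("VesselModel", branches = branchList, centerlines = centerlines,
      diameters = diameters, bifurcations = bif, spacing = spacing(mask))
}

#' Per-branch morphometry table
#'
#' One row per branch with its order (reported as at most 3, tertiary-plus
#' collapsed), arc length, mean/min/max equivalent diameter, and mean
#' curvature from the analytic second derivative of the Bezier segments. The
#' per-order branch counts are attached as `attr(, "orderCounts")`.
#'
#' @param m A [VesselModel-class].
#' @return A data frame with columns `id, order, lengthMM, meanDiamMM,
#'   minDiamMM, maxDiamMM, meanCurvature`.
#' @export
morphometry <- function(m) {
  rows <- lapply(seq_along(m@branches), function(i) {
    b <- m@branches[[i]]
    cl <- m@centerlines[[i]]
    dm <- m@diameters[[i]]
    sm <- sampleCenterline(cl, 32L)
    data.frame(id = b@id, order = min(b@order, 3L),
               lengthMM = arcLength(cl),
               meanDiamMM = mean(dm), minDiamMM = min(dm),
               maxDiamMM = max(dm),
               meanCurvature = mean(sm$curvature))
  })
  out <- do.call(rbind, rows)
  counts <- table(factor(out$order, levels = 1:3))
  attr(out, "orderCounts") <- as.integer(counts)
  out
}

#' Compare two vessel models
#'
#' Branches are matched greedily by mean closest-point distance (threshold
#' `matchThreshold` mm). For each matched pair, key points — arc-length
#' proportional stations including both endpoints — give point offsets;
#' branch lengths and mean diameters give signed differences (a - b),
#' Pearson correlations, and Bland-Altman statistics (mean difference and
#' mean +/- 1.96 SD limits).
#'
#' @param a,b [VesselModel-class] objects.
#' @param matchThreshold Branch matching threshold in mm (default 1).
#' @param nKeyPoints Key points per matched branch (default 21).
#' @return List with `matches`, `keypointOffsets`, `lengthDiffs`,
#'   `diameterDiffs`, `pearsonLength`, `pearsonDiameter`, `blandAltmanLength`,
#'   `blandAltmanDiameter`; empty comparison is flagged via `flag`.
#' @export
compareModels <- function(a, b, matchThreshold = 1, nKeyPoints = 21L) {
  if (!length(a@branches) || !length(b@branches))
    stop("both models must be non-empty")
  nA <- length(a@branches); nB <- length(b@branches)
  cost <- matrix(Inf, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    cost[i, j] <- mean(pairwiseMinDist(a@branches[[i]]@points,
                                       b@branches[[j]]@points))
  }
  matches <- NULL
  cw <- cost
  repeat {
    mn <- which(cw == min(cw), arr.ind = TRUE)[1, , drop = FALSE]
    if (!is.finite(cw[mn]) || cw[mn] > matchThreshold) break
    matches <- rbind(matches, cbind(mn, dist = cw[mn]))
    cw[mn[1], ] <- Inf; cw[, mn[2]] <- Inf
    if (all(!is.finite(cw))) break
  }
  if (is.null(matches)) {
    return(list(matches = data.frame(), keypointOffsets = numeric(0),
                lengthDiffs = numeric(0), diameterDiffs = numeric(0),
                pearsonLength = NA_real_, pearsonDiameter = NA_real_,
                blandAltmanLength = NULL, blandAltmanDiameter = NULL,
                flag = "no-matches"))
  }
  offsets <- c(); lenD <- c(); diaD <- c()
  lenA <- c(); lenB <- c(); diaA <- c(); diaB <- c()
  for (r in seq_len(nrow(matches))) {
    i <- matches[r, 1]; j <- matches[r, 2]
    ka <- keyPoints(a@centerlines[[i]], nKeyPoints)
    kb <- keyPoints(b@centerlines[[j]], nKeyPoints)
    offsets <- c(offsets, sqrt(rowSums((ka - kb)^2)))
    la <- arcLength(a@centerlines[[i]]); lb <- arcLength(b@centerlines[[j]])
    da <- mean(a@diameters[[i]]); db <- mean(b@diameters[[j]])
    lenA <- c(lenA, la); lenB <- c(lenB, lb)
    diaA <- c(diaA, da); diaB <- c(diaB, db)
    lenD <- c(lenD, la - lb); diaD <- c(diaD, da - db)
  }
  pl <- if (length(lenA) >= 3 && sd(lenA) > 0 && sd(lenB) > 0)
    cor(lenA, lenB) else NA_real_
  pd <- if (length(diaA) >= 3 && sd(diaA) > 0 && sd(diaB) > 0)
    cor(diaA, diaB) else NA_real_
  list(matches = as.data.frame(matches), keypointOffsets = offsets,
       lengthDiffs = lenD, diameterDiffs = diaD,
       pearsonLength = pl, pearsonDiameter = pd,
       blandAltmanLength = blandAltman(lenA, lenB),
       blandAltmanDiameter = blandAltman(diaA, diaB), flag = NULL)
}

## arc-length proportional key points (both endpoints included)
keyPoints <- function(cl, n) {
  dense <- sampleCenterline(cl, 64L)
  seg <- sqrt(rowSums((dense$points[-1, , drop = FALSE] -
                       dense$points[-nrow(dense$points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  targets <- seq(0, s[length(s)], length.out = n)
  idx <- vapply(targets, function(si) which.min(abs(s - si)), integer(1))
  dense$points[idx, , drop = FALSE]
}

#' Bland-Altman statistics for paired measurements
#'
#' @param x,y Paired numeric vectors.
#' @return List with `meanDiff`, `sdDiff`, `lower`, `upper` (mean +/- 1.96 SD).
#' @export
blandAltman <- function(x, y) {
  d <- x - y
  list(meanDiff = mean(d), sdDiff = sd(d),
       lower = mean(d) - 1.96 * sd(d), upper = mean(d) + 1.96 * sd(d))
}

#' Export a vessel model as tube surface meshes
#'
#' Builds a triangulated tube per branch (rings of `nSides` vertices at the
#' local radius around arc-length stations, with end caps) and stores the
#' local diameter as a per-vertex scalar for color mapping.
#'
#' @param m A [VesselModel-class].
#' @param nSides Circumferential resolution (default 12).
#' @param ds Ring spacing in mm (default 0.25).
#' @return List of meshes, each with `vertices` (V x 3), `triangles`
#'   (T x 3, 1-based), `scalars` (per-vertex diameter, mm), `branchId`.
#' @export
exportTubeMesh <- function(m, nSides = 12L, ds = 0.25) {
  out <- vector("list", length(m@branches))
  for (bi in seq_along(m@branches)) {
    cl <- m@centerlines[[bi]]
    dm <- m@diameters[[bi]]
    st <- sampleUniform(cl, ds)
    n <- nrow(st$points)
    samples <- attr(dm, "samples")
    nn <- nearestRowIndex(st$points, samples)
    radii <- dm[nn] / 2
    theta <- seq(0, 2 * pi, length.out = nSides + 1)[-(nSides + 1)]
    verts <- matrix(0, n * nSides, 3)
    scal <- numeric(n * nSides)
    for (i in seq_len(n)) {
      basis <- planeBasis(unitVector(st$tangents[i, ]))
      ring <- outer(rep(1, nSides), st$points[i, ]) +
        radii[i] * (outer(cos(theta), basis$u) + outer(sin(theta), basis$v))
      verts[(i - 1) * nSides + seq_len(nSides), ] <- ring
      scal[(i - 1) * nSides + seq_len(nSides)] <- 2 * radii[i]
    }
    tris <- list()
    for (i in seq_len(n - 1)) {
      for (k in seq_len(nSides)) {
        k2 <- k %% nSides + 1
        a1 <- (i - 1) * nSides + k;  a2 <- (i - 1) * nSides + k2
        b1 <- i * nSides + k;        b2 <- i * nSides + k2
        tris[[length(tris) + 1]] <- c(a1, b1, a2)
        tris[[length(tris) + 1]] <- c(a2, b1, b2)
      }
    }
    ## end caps: center vertex fans
    verts <- rbind(verts, st$points[1, ], st$points[n, ])
    scal <- c(scal, 2 * radii[1], 2 * radii[n])
    c1 <- nrow(verts) - 1L; c2 <- nrow(verts)
    for (k in seq_len(nSides)) {
      k2 <- k %% nSides + 1
      tris[[length(tris) + 1]] <- c(c1, k2, k)
      tris[[length(tris) + 1]] <- c(c2, (n - 1) * nSides + k,
                                    (n - 1) * nSides + k2)
    }
    out[[bi]] <- list(vertices = verts, triangles = do.call(rbind, tris),
                      scalars = scal, branchId = m@branches[[bi]]@id)
  }
  out
}
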