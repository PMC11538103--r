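#' Construct a tracking cylinder
#'
#' The tracking primitive: a finite cylinder with its base-face center,
#' unit axis, radius and height (all mm).
#'
#' @param base Length-3 mm position of the base-face center.
#' @param axis Length-3 direction (normalized internally).
#' @param radius Radius in mm (> 0).
#' @param height Height in mm (> 0).
#' @return A `cylinder` list with `base`, `axis` (unit), `radius`, `height`,
#'   and `end` (= base + axis * height).
#' @export
cylinder <- function(base, axis, radius, height) {
  if (radius <= 0) stop("radius must be > 0")
  if (height <= 0) stop("height must be > 0")
  axis <- unitVector(axis)
  structure(list(base = as.numeric(base), axis = axis, radius = radius,
                 height = height, end = as.numeric(base) + axis * height),
            class = "cylinder")
}

## separable Gaussian smoothing with replicate padding
gaussianSmooth3 <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  d <- dim(x)
  for (a in 1:3) {
    perm <- c(a, setdiff(1:3, a))
    xp <- aperm(x, perm)
    m <- matrix(xp, nrow = d[a])
    mp <- rbind(m[rep(1, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
    out <- matrix(0, d[a], ncol(m))
    for (t in seq_along(w)) {
      out <- out + w[t] * mp[(t - 1) + seq_len(d[a]), , drop = FALSE]
    }
    x <- aperm(array(out, dim = d[perm]), order(perm))
  }
  x
}

#' Hessian eigenvalues of the Gaussian-smoothed image at a point
#'
#' Extracts the cubic neighborhood (default 11^3) around the nearest voxel,
#' smooths it with a Gaussian of `sigma` voxels, and evaluates the Hessian at
#' the center by central second differences (voxel units). A bright tube
#' yields two large negative eigenvalues and one near zero.
#'
#' @param v An [MRAVolume-class].
#' @param pointMM Length-3 physical position in mm.
#' @param sigma Gaussian scale in voxels (default 1.5).
#' @param halfWidth Neighborhood half-width in voxels (default 5, i.e. 11^3).
#' @return Length-3 eigenvalues sorted ascending.
#' @export
hessianEigenAt <- function(v, pointMM, sigma = 1.5, halfWidth = 5L) {
  x <- imgData(v); d <- dim(x)
  ctr <- mmToNearestIndex(matrix(pointMM, 1, 3), spacing(v), d, origin(v))[1, ]
  r <- halfWidth + max(1L, ceiling(3 * sigma))
  ii <- clamp(ctr[1] + (-r):r, 1L, d[1])
  jj <- clamp(ctr[2] + (-r):r, 1L, d[2])
  kk <- clamp(ctr[3] + (-r):r, 1L, d[3])
  blk <- x[ii, jj, kk, drop = FALSE]
  sm <- gaussianSmooth3(blk, sigma)
  c0 <- r + 1L
  f <- function(di, dj, dk) sm[c0 + di, c0 + dj, c0 + dk]
  H <- matrix(0, 3, 3)
  H[1, 1] <- f(1, 0, 0) - 2 * f(0, 0, 0) + f(-1, 0, 0)
  H[2, 2] <- f(0, 1, 0) - 2 * f(0, 0, 0) + f(0, -1, 0)
  H[3, 3] <- f(0, 0, 1) - 2 * f(0, 0, 0) + f(0, 0, -1)
  H[1, 2] <- H[2, 1] <- (f(1, 1, 0) - f(1, -1, 0) - f(-1, 1, 0) + f(-1, -1, 0)) / 4
  H[1, 3] <- H[3, 1] <- (f(1, 0, 1) - f(1, 0, -1) - f(-1, 0, 1) + f(-1, 0, -1)) / 4
  H[2, 3] <- H[3, 2] <- (f(0, 1, 1) - f(0, 1, -1) - f(0, -1, 1) + f(0, -1, -1)) / 4
  sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
}

## is each mm point inside the mask? (nearest-voxel lookup, FALSE off-grid)
maskAtMM <- function(mask, pts) {
  m <- imgData(mask); d <- dim(m); sp <- spacing(mask)
  idx <- round(mmToIndex(pts, sp, origin(mask)))
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- logical(nrow(pts))
  if (any(ok)) {
    ii <- idx[ok, , drop = FALSE]
    storage.mode(ii) <- "integer"
    out[ok] <- m[ii]
  }
  out
}

## distances from `point` to the mask boundary along rays perpendicular to
## `axis`, marched at quarter-voxel steps
rayBoundaryDistances <- function(mask, point, axis, nRays = 8,
                                 maxReach = NULL) {
  sp <- min(spacing(mask))
  if (is.null(maxReach)) maxReach <- 20 * sp
  basis <- planeBasis(axis)
  theta <- seq(0, 2 * pi, length.out = nRays + 1)[-(nRays + 1)]
  step <- 0.25 * sp
  ss <- seq(step, maxReach, by = step)
  dists <- numeric(nRays)
  for (k in seq_len(nRays)) {
    dir <- cos(theta[k]) * basis$u + sin(theta[k]) * basis$v
    pts <- outer(rep(1, length(ss)), point) + outer(ss, dir)
    inside <- maskAtMM(mask, pts)
    firstOut <- which(!inside)
    dists[k] <- if (length(firstOut)) ss[firstOut[1]] - step / 2 else maxReach
  }
  dists
}

## voxel centers inside a cylinder; returns linear indices and total count
cylinderVoxels <- function(cyl, dims, sp, origin = c(0, 0, 0)) {
  lo <- pmin(cyl$base, cyl$end) - cyl$radius
  hi <- pmax(cyl$base, cyl$end) + cyl$radius
  i0 <- pmax(1L, as.integer(floor((lo - origin) / sp)) + 1L)
  i1 <- pmin(dims, as.integer(ceiling((hi - origin) / sp)) + 1L)
  if (any(i0 > i1)) return(list(lin = integer(0), n = 0L))
  g <- as.matrix(expand.grid(i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]))
  xyz <- indexToMM(g, sp, origin)
  rel <- sweep(xyz, 2, cyl$base, `-`)
  t <- as.vector(rel %*% cyl$axis)
  inAx <- t >= 0 & t <= cyl$height
  rad2 <- rowSums(rel^2) - t^2
  ins <- inAx & rad2 <= cyl$radius^2
  list(lin = linIndex(g[ins, , drop = FALSE], dims), n = sum(ins))
}

#' Compute the five step features of a candidate cylinder
#'
#' The features scored by the step forest: (f1) the fraction of cylinder
#' voxels that are vessel, (f2) the variance (mm^2) of the distances from the
#' end-face center to the vessel-region edge measured along rays in the
#' end-face plane, (f3) the angle between the cylinder axis and the previous
#' axis, (f4) the vessel voxel count in the 5x5x5 neighborhood of the
#' cylinder end, and (f5) the three Hessian eigenvalues (sigma = 1.5 voxels,
#' 11^3 neighborhoods) of the original image averaged over the two cylinder
#' endpoints, sorted ascending.
#'
#' @param cyl A [cylinder()].
#' @param prevAxis Previous step's unit axis.
#' @param mask A [VesselMask-class].
#' @param original The original (intensity) [MRAVolume-class].
#' @param nRays Rays for the edge-distance feature (default 8).
#' @return Named numeric: `f1, f2, f3, f4, f5a, f5b, f5c`.
#' @export
computeStepFeatures <- function(cyl, prevAxis, mask, original, nRays = 8) {
  d <- dim(imgData(mask)); sp <- spacing(mask)
  cv <- cylinderVoxels(cyl, d, sp, origin(mask))
  if (cv$n == 0) {
    extent <- (d - 1) * sp
    insideBase <- all(cyl$base >= 0) && all(cyl$base <= extent)
    insideEnd <- all(cyl$end >= 0) && all(cyl$end <= extent)
    if (!insideBase && !insideEnd)
      stop("cylinder lies fully outside the grid")
  }
  f1 <- if (cv$n > 0) sum(imgData(mask)[cv$lin]) / cv$n else 0
  rays <- rayBoundaryDistances(mask, cyl$end, cyl$axis, nRays,
                               maxReach = max(4 * cyl$radius, 8 * min(sp)))
  f2 <- if (nRays > 1) var(rays) else 0
  f3 <- vectorAngle(cyl$axis, unitVector(prevAxis))
  endIdx <- mmToNearestIndex(matrix(cyl$end, 1, 3), sp, d, origin(mask))[1, ]
  ii <- clamp(endIdx[1] + (-2):2, 1L, d[1])
  jj <- clamp(endIdx[2] + (-2):2, 1L, d[2])
  kk <- clamp(endIdx[3] + (-2):2, 1L, d[3])
  f4 <- sum(imgData(mask)[unique(ii), unique(jj), unique(kk)])
  ev <- (hessianEigenAt(original, cyl$base) +
         hessianEigenAt(original, cyl$end)) / 2
  c(f1 = f1, f2 = f2, f3 = f3, f4 = f4,
    f5a = ev[1], f5b = ev[2], f5c = ev[3])
}
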