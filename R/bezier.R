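## cubic Bezier evaluation and derivatives for one 4 x 3 segment
bezierPoint <- function(cp, t) {
  b <- cbind((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
  b %*% cp
}

bezierD1 <- function(cp, t) {
  b <- cbind(-3 * (1 - t)^2, 3 * (1 - t)^2 - 6 * t * (1 - t),
             6 * t * (1 - t) - 3 * t^2, 3 * t^2)
  b %*% cp
}

bezierD2 <- function(cp, t) {
  b <- cbind(6 * (1 - t), -12 * (1 - t) + 6 * t, 6 * (1 - t) - 12 * t, 6 * t)
  b %*% cp
}

#' Fit an interpolating C1 piecewise cubic Bezier centerline
#'
#' Third-order Bezier segments interpolate the input points exactly, with
#' inner control points derived from local (Catmull-Rom style) tangent
#' estimates so that consecutive segments join with continuous first
#' derivatives. Duplicate consecutive points are collapsed.
#'
#' @param points Ordered n x 3 matrix of centerline samples (mm), n >= 2
#'   distinct points.
#' @return A [BezierCenterline-class].
#' @export
fitCenterline <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) >= 2) {
    keep <- c(TRUE, rowSums((p[-1, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE])^2) > 1e-18)
    p <- p[keep, , drop = FALSE]
  }
  if (nrow(p) < 2) stop("need at least 2 distinct points")
  n <- nrow(p)
  ## tangents: central differences inside, one-sided at the ends
  tang <- matrix(0, n, 3)
  if (n == 2) {
    tang[1, ] <- tang[2, ] <- p[2, ] - p[1, ]
  } else {
    tang[1, ] <- p[2, ] - p[1, ]
    tang[n, ] <- p[n, ] - p[n - 1, ]
    for (i in 2:(n - 1)) tang[i, ] <- (p[i + 1, ] - p[i - 1, ]) / 2
  }
  segs <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    segs[[i]] <- rbind(p[i, ],
                       p[i, ] + tang[i, ] / 3,
                       p[i + 1, ] - tang[i + 1, ] / 3,
                       p[i + 1, ])
  }
  new("BezierCenterline", segments = segs, knots = p)
}

#' Sample a Bezier centerline
#'
#' @param c A [BezierCenterline-class].
#' @param nPerSegment Samples per segment (default 16).
#' @return List with `points` (m x 3), `tangents` (m x 3 unit vectors), and
#'   `curvature` (1/mm at each sample, from the analytic derivatives).
#' @export
sampleCenterline <- function(c, nPerSegment = 16L) {
  pts <- list(); tans <- list(); curv <- list()
  nSeg <- length(c@segments)
  for (i in seq_len(nSeg)) {
    tt <- seq(0, 1, length.out = nPerSegment + 1)
    if (i < nSeg) tt <- tt[-length(tt)]
    cp <- c@segments[[i]]
    P <- bezierPoint(cp, tt)
    D1 <- bezierD1(cp, tt)
    D2 <- bezierD2(cp, tt)
    sp1 <- sqrt(rowSums(D1^2))
    cr <- pracmaCrossRows(D1, D2)
    k <- sqrt(rowSums(cr^2)) / pmax(sp1^3, 1e-12)
    pts[[i]] <- P
    tans[[i]] <- D1 / pmax(sp1, 1e-12)
    curv[[i]] <- k
  }
  list(points = do.call(rbind, pts), tangents = do.call(rbind, tans),
       curvature = unlist(curv))
}

pracmaCrossRows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Arc length of a Bezier centerline
#'
#' Adaptive polyline refinement: sample density doubles until the relative
#' length change falls below `tol`.
#'
#' @param c A [BezierCenterline-class].
#' @param tol Relative convergence tolerance (default 1e-4).
#' @return Length in mm.
#' @export
arcLength <- function(c, tol = 1e-4) {
  n <- 8L
  len <- polylineLength(sampleCenterline(c, n)$points)
  repeat {
    n <- n * 2L
    len2 <- polylineLength(sampleCenterline(c, n)$points)
    if (abs(len2 - len) <= tol * max(len2, 1e-12) || n > 2048) return(len2)
    len <- len2
  }
}

#' Evaluate a centerline at arc-length-uniform stations
#'
#' @param c A [BezierCenterline-class].
#' @param ds Station spacing in mm (default 0.5); endpoints always included.
#' @return List with `points`, `tangents`, `curvature`, `s` (arc length at
#'   each station).
#' @export
sampleUniform <- function(c, ds = 0.5) {
  dense <- sampleCenterline(c, 64L)
  seg <- sqrt(rowSums((dense$points[-1, , drop = FALSE] -
                       dense$points[-nrow(dense$points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  stations <- unique(c(seq(0, total, by = ds), total))
  idx <- vapply(stations, function(si) which.min(abs(s - si)), integer(1))
  list(points = dense$points[idx, , drop = FALSE],
       tangents = dense$tangents[idx, , drop = FALSE],
       curvature = dense$curvature[idx], s = s[idx])
}
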