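#' @keywords internal
"_PACKAGE"

#' @importFrom methods new validObject is slot
#' @importFrom stats quantile sd var median rnorm runif predict cor
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All randomness in the package flows from one global seed; each stage draws
#' from its own substream so that adding a stage never perturbs another.
#'
#' @param seed Integer global seed.
#' @param name Character stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 1000003 + h * 7919) %% 2147483629 + 1)
}

unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

## angle between two unit vectors, safe against rounding
vectorAngle <- function(a, b) acos(clamp(sum(a * b), -1, 1))

## orthonormal basis (u, v) of the plane perpendicular to unit vector w
planeBasis <- function(w) {
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitVector(pracmaCross(w, ref))
  v <- pracmaCross(w, u)
  list(u = u, v = v)
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## offsets of the 26-neighborhood as a 26 x 3 integer matrix
neighborOffsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

## linear index <-> array index helpers for a 3D grid
linIndex <- function(ijk, dims) {
  ijk[, 1] + (ijk[, 2] - 1L) * dims[1] + (ijk[, 3] - 1L) * dims[1] * dims[2]
}

arrIndex <- function(lin, dims) {
  lin0 <- lin - 1L
  i <- lin0 %% dims[1]
  j <- (lin0 %/% dims[1]) %% dims[2]
  k <- lin0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

## voxel index (1-based) -> physical mm, and back
indexToMM <- function(ijk, spacing, origin = c(0, 0, 0)) {
  sweep(sweep(ijk - 1, 2, spacing, `*`), 2, origin, `+`)
}

mmToIndex <- function(xyz, spacing, origin = c(0, 0, 0)) {
  sweep(sweep(xyz, 2, origin, `-`), 2, spacing, `/`) + 1
}

## nearest voxel index with clamping to the grid
mmToNearestIndex <- function(xyz, spacing, dims, origin = c(0, 0, 0)) {
  idx <- round(mmToIndex(xyz, spacing, origin))
  for (a in 1:3) idx[, a] <- clamp(idx[, a], 1, dims[a])
  storage.mode(idx) <- "integer"
  idx
}

## symmetric grid around (and exactly containing) zero
symmetricGrid <- function(halfWidth, step) {
  m <- max(1L, ceiling(halfWidth / step))
  c(-(m:1), 0, 1:m) * step
}

## polyline length of an n x 3 matrix of points
polylineLength <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

## pairwise Euclidean distances between rows of a (n x 3) and b (m x 3),
## computed blockwise to bound memory
pairwiseMinDist <- function(a, b, block = 2000L) {
  n <- nrow(a)
  out <- numeric(n)
  b2 <- rowSums(b^2)
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1L, n)
    ab <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ab^2), b2, `+`) - 2 * tcrossprod(ab, b)
    mn <- apply(d2, 1, min)
    mn[mn < 1e-14] <- 0                  # roundoff of the expanded form
    out[s:e] <- sqrt(mn)
  }
  out
}
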