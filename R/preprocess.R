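#' Preprocessing configuration
#'
#' @param targetSpacing Isotropic working resolution in mm (default 0.10;
#'   0.10-0.20 trades detail against computation).
#' @param denoiseMethod `"mean"`, `"median"` or `"none"`.
#' @param denoiseKernel Odd kernel side in voxels (default 3).
#' @param biasMethod `"polynomial"` (smooth multiplicative surface fit) or
#'   `"none"`.
#' @param biasDegree Polynomial degree of the bias surface (default 3).
#' @param standardizeRange Output intensity interval (default c(0, 255)).
#' @return A `preprocessConfig` list.
#' @export
preprocessConfig <- function(targetSpacing = 0.10, denoiseMethod = "mean",
                             denoiseKernel = 3L, biasMethod = "polynomial",
                             biasDegree = 3L, standardizeRange = c(0, 255)) {
  if (targetSpacing <= 0) stop("targetSpacing must be > 0")
  if (denoiseKernel < 1 || denoiseKernel %% 2 == 0)
    stop("denoiseKernel must be odd and >= 1")
  structure(list(targetSpacing = targetSpacing,
                 denoiseMethod = match.arg(denoiseMethod,
                                           c("mean", "median", "none")),
                 denoiseKernel = as.integer(denoiseKernel),
                 biasMethod = match.arg(biasMethod, c("polynomial", "none")),
                 biasDegree = as.integer(biasDegree),
                 standardizeRange = standardizeRange),
            class = "preprocessConfig")
}

## polynomial design matrix over normalized [-1,1]^3 coordinates
polyDesign <- function(coords, degree) {
  cols <- list(rep(1, nrow(coords)))
  for (d in 1:degree) {
    for (i in 0:d) for (j in 0:(d - i)) {
      k <- d - i - j
      cols[[length(cols) + 1]] <-
        coords[, 1]^i * coords[, 2]^j * coords[, 3]^k
    }
  }
  do.call(cbind, cols)
}

#' Correct a smooth multiplicative bias field
#'
#' Estimates the bias as a low-degree polynomial surface fitted by least
#' squares to log intensities, then divides it out. The field is strictly
#' positive and normalized to unit geometric mean, and the output is rescaled
#' so the mean intensity is preserved. Volumes containing non-positive
#' intensities are shifted positive before the log fit and shifted back
#' afterwards. An (almost) constant volume is returned unchanged.
#'
#' @param v An [MRAVolume-class] (raw scale).
#' @param config A [preprocessConfig()].
#' @param nFit Maximum number of voxels used in the least-squares fit
#'   (subsampled deterministically).
#' @return The corrected [MRAVolume-class]; the estimated field is attached
#'   as `attr(, "biasField")`.
#' @export
correctBias <- function(v, config = preprocessConfig(), nFit = 50000L) {
  stopifnot(is(v, "MRAVolume"))
  x <- imgData(v)
  if (config$biasMethod == "none") return(v)
  if (sd(x) < 1e-9 * (abs(mean(x)) + 1)) return(v)  # constant: identity

  dims <- dim(x)
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift

  n <- prod(dims)
  idx <- if (n > nFit) round(seq(1, n, length.out = nFit)) else seq_len(n)
  ijk <- arrIndex(idx, dims)
  coords <- sweep(sweep(ijk - 1, 2, pmax(dims - 1, 1) / 2, `/`), 2,
                  rep(1, 3), `-`)
  X <- polyDesign(coords, config$biasDegree)
  fit <- stats::lm.fit(X, log(xs[idx]))

  ijkAll <- arrIndex(seq_len(n), dims)
  coordsAll <- sweep(sweep(ijkAll - 1, 2, pmax(dims - 1, 1) / 2, `/`), 2,
                     rep(1, 3), `-`)
  pred <- polyDesign(coordsAll, config$biasDegree) %*% fit$coefficients
  field <- array(exp(pred - mean(pred)), dim = dims)  # unit geometric mean

  corr <- xs / field
  corr <- corr * (mean(xs) / mean(corr))              # preserve mean
  out <- MRAVolume(array(corr - shift, dim = dims), spacing(v), origin(v),
                   intensityScale(v))
  attr(out, "biasField") <- field
  out
}

## 1D box mean along axis `a` with replicate padding
boxFilterAxis <- function(x, k, a) {
  if (k == 1) return(x)
  h <- (k - 1) %/% 2
  d <- dim(x)
  perm <- c(a, setdiff(1:3, a))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[a])
  padTop <- m[rep(1, h), , drop = FALSE]
  padBot <- m[rep(nrow(m), h), , drop = FALSE]
  mp <- rbind(padTop, m, padBot)
  cs <- apply(mp, 2, cumsum)
  cs <- rbind(0, cs)
  out <- (cs[(k + 1):(k + d[a]), , drop = FALSE] -
          cs[1:d[a], , drop = FALSE]) / k
  res <- array(out, dim = d[perm])
  aperm(res, order(perm))
}

#' Denoise a volume
#'
#' `"mean"` applies a separable linear box filter of the configured kernel
#' (constant regions are unchanged, edges handled by replication); `"median"`
#' applies a full 3D moving-median of the same kernel.
#'
#' @param v An [MRAVolume-class].
#' @param config A [preprocessConfig()].
#' @return The filtered [MRAVolume-class].
#' @export
denoiseVolume <- function(v, config = preprocessConfig()) {
  stopifnot(is(v, "MRAVolume"))
  k <- config$denoiseKernel
  if (config$denoiseMethod == "none" || k == 1) return(v)
  x <- imgData(v)
  if (config$denoiseMethod == "mean") {
    for (a in 1:3) x <- boxFilterAxis(x, k, a)
  } else {
    x <- medianFilter3(x, k)
  }
  MRAVolume(x, spacing(v), origin(v), intensityScale(v))
}

## full 3D moving median via neighborhood gather
medianFilter3 <- function(x, k) {
  d <- dim(x); h <- (k - 1) %/% 2
  clampIdx <- function(i, n) pmin(pmax(i, 1L), n)
  rel <- as.matrix(expand.grid(-h:h, -h:h, -h:h))
  n <- prod(d)
  ijk <- arrIndex(seq_len(n), d)
  cols <- matrix(0, n, nrow(rel))
  for (r in seq_len(nrow(rel))) {
    ii <- cbind(clampIdx(ijk[, 1] + rel[r, 1], d[1]),
                clampIdx(ijk[, 2] + rel[r, 2], d[2]),
                clampIdx(ijk[, 3] + rel[r, 3], d[3]))
    cols[, r] <- x[linIndex(ii, d)]
  }
  array(apply(cols, 1, median), dim = d)
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation onto a grid whose physical extent equals the
#' input's within one target voxel; voxel (1,1,1) stays at the same physical
#' position. If the input is already isotropic at the target spacing the grid
#' is returned unchanged. Masks are resampled with nearest-neighbor
#' interpolation so they stay binary.
#'
#' @param v An [MRAVolume-class] or [VesselMask-class].
#' @param targetSpacing Target isotropic spacing in mm (>= 0.01).
#' @return The resampled object with `spacing = rep(targetSpacing, 3)`.
#' @export
resampleIsotropic <- function(v, targetSpacing = 0.10) {
  if (targetSpacing <= 0) stop("targetSpacing must be > 0")
  if (targetSpacing < 0.01)
    stop("targetSpacing below 0.01 mm refused (memory guard)")
  isMask <- is(v, "VesselMask")
  sp <- spacing(v)
  x <- imgData(v)
  d <- dim(x)
  if (all(abs(sp - targetSpacing) < 1e-12)) return(v)
  newDim <- pmax(2L, as.integer(floor((d - 1) * sp / targetSpacing + 1e-9)) + 1L)

  ## fractional source coordinates per output axis (1-based)
  src <- lapply(1:3, function(a) {
    s <- (seq_len(newDim[a]) - 1) * targetSpacing / sp[a] + 1
    clamp(s, 1, d[a])
  })
  if (isMask) {
    idx <- lapply(1:3, function(a) clamp(round(src[[a]]), 1, d[a]))
    out <- x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    return(VesselMask(out, rep(targetSpacing, 3), origin(v)))
  }
  i0 <- lapply(1:3, function(a) pmin(floor(src[[a]]), d[a] - 1))
  fr <- lapply(1:3, function(a) src[[a]] - i0[[a]])
  out <- array(0, dim = newDim)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
    sub <- x[i0[[1]] + cx, i0[[2]] + cy, i0[[3]] + cz, drop = FALSE]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * sub
  }
  MRAVolume(out, rep(targetSpacing, 3), origin(v), intensityScale(v))
}

#' Standardize intensities to a fixed range
#'
#' Linearly rescales the robust intensity window (0.5th to 99.5th percentile)
#' onto the standardized range (default [0, 255]) and clips, so that the
#' pre-screening thresholds 80 and 120 are portable across inputs. The
#' operation is idempotent: an already standardized volume is returned
#' unchanged. A constant volume maps to the range midpoint and is flagged via
#' `attr(, "flag")`.
#'
#' @param v An [MRAVolume-class].
#' @param range Output interval (default c(0, 255)).
#' @param probs Robust window percentiles (default c(0.005, 0.995)).
#' @return The standardized [MRAVolume-class] (tag `"standardized"`).
#' @export
standardizeIntensity <- function(v, range = c(0, 255),
                                 probs = c(0.005, 0.995)) {
  stopifnot(is(v, "MRAVolume"))
  if (intensityScale(v) == "standardized") return(v)
  x <- imgData(v)
  q <- quantile(x, probs, names = FALSE)
  if (q[2] - q[1] < 1e-12) {
    out <- MRAVolume(array(mean(range), dim = dim(x)), spacing(v), origin(v),
                     "standardized")
    attr(out, "flag") <- "constant-volume"
    return(out)
  }
  y <- (x - q[1]) / (q[2] - q[1]) * (range[2] - range[1]) + range[1]
  MRAVolume(clamp(y, range[1], range[2]), spacing(v), origin(v),
            "standardized")
}

#' Run the full preprocessing chain
#'
#' Applies bias correction, denoising, isotropic resampling, and intensity
#' standardization, in that order; stages already satisfied (e.g. an input
#' already standardized) are skipped.
#'
#' @param v An [MRAVolume-class].
#' @param config A [preprocessConfig()].
#' @return The preprocessed [MRAVolume-class].
#' @export
preprocessVolume <- function(v, config = preprocessConfig()) {
  if (intensityScale(v) == "raw") v <- correctBias(v, config)
  v <- denoiseVolume(v, config)
  v <- resampleIsotropic(v, config$targetSpacing)
  standardizeIntensity(v, config$standardizeRange)
}
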