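#' Tracking configuration
#'
#' @param maxTurnDeg Maximum turning angle between consecutive cylinder axes
#'   in degrees (default 60).
#' @param radiusFactors Candidate radii as multiples of the current radius.
#' @param stepHeightVox Cylinder height in voxels (default 3).
#' @param stopThreshold Minimum step score to continue (default 0.5).
#' @param lambdaCurv Curvature penalty weight in the energy term.
#' @param lambdaEnergy Weight of the energy term in the step score.
#' @param shellFactor Bifurcation shell radius as a multiple of the local
#'   radius (default 2).
#' @param maxSteps Per-branch step cap.
#' @param maxBranches Total branch cap per traced tree.
#' @param revisitFraction Candidate cylinders claiming more than this
#'   fraction of already-visited vessel voxels are discarded (prevents
#'   re-tracing).
#' @param nRays Rays used in edge-distance features.
#' @param minRadiusVox,maxRadiusMM Radius clamps (voxels / mm).
#' @return A `trackingConfig` list.
#' @export
trackingConfig <- function(maxTurnDeg = 60, radiusFactors = c(0.5, 0.75, 1, 1.25, 1.5),
                           stepHeightVox = 3, stopThreshold = 0.5,
                           lambdaCurv = 0.5, lambdaEnergy = 0.2,
                           shellFactor = 2, maxSteps = 200L,
                           maxBranches = 64L, revisitFraction = 0.8,
                           nRays = 8L, minRadiusVox = 0.8, maxRadiusMM = 1.5) {
  structure(as.list(environment()), class = "trackingConfig")
}

#' Step-forest configuration
#'
#' The step classifier is an ensemble of `nTrees` decision trees (default
#' 2,000) with randomized training samples per tree; `nIterations` records
#' the resampling rounds of the training protocol (each tree draws its own
#' bootstrap sample). A 0.2 train fraction mirrors the 2,800 : 11,200
#' train-test protocol the forest was validated under.
#'
#' @param nTrees Number of trees (default 2000).
#' @param nIterations Resampling rounds (default 100; bookkeeping).
#' @param sampleRandomization Randomize training samples per tree.
#' @param trainFraction Fraction used for training; the rest measures
#'   out-of-sample accuracy (default 0.2).
#' @param seed Integer seed.
#' @return A `stepForestConfig` list.
#' @export
stepForestConfig <- function(nTrees = 2000L, nIterations = 100L,
                             sampleRandomization = TRUE, trainFraction = 0.2,
                             seed = 1L) {
  if (nTrees < 1) stop("nTrees must be >= 1")
  structure(list(nTrees = as.integer(nTrees),
                 nIterations = as.integer(nIterations),
                 sampleRandomization = sampleRandomization,
                 trainFraction = trainFraction, seed = as.integer(seed)),
            class = "stepForestConfig")
}

## ---- connected components / geodesics on the voxel graph -----------------

## 26-connected components of a logical array; returns integer labels
connectedComponents <- function(m) {
  d <- dim(m)
  labels <- array(0L, dim = d)
  off <- neighborOffsets26()
  todo <- which(m)
  lab <- 0L
  unvisited <- m
  while (length(todo <- which(unvisited))) {
    lab <- lab + 1L
    frontier <- todo[1]
    unvisited[frontier] <- FALSE
    labels[frontier] <- lab
    while (length(frontier)) {
      ijk <- arrIndex(frontier, d)
      cand <- ijk[rep(seq_len(nrow(ijk)), each = 26), , drop = FALSE] +
        off[rep(seq_len(26), nrow(ijk)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      lin <- unique(linIndex(cand[ok, , drop = FALSE], d))
      lin <- lin[unvisited[lin]]
      if (length(lin)) {
        unvisited[lin] <- FALSE
        labels[lin] <- lab
      }
      frontier <- lin
    }
  }
  labels
}

## BFS geodesic (step-count) distances within a voxel set from a start voxel
bfsDistances <- function(m, startLin) {
  d <- dim(m)
  dist <- array(NA_integer_, dim = d)
  dist[startLin] <- 0L
  frontier <- startLin
  off <- neighborOffsets26()
  lvl <- 0L
  while (length(frontier)) {
    lvl <- lvl + 1L
    ijk <- arrIndex(frontier, d)
    cand <- ijk[rep(seq_len(nrow(ijk)), each = 26), , drop = FALSE] +
      off[rep(seq_len(26), nrow(ijk)), , drop = FALSE]
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    lin <- unique(linIndex(cand[ok, , drop = FALSE], d))
    lin <- lin[m[lin] & is.na(dist[lin])]
    if (length(lin)) dist[lin] <- lvl
    frontier <- lin
  }
  dist
}

## move a point onto the centroid of its perpendicular mask cross-section;
## shift capped at one local radius
recenterPoint <- function(mask, point, axis, radius) {
  sp <- min(spacing(mask))
  rr <- symmetricGrid(2 * radius, sp / 2)
  g2 <- as.matrix(expand.grid(u = rr, v = rr))
  basis <- planeBasis(axis)
  pts <- outer(rep(1, nrow(g2)), point) +
    outer(g2[, 1], basis$u) + outer(g2[, 2], basis$v)
  inside <- maskAtMM(mask, pts)
  n <- length(rr)
  ctr <- which(g2[, 1] == 0 & g2[, 2] == 0)
  if (!inside[ctr]) return(point)
  img <- matrix(inside, n, n)
  comp <- floodFill2(img, ((ctr - 1) %% n) + 1, ((ctr - 1) %/% n) + 1)
  sel <- as.vector(comp)
  shift <- c(mean(g2[sel, 1]), mean(g2[sel, 2]))
  if (sqrt(sum(shift^2)) > radius) shift <- shift * radius / sqrt(sum(shift^2))
  point + shift[1] * basis$u + shift[2] * basis$v
}

## crude local radius estimate from perpendicular boundary rays
estimateLocalRadius <- function(mask, point, dir, nRays = 8) {
  r <- mean(rayBoundaryDistances(mask, point, dir, nRays,
                                 maxReach = 12 * min(spacing(mask))))
  max(r, 0.8 * min(spacing(mask)))
}

#' Keep only substantial components of a large-vessel mask
#'
#' Isolated voxels above the large-vessel threshold are noise outliers, not
#' arteries; for seeding and artifact screening only connected components of
#' a meaningful size count as large vessel.
#'
#' @param largeMask A [VesselMask-class] (or `NULL`).
#' @param minVoxels Minimum component size (default 100).
#' @return The cleaned [VesselMask-class] (or `NULL`).
#' @export
cleanLargeVesselMask <- function(largeMask, minVoxels = 100L) {
  if (is.null(largeMask) || sum(imgData(largeMask)) == 0) return(largeMask)
  labels <- connectedComponents(imgData(largeMask))
  keep <- array(FALSE, dim = dim(labels))
  for (cc in seq_len(max(labels))) {
    lin <- which(labels == cc)
    if (length(lin) >= minVoxels) keep[lin] <- TRUE
  }
  VesselMask(keep, spacing(largeMask), origin(largeMask))
}

#' Detect tracking seed points
#'
#' With a non-empty large-vessel mask, seeds are placed where small-vessel
#' components abut the large vessel, with the initial direction pointing away
#' from it — emulating tracking that starts at the origins of the parent
#' arteries. Without a large vessel (pure phantom mode), one seed is placed
#' at a geodesic endpoint of each mask component, pointing into the tube.
#'
#' @param mask Small-vessel [VesselMask-class].
#' @param largeMask Optional large-vessel [VesselMask-class].
#' @param config A [trackingConfig()].
#' @return List of seeds, each with `point` (mm), `direction` (unit vector),
#'   and `radius` (mm).
#' @export
detectSeeds <- function(mask, largeMask = NULL, config = trackingConfig()) {
  m <- imgData(mask); d <- dim(m); sp <- spacing(mask)
  if (!sum(m)) return(list())
  labels <- connectedComponents(m)
  nComp <- max(labels)
  haveLarge <- !is.null(largeMask) && sum(imgData(largeMask)) > 0
  seeds <- list()
  largeDil <- NULL
  if (haveLarge) {
    lg <- imgData(largeMask)
    off <- neighborOffsets26()
    lin <- which(lg)
    ijk <- arrIndex(lin, d)
    cand <- ijk[rep(seq_len(nrow(ijk)), each = 26), , drop = FALSE] +
      off[rep(seq_len(26), nrow(ijk)), , drop = FALSE]
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    largeDil <- lg
    largeDil[unique(linIndex(cand[ok, , drop = FALSE], d))] <- TRUE
  }
  for (cc in seq_len(nComp)) {
    compLin <- which(labels == cc)
    if (length(compLin) < 5) next      # specks cannot anchor a trace
    attached <- FALSE
    if (haveLarge) {
      abut <- compLin[largeDil[compLin]]
      if (length(abut)) {
        attached <- TRUE
        seedPt <- colMeans(indexToMM(arrIndex(abut, d), sp, origin(mask)))
        compPts <- indexToMM(arrIndex(compLin, d), sp, origin(mask))
        dd <- sqrt(rowSums(sweep(compPts, 2, seedPt, `-`)^2))
        nearPts <- compPts[dd <= 10 * min(sp) & dd > 0.5 * min(sp), ,
                           drop = FALSE]
        if (nrow(nearPts) < 2) nearPts <- compPts
        dvec <- colMeans(nearPts) - seedPt
        if (sqrt(sum(dvec^2)) < 1e-9) next
        dir <- unitVector(dvec)
        rad <- estimateLocalRadius(mask, seedPt + dir * 2 * min(sp), dir,
                                   config$nRays)
        seedPt <- recenterPoint(mask, seedPt, dir, max(rad, 2 * min(sp)))
        seeds[[length(seeds) + 1]] <-
          list(point = seedPt, direction = dir, radius = rad)
      }
    }
    if (!attached) {
      ## geodesic endpoint: farthest voxel from an arbitrary start, twice
      comp <- array(FALSE, dim = d); comp[compLin] <- TRUE
      d1 <- bfsDistances(comp, compLin[1])
      a <- compLin[which.max(d1[compLin])]
      d2 <- bfsDistances(comp, a)
      seedPt <- indexToMM(arrIndex(a, d), sp, origin(mask))[1, ]
      ## direction: toward voxels a few geodesic steps inward
      lvls <- d2[compLin]
      inward <- compLin[lvls >= 2 & lvls <= 6]
      if (!length(inward)) inward <- compLin[which.max(lvls)]
      tgt <- colMeans(indexToMM(arrIndex(inward, d), sp, origin(mask)))
      if (sqrt(sum((tgt - seedPt)^2)) < 1e-9) next
      dir <- unitVector(tgt - seedPt)
      ## endpoint voxels sit on the (possibly ragged) tube cap: recenter the
      ## seed into the lumen, then probe the caliber at recentered depths
      ## along the inward direction and re-aim through the deepest probe
      sp1 <- min(sp)
      seedPt <- recenterPoint(mask, seedPt + dir * sp1, dir, 3 * sp1)
      probes <- list()
      for (depth in c(2, 4, 6)) {
        q <- recenterPoint(mask, seedPt + dir * depth * sp1, dir, 4 * sp1)
        if (maskAtMM(mask, matrix(q, 1, 3)))
          probes[[length(probes) + 1]] <- q
      }
      if (length(probes)) {
        qf <- probes[[length(probes)]]
        if (sqrt(sum((qf - seedPt)^2)) > sp1 / 2)
          dir <- unitVector(qf - seedPt)
        rad <- max(vapply(probes, function(q)
          estimateLocalRadius(mask, q, dir, config$nRays), numeric(1)))
      } else {
        rad <- estimateLocalRadius(mask, seedPt + dir * 2 * sp1, dir,
                                   config$nRays)
      }
      seeds[[length(seeds) + 1]] <-
        list(point = seedPt, direction = dir, radius = rad)
    }
  }
  seeds
}

#' Generate labeled step examples from a rendered phantom
#'
#' Valid steps are cylinders centered on ground-truth centerline samples and
#' aligned with the local tube direction; invalid steps are cylinders at
#' random off-vessel positions or on-vessel with strongly misaligned axes.
#'
#' @param phantom A rendered phantom from [renderPhantom()].
#' @param nValid,nInvalid Example counts.
#' @param config A [trackingConfig()].
#' @param mask Optional [VesselMask-class] on which features are computed
#'   (labels still come from the ground-truth centerlines). Passing an
#'   actual segmentation output here trains the forest on the ragged masks
#'   it will track at run time.
#' @param seed Integer seed.
#' @return Data frame of step features plus a `label` column (1 = valid).
#' @export
makeStepExamples <- function(phantom, nValid, nInvalid,
                             config = trackingConfig(), mask = NULL,
                             seed = 1L) {
  v <- phantom$volume; tr <- phantom$truth
  mask <- mask %||% tr$mask
  sp <- spacing(v); d <- dim(imgData(v)); extent <- (d - 1) * sp
  h <- config$stepHeightVox * min(sp)
  cl <- do.call(rbind, tr$centerlines)
  dirs <- do.call(rbind, tr$dirs)
  radii <- unlist(tr$radii)
  set.seed(deriveSeed(seed, "step-examples"))
  rows <- list()
  addRow <- function(cyl, prevAxis, label) {
    f <- tryCatch(computeStepFeatures(cyl, prevAxis, mask, v, config$nRays),
                  error = function(e) NULL)
    if (!is.null(f)) rows[[length(rows) + 1]] <<- c(f, label = label)
  }
  ## valid steps come from tube interiors: at least one step height away
  ## from the tube's own endpoints and from the grid boundary
  interior <- logical(nrow(cl))
  tubeEnds <- list()
  csum <- 0L
  for (t in seq_along(tr$centerlines)) {
    ct <- tr$centerlines[[t]]
    n_t <- nrow(ct)
    seg <- sqrt(rowSums((ct[-1, , drop = FALSE] -
                         ct[-n_t, , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    interior[csum + seq_len(n_t)] <- s > h / 2 & s < s[n_t] - h / 2
    tubeEnds[[length(tubeEnds) + 1]] <-
      list(p = ct[1, ], d = -tr$dirs[[t]][1, ], r = tr$radii[[t]][1])
    tubeEnds[[length(tubeEnds) + 1]] <-
      list(p = ct[n_t, ], d = tr$dirs[[t]][n_t, ], r = tr$radii[[t]][n_t])
    csum <- csum + n_t
  }
  inGrid <- cl[, 1] > h & cl[, 1] < extent[1] - h &
    cl[, 2] > h & cl[, 2] < extent[2] - h &
    cl[, 3] > h & cl[, 3] < extent[3] - h
  idxPool <- which(interior & inGrid)
  ## valid steps are jittered the way real tracking steps are: slightly
  ## off-center, slightly misaligned, radius off by up to a quarter — the
  ## forest must accept imperfect-but-correct steps, not only pristine ones
  for (i in sample(idxPool, min(nValid, length(idxPool)))) {
    axis <- unitVector(dirs[i, ] + rnorm(3, 0, 0.12))
    basis <- planeBasis(axis)
    jit <- runif(1, 0, 0.4 * radii[i])
    phi <- runif(1, 0, 2 * pi)
    ctr <- cl[i, ] + jit * (cos(phi) * basis$u + sin(phi) * basis$v)
    r <- radii[i] * runif(1, 0.75, 1.25)
    cyl <- cylinder(ctr - axis * h / 2, axis, r, h)
    prev <- unitVector(axis + rnorm(3, 0, 0.1))
    addRow(cyl, prev, 1)
  }
  nOff <- ceiling(nInvalid * 0.4)        # off-vessel cylinders
  for (i in seq_len(nOff)) {
    p <- runif(3, 0.1, 0.9) * extent
    axis <- unitVector(rnorm(3))
    near <- min(pairwiseMinDist(matrix(p, 1, 3), cl))
    if (near < 3 * min(sp)) p <- clamp(p + 6 * min(sp), 0, extent)
    cyl <- cylinder(p, axis, max(radii[1], min(sp)), h)
    addRow(cyl, axis, 0)
  }
  nOver <- ceiling(nInvalid * 0.2)       # overshoot past a tube end
  for (i in seq_len(nOver)) {
    te <- tubeEnds[[sample(length(tubeEnds), 1)]]
    cyl <- cylinder(te$p + te$d * runif(1, 0, h / 2), te$d, te$r, h)
    addRow(cyl, te$d, 0)
  }
  for (i in sample(idxPool, min(nInvalid - nOff - nOver,
                                length(idxPool)))) {
    axis0 <- dirs[i, ]                    # on-vessel, wrong direction
    perp <- planeBasis(axis0)$u
    cyl <- cylinder(cl[i, ], perp, radii[i], h)
    addRow(cyl, axis0, 0)
  }
  df <- as.data.frame(do.call(rbind, rows))
  df$label <- as.integer(df$label)
  df
}

#' Train the random-forest step classifier
#'
#' Trains an ensemble of decision trees (default 2,000, each on its own
#' randomized bootstrap sample) on labeled step features and reports
#' out-of-sample accuracy on the held-out fraction.
#'
#' @param examples Data frame from [makeStepExamples()] (feature columns +
#'   `label`).
#' @param config A [stepForestConfig()].
#' @return A `stepForest` list with the fitted ensemble, the held-out
#'   `accuracy`, and the config.
#' @export
trainStepForest <- function(examples, config = stepForestConfig()) {
  if (length(unique(examples$label)) < 2)
    stop("step examples must contain both classes")
  set.seed(deriveSeed(config$seed, "step-forest-split"))
  n <- nrow(examples)
  trIdx <- sample(n, max(2, round(config$trainFraction * n)))
  train <- examples[trIdx, , drop = FALSE]
  test <- examples[-trIdx, , drop = FALSE]
  if (length(unique(train$label)) < 2)
    stop("training fraction ended up single-class; increase trainFraction")
  train$label <- factor(train$label, levels = c(0, 1))
  fit <- ranger::ranger(label ~ ., data = train,
                        num.trees = config$nTrees, probability = TRUE,
                        replace = config$sampleRandomization,
                        seed = deriveSeed(config$seed, "step-forest"),
                        num.threads = 1)
  acc <- NA_real_
  if (nrow(test)) {
    p <- predict(fit, test[, setdiff(names(test), "label"), drop = FALSE],
                 num.threads = 1)$predictions[, "1"]
    acc <- mean((p >= 0.5) == (test$label == 1))
  }
  structure(list(model = fit, accuracy = acc, config = config),
            class = "stepForest")
}

#' Predict step validity probabilities
#'
#' @param forest A `stepForest` from [trainStepForest()].
#' @param features Matrix or data frame of step feature rows.
#' @return Numeric probabilities that each step is valid.
#' @export
predictStepForest <- function(forest, features) {
  df <- as.data.frame(features)
  predict(forest$model, df, num.threads = 1)$predictions[, "1"]
}

#' Detect bifurcations with a spherical-shell test
#'
#' Intersects a spherical shell of radius `shellFactor` times the local
#' radius with the vessel mask and counts 26-connected components among the
#' shell voxels. The component pointing back along the incoming direction is
#' the inflow; the remaining components' centroid directions are returned
#' (the best-aligned one is the continuation, extra ones are children).
#'
#' @param point Length-3 mm position.
#' @param radius Local vessel radius in mm.
#' @param mask A [VesselMask-class].
#' @param incomingDir Optional unit vector of travel; when given, the inflow
#'   component is removed from the result.
#' @param config A [trackingConfig()].
#' @return List with `nComponents` and `directions` (k x 3 matrix of unit
#'   vectors, inflow excluded when `incomingDir` is given).
#' @export
detectBifurcation <- function(point, radius, mask, incomingDir = NULL,
                              config = trackingConfig()) {
  m <- imgData(mask); d <- dim(m); sp <- spacing(mask)
  R <- max(config$shellFactor * radius, 2.2 * min(sp))
  th <- 0.75 * min(sp)
  lo <- point - R - th; hi <- point + R + th
  i0 <- pmax(1L, as.integer(floor((lo - origin(mask)) / sp)) + 1L)
  i1 <- pmin(d, as.integer(ceiling((hi - origin(mask)) / sp)) + 1L)
  if (any(i0 > i1)) return(list(nComponents = 0L, directions = matrix(0, 0, 3)))
  g <- as.matrix(expand.grid(i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]))
  xyz <- indexToMM(g, sp, origin(mask))
  dd <- sqrt(rowSums(sweep(xyz, 2, point, `-`)^2))
  onShell <- abs(dd - R) <= th
  lin <- linIndex(g[onShell, , drop = FALSE], d)
  lin <- lin[m[lin]]
  if (!length(lin)) return(list(nComponents = 0L, directions = matrix(0, 0, 3)))
  shell <- array(FALSE, dim = d); shell[lin] <- TRUE
  labels <- connectedComponents(shell)
  ## single-voxel shell fragments are boundary noise, not vessels
  sizes <- tabulate(labels[labels > 0])
  comps <- which(sizes >= 2)
  nc <- length(comps)
  dirs <- matrix(0, nc, 3)
  for (i in seq_len(nc)) {
    ctr <- colMeans(indexToMM(arrIndex(which(labels == comps[i]), d), sp,
                              origin(mask)))
    dirs[i, ] <- unitVector(ctr - point)
  }
  if (!is.null(incomingDir) && nc > 0) {
    back <- dirs %*% (-unitVector(incomingDir))
    drop_i <- which.max(back)
    if (back[drop_i] > 0.3) dirs <- dirs[-drop_i, , drop = FALSE]
  }
  list(nComponents = nc, directions = dirs)
}

#' Advance the tracker by one cylinder step
#'
#' Enumerates candidate cylinders over a cone of directions (turning angle
#' capped) and a radius grid from the current cylinder's end, scores each by
#' the forest probability minus a weighted minimal-path-style energy
#' (curvature penalty minus boundary clearance), and returns the best
#' candidate if its score clears the stop threshold, else `NULL` (STOP).
#' Vessel voxels inside the accepted cylinder are claimed in `visited`.
#'
#' @param current The current [cylinder()].
#' @param prevAxis The previous step's axis.
#' @param mask,original Mask and intensity volume.
#' @param forest A trained `stepForest`.
#' @param config A [trackingConfig()].
#' @param visited Optional logical array of claimed voxels (same grid).
#' @param ignoreVisited Disable the revisit filter (used for the first steps
#'   of bifurcation children, which necessarily re-cross the junction).
#' @return List with `cyl`, `score`, `visited`, or `NULL` for STOP.
#' @export
stepCylinder <- function(current, prevAxis, mask, original, forest,
                         config = trackingConfig(), visited = NULL,
                         ignoreVisited = FALSE) {
  sp <- spacing(mask); d <- dim(imgData(mask)); extent <- (d - 1) * sp
  if (is.null(visited)) visited <- array(FALSE, dim = d)
  base <- current$end
  if (any(base < -2 * min(sp)) || any(base > extent + 2 * min(sp)))
    return(NULL)
  maxTurn <- config$maxTurnDeg * pi / 180
  offs <- neighborOffsets26()
  dirs <- offs / sqrt(rowSums(offs^2))
  keep <- (dirs %*% current$axis) >= cos(maxTurn) - 1e-9
  dirs <- rbind(current$axis, dirs[keep, , drop = FALSE])
  h <- config$stepHeightVox * min(sp)
  radii <- unique(clamp(config$radiusFactors * current$radius,
                        config$minRadiusVox * min(sp), config$maxRadiusMM))
  cands <- list(); feats <- list()
  for (di in seq_len(nrow(dirs))) {
    axis <- dirs[di, ]
    endPt <- base + axis * h
    ## rays and Hessian depend only on the endpoint: once per direction
    rays <- rayBoundaryDistances(mask, endPt, axis, config$nRays,
                                 maxReach = max(4 * current$radius,
                                                8 * min(sp)))
    rayEst <- clamp(mean(rays), config$minRadiusVox * min(sp),
                    config$maxRadiusMM)
    evCache <- NULL
    f3 <- vectorAngle(axis, prevAxis)
    for (r in radii) {
      cyl <- cylinder(base, axis, r, h)
      cv <- cylinderVoxels(cyl, d, sp, origin(mask))
      if (cv$n == 0) next
      maskIn <- imgData(mask)[cv$lin]
      if (!ignoreVisited && sum(maskIn) > 0 &&
          sum(visited[cv$lin] & maskIn) / max(sum(maskIn), 1) >
          config$revisitFraction) next
      f1 <- sum(maskIn) / cv$n
      f2 <- var(rays)
      endIdx <- mmToNearestIndex(matrix(endPt, 1, 3), sp, d,
                                 origin(mask))[1, ]
      ii <- unique(clamp(endIdx[1] + (-2):2, 1L, d[1]))
      jj <- unique(clamp(endIdx[2] + (-2):2, 1L, d[2]))
      kk <- unique(clamp(endIdx[3] + (-2):2, 1L, d[3]))
      f4 <- sum(imgData(mask)[ii, jj, kk])
      if (is.null(evCache))
        evCache <- (hessianEigenAt(original, cyl$base) +
                    hessianEigenAt(original, cyl$end)) / 2
      ## minimal-path-style energy: curvature penalty minus centeredness
      clearance <- min(rays) / max(rayEst, min(sp))
      energy <- config$lambdaCurv * f3^2 - clearance
      cands[[length(cands) + 1]] <- list(cyl = cyl, energy = energy,
                                         rayEst = rayEst)
      feats[[length(feats) + 1]] <-
        c(f1 = f1, f2 = f2, f3 = f3, f4 = f4,
          f5a = evCache[1], f5b = evCache[2], f5c = evCache[3])
    }
  }
  if (!length(cands)) return(NULL)
  fm <- as.data.frame(do.call(rbind, feats))
  p <- predictStepForest(forest, fm)
  score <- p - config$lambdaEnergy *
    vapply(cands, function(cd) cd$energy, numeric(1))
  best <- which.max(score)
  if (score[best] < config$stopThreshold) return(NULL)
  bc <- cands[[best]]
  ## the chosen cylinder takes the measured local radius, and its end is
  ## recentered onto the cross-section centroid (minimal-path centering)
  axis <- bc$cyl$axis
  newEnd <- recenterPoint(mask, bc$cyl$end, axis, bc$rayEst)
  cylOut <- cylinder(base, newEnd - base, bc$rayEst,
                     max(sqrt(sum((newEnd - base)^2)), 0.5 * h))
  ## respect the turning cap even after recentering
  if (vectorAngle(cylOut$axis, current$axis) > maxTurn)
    cylOut <- cylinder(base, bc$cyl$axis, bc$rayEst, h)
  cv <- cylinderVoxels(cylOut, d, sp, origin(mask))
  claim <- cv$lin[imgData(mask)[cv$lin]]
  visited[claim] <- TRUE
  list(cyl = cylOut, score = score[best], visited = visited)
}

## distance from a point to the nearest background (non-mask) voxel center:
## the local inscribed-sphere radius of the vessel lumen
clearanceAt <- function(mask, point, searchRadius) {
  m <- imgData(mask); d <- dim(m); sp <- spacing(mask)
  lo <- point - searchRadius; hi <- point + searchRadius
  i0 <- pmax(1L, as.integer(floor((lo - origin(mask)) / sp)) + 1L)
  i1 <- pmin(d, as.integer(ceiling((hi - origin(mask)) / sp)) + 1L)
  g <- as.matrix(expand.grid(i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]))
  bgSel <- !m[linIndex(g, d)]
  if (!any(bgSel)) return(searchRadius)
  xyz <- indexToMM(g[bgSel, , drop = FALSE], sp, origin(mask))
  sqrt(min(rowSums(sweep(xyz, 2, point, `-`)^2)))
}

## refine a bifurcation point. The shell test fires up to a shell radius
## before the true junction; the junction itself is where the recentered
## lumen is locally thickest (the inscribed sphere is largest where the
## three lumens merge), so march along the incoming axis, recenter each
## candidate in its perpendicular cross-section, and take the clearance
## maximum.
refineBifurcation <- function(point, axis, radius, mask,
                              config = trackingConfig()) {
  sp <- min(spacing(mask))
  R <- max(config$shellFactor * radius, 2.2 * sp)
  best <- point; bestC <- -Inf
  for (s in seq(0, 1.5 * R, by = 0.5 * sp)) {
    q <- recenterPoint(mask, point + axis * s, axis, radius)
    if (!maskAtMM(mask, matrix(q, 1, 3))) next
    cl <- clearanceAt(mask, q, 3 * radius + 2 * sp)
    if (cl > bestC) { bestC <- cl; best <- q }
  }
  best
}

#' Trace the full vascular tree from seed points
#'
#' Breadth-first tracing: each seed starts a primary branch that advances by
#' forest-scored cylinder steps. When the spherical-shell test reports two or
#' more outgoing components, the bifurcation point is localized by marching
#' to where the perpendicular cross-section splits, the branch terminates
#' there, and each outgoing component spawns a child branch with order =
#' parent order + 1. Visited-voxel claiming prevents re-tracing, and the
#' finite grid plus the step caps guarantee termination.
#'
#' @param seeds Seed list from [detectSeeds()].
#' @param mask,original Mask and intensity volume.
#' @param forest A trained `stepForest`.
#' @param config A [trackingConfig()].
#' @return List of [BranchTrack-class].
#' @export
traceTree <- function(seeds, mask, original, forest,
                      config = trackingConfig()) {
  d <- dim(imgData(mask))
  sp <- min(spacing(mask))
  visited <- array(FALSE, dim = d)
  queue <- lapply(seq_along(seeds), function(i) {
    s <- seeds[[i]]
    list(point = s$point, dir = s$direction, radius = s$radius,
         order = 1L, parent = NA_integer_, parentPoint = NA_integer_,
         provenance = sprintf("seed:%d", i), fromBif = FALSE)
  })
  out <- list()
  nextId <- 1L
  while (length(queue) && length(out) < config$maxBranches) {
    job <- queue[[1]]; queue[[1]] <- NULL
    h0 <- config$stepHeightVox * sp
    ## the initial cylinder ends at the seed point: stepping starts there
    cyl <- cylinder(job$point - job$dir * h0, job$dir, job$radius, h0)
    pts <- matrix(job$point, 1, 3)
    radii <- job$radius
    prevAxis <- job$dir
    childJobs <- list()
    pathLen <- 0
    ## children re-entering the junction region must not re-bifurcate
    noBifLen <- if (job$fromBif)
      1.5 * config$shellFactor * job$radius + config$stepHeightVox * sp
    else 0
    for (st in seq_len(config$maxSteps)) {
      res <- stepCylinder(cyl, prevAxis, mask, original, forest, config,
                          visited,
                          ignoreVisited = job$fromBif && st <= 2)
      if (is.null(res)) break
      visited <- res$visited
      prevAxis <- cyl$axis
      cyl <- res$cyl
      pts <- rbind(pts, cyl$end)
      radii <- c(radii, cyl$radius)
      pathLen <- pathLen + cyl$height
      if (pathLen <= noBifLen) next
      bif <- detectBifurcation(cyl$end, cyl$radius, mask,
                               incomingDir = cyl$axis, config = config)
      if (nrow(bif$directions) >= 2) {
        bp <- refineBifurcation(cyl$end, cyl$axis, cyl$radius, mask, config)
        pts <- rbind(pts, bp)
        radii <- c(radii, cyl$radius)
        for (ci in seq_len(nrow(bif$directions))) {
          cdir <- bif$directions[ci, ]
          ## measure the child's own caliber a little way down its arm
          probe <- bp + cdir * max(3 * sp, cyl$radius)
          cr <- clamp(estimateLocalRadius(mask, probe, cdir, config$nRays),
                      config$minRadiusVox * sp, config$maxRadiusMM)
          childJobs[[length(childJobs) + 1]] <-
            list(point = bp, dir = cdir, radius = cr,
                 order = job$order + 1L, parent = nextId,
                 parentPoint = nrow(pts),
                 provenance = sprintf("bif:%d:%d", nextId, nrow(pts)),
                 fromBif = TRUE)
        }
        break
      }
    }
    if (nrow(pts) >= 2) {
      out[[length(out) + 1]] <-
        BranchTrack(pts, radii, parent = job$parent,
                    parentPoint = job$parentPoint, order = job$order,
                    id = nextId, provenance = job$provenance)
      ## only enqueue children of branches that materialized
      queue <- c(queue, childJobs)
      nextId <- nextId + 1L
    }
  }
  out
}
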