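# Shared fixture builders: everything is generated in code at test time.

# straight axis-aligned tube, no noise
straightTubePhantom <- function(radius = 0.3, spacing = 0.1,
                                gridShape = c(40, 40, 40), noiseSd = 0,
                                intensity = 100, seed = 1L) {
  extent <- (gridShape - 1) * spacing
  tube <- tubeSpec(rbind(c(0.5, extent[2] / 2, extent[3] / 2),
                         c(extent[1] - 0.5, extent[2] / 2, extent[3] / 2)),
                   radius, intensity)
  renderPhantom(phantomSpec(gridShape, spacing, list(tube),
                            noiseSd = noiseSd, seed = seed))
}

# Y-junction: a stem splitting into two children
yJunctionPhantom <- function(spacing = 0.1, gridShape = c(50, 50, 50),
                             noiseSd = 0, seed = 1L) {
  extent <- (gridShape - 1) * spacing
  mid <- extent / 2
  stemStart <- c(0.4, mid[2], mid[3])
  bif <- c(mid[1], mid[2], mid[3])
  stem <- tubeSpec(rbind(stemStart, bif), 0.3, 100)
  d1 <- unitVector(c(1, 0.85, 0))
  d2 <- unitVector(c(1, -0.85, 0))
  len <- 0.45 * extent[1]  # 2.2 mm arms: clearly above the 2 mm noise floor
  c1 <- tubeSpec(rbind(bif, bif + d1 * len), 0.22, 100)
  c2 <- tubeSpec(rbind(bif, bif + d2 * len), 0.22, 100)
  renderPhantom(phantomSpec(gridShape, spacing, list(stem, c1, c2),
                            topology = c(NA, 1L, 1L), noiseSd = noiseSd,
                            seed = seed))
}

# random voxel mask with a given count inside a small grid
randomMask <- function(n, gridShape = c(8, 8, 8), spacing = 0.1) {
  idx <- sample(prod(gridShape), n)
  m <- array(FALSE, dim = gridShape)
  m[idx] <- TRUE
  VesselMask(m, spacing)
}

# brute-force oracles, independent of the package implementations
bruteDice <- function(pred, gt) {
  p <- imgData(pred); g <- imgData(gt)
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(p)) {
    if (p[i] && g[i]) tp <- tp + 1
    else if (p[i]) fp <- fp + 1
    else if (g[i]) fn <- fn + 1
  }
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

bruteHausdorff <- function(pred, gt) {
  ptsOf <- function(m) {
    idx <- which(imgData(m))
    d <- dim(imgData(m))
    i <- (idx - 1) %% d[1]
    j <- ((idx - 1) %/% d[1]) %% d[2]
    k <- (idx - 1) %/% (d[1] * d[2])
    cbind(i, j, k) * rep(spacing(m), each = length(idx))
  }
  P <- ptsOf(pred); G <- ptsOf(gt)
  directed <- function(A, B) {
    mx <- 0
    for (a in seq_len(nrow(A))) {
      mn <- Inf
      for (b in seq_len(nrow(B))) {
        dd <- sqrt(sum((A[a, ] - B[b, ])^2))
        if (dd < mn) mn <- dd
      }
      if (mn > mx) mx <- mn
    }
    mx
  }
  max(directed(P, G), directed(G, P))
}

# tiny trained CNN shared across tests in a file (built on demand, cached)
.cnnCache <- new.env()
tinyTrainedCNN <- function() {
  if (!is.null(.cnnCache$net)) return(.cnnCache)
  ph <- renderPhantom(orientationPhantomSpec(seed = 11, nTubes = 18,
                                             gridShape = c(50, 50, 50),
                                             noiseSd = 10))
  ds <- makeTrainingPatches(list(ph), nPos = 250, nNeg = 250,
                            patchSize = 9, seed = 2)
  cfg <- spcnnConfig(featureMaps = 8, nBlocks = 2, denseUnits = 16,
                     initialLr = 1e-3, batchSize = 25, seed = 3)
  net <- trainSPCNN(buildSPCNN(cfg, patchSize = 9), ds, epochs = 10)
  .cnnCache$net <- net
  .cnnCache$data <- ds
  .cnnCache
}

# tiny trained step forest shared across tests (built on demand, cached)
.forestCache <- new.env()
tinyStepForest <- function() {
  if (!is.null(.forestCache$forest)) return(.forestCache$forest)
  phS <- straightTubePhantom(gridShape = c(50, 50, 50))
  phY <- yJunctionPhantom()
  ex <- rbind(makeStepExamples(phS, 200, 300, seed = 1),
              makeStepExamples(phY, 200, 300, seed = 2))
  # domain-matched examples: features on an actual segmentation of a noisy
  # phantom, labels from its ground truth
  cnn <- tinyTrainedCNN()$net
  phN <- yJunctionPhantom(noiseSd = 8, seed = 35)
  segMask <- segmentVolume(phN$volume, cnn, smallVesselsOnly = TRUE)
  ex <- rbind(ex, makeStepExamples(phN, 150, 200, mask = segMask, seed = 3))
  .forestCache$examples <- ex
  .forestCache$forest <- trainStepForest(ex, stepForestConfig(nTrees = 500,
                                                              seed = 4))
  .forestCache$forest
}

# a constant-probability "classifier" usable by segmentVolume
constantClassifier <- function(p, patchSize = 9L) {
  f <- function(X) rep(p, nrow(X))
  attr(f, "patchSize") <- patchSize
  f
}
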