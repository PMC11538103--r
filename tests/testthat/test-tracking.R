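test_that("step features behave analytically on constructed geometries", {
  # solid block: any interior cylinder has f1 = 1 and full f4 neighborhood
  solid <- VesselMask(array(TRUE, c(30, 30, 30)), 0.1)
  v <- MRAVolume(array(100, c(30, 30, 30)), 0.1)
  cyl <- cylinder(c(1.4, 1.4, 1.4), c(1, 0, 0), 0.25, 0.3)
  f <- computeStepFeatures(cyl, c(1, 0, 0), solid, v)
  expect_equal(unname(f["f1"]), 1)
  expect_equal(unname(f["f4"]), 125)
  expect_equal(unname(f["f3"]), 0)
  # antiparallel previous axis gives f3 = pi
  f2 <- computeStepFeatures(cyl, c(-1, 0, 0), solid, v)
  expect_equal(unname(f2["f3"]), pi, tolerance = 1e-9)
  # f5 sorted ascending
  expect_true(all(diff(f[c("f5a", "f5b", "f5c")]) >= 0))
  expect_error(computeStepFeatures(cylinder(c(90, 90, 90), c(1, 0, 0),
                                            0.2, 0.3),
                                   c(1, 0, 0), solid, v), "outside")
})

test_that("edge-distance variance is near zero for a centered tube", {
  ph <- straightTubePhantom(radius = 0.3, gridShape = c(40, 40, 40))
  cl <- ph$truth$centerlines[[1]]
  mid <- cl[nrow(cl) %/% 2, ]
  cyl <- cylinder(mid - c(0.15, 0, 0), c(1, 0, 0), 0.3, 0.3)
  f <- computeStepFeatures(cyl, c(1, 0, 0), ph$truth$mask, ph$volume)
  expect_lt(unname(f["f2"]), 0.01)  # mm^2, within discretization
  # Hessian signature of a bright tube: two clearly negative eigenvalues,
  # one near zero
  ev <- f[c("f5a", "f5b", "f5c")]
  expect_lt(ev[2], 0)
  expect_lt(abs(ev[3]), abs(ev[2]) * 0.5)
})

test_that("f1 and f4 match brute-force voxel enumeration", {
  set.seed(3)
  for (trial in 1:10) {
    m <- randomMask(150, c(10, 10, 10))
    v <- MRAVolume(array(100, c(10, 10, 10)), 0.1)
    base <- runif(3, 0.25, 0.65)
    axis <- lsatrace:::unitVector(rnorm(3))
    cyl <- cylinder(base, axis, runif(1, 0.1, 0.3), 0.3)
    f <- computeStepFeatures(cyl, axis, m, v)
    # brute force over every voxel center
    cnt <- 0; tot <- 0
    for (i in 1:10) for (j in 1:10) for (k in 1:10) {
      x <- (c(i, j, k) - 1) * 0.1
      t <- sum((x - base) * axis)
      if (t >= 0 && t <= cyl$height &&
          sum((x - base)^2) - t^2 <= cyl$radius^2 + 1e-15) {
        tot <- tot + 1
        if (imgData(m)[i, j, k]) cnt <- cnt + 1
      }
    }
    if (tot > 0) expect_equal(unname(f["f1"]), cnt / tot)
    # f4: 5x5x5 neighborhood of the end voxel
    e <- round(cyl$end / 0.1) + 1
    ii <- max(1, e[1] - 2):min(10, e[1] + 2)
    jj <- max(1, e[2] - 2):min(10, e[2] + 2)
    kk <- max(1, e[3] - 2):min(10, e[3] + 2)
    expect_equal(unname(f["f4"]), sum(imgData(m)[ii, jj, kk]))
  }
})

test_that("seeds are found at junctions with the large vessel", {
  # one tube branching off a bright large vessel
  extent <- 3.9
  lv <- tubeSpec(rbind(c(0.8, 0.2, 1.95), c(0.8, 3.7, 1.95)), 0.5, 200)
  tube <- tubeSpec(rbind(c(1.3, 1.95, 1.95), c(3.6, 1.95, 1.95)), 0.25, 100)
  ph <- renderPhantom(phantomSpec(c(40, 40, 40), 0.1, list(tube),
                                  largeVessel = lv))
  seeds <- detectSeeds(ph$truth$mask, ph$truth$largeMask)
  expect_length(seeds, 1)
  ang <- acos(sum(seeds[[1]]$direction * c(1, 0, 0)))
  expect_lt(ang, 30 * pi / 180)
})

test_that("phantom-mode seeding uses skeleton endpoints per component", {
  empty <- VesselMask(array(FALSE, c(20, 20, 20)), 0.1)
  expect_length(detectSeeds(empty), 0)
  # two disjoint tubes give two seeds
  t1 <- tubeSpec(rbind(c(0.5, 1, 1), c(3.4, 1, 1)), 0.2)
  t2 <- tubeSpec(rbind(c(0.5, 3, 3), c(3.4, 3, 3)), 0.2)
  ph <- renderPhantom(phantomSpec(c(40, 40, 40), 0.1, list(t1, t2)))
  expect_length(detectSeeds(ph$truth$mask), 2)
})

test_that("the step forest separates valid from invalid steps", {
  forest <- tinyStepForest()
  expect_gte(forest$accuracy, 0.9)
  expect_equal(forest$model$num.trees, 500)
  # honoring the configured tree count at full scale
  exSmall <- .forestCache$examples[seq(1, nrow(.forestCache$examples),
                                       by = 4), ]
  big <- trainStepForest(exSmall, stepForestConfig(nTrees = 2000, seed = 9))
  expect_equal(big$model$num.trees, 2000)
  # seeded determinism of predictions
  f2 <- trainStepForest(.forestCache$examples,
                        stepForestConfig(nTrees = 500, seed = 4))
  X <- .forestCache$examples[1:20, 1:7]
  expect_identical(predictStepForest(forest, X), predictStepForest(f2, X))
  expect_error(trainStepForest(transform(exSmall, label = 1L)),
               "both classes")
})

test_that("tracing a straight tube recovers its centerline and length", {
  forest <- tinyStepForest()
  ph <- straightTubePhantom(gridShape = c(50, 50, 50))
  seeds <- detectSeeds(ph$truth$mask)
  br <- traceTree(seeds, ph$truth$mask, ph$volume, forest)
  expect_length(br, 1)
  expect_equal(br[[1]]@order, 1L)
  cl <- ph$truth$centerlines[[1]]
  traced <- lsatrace:::polylineLength(br[[1]]@points)
  expect_lt(abs(traced - lsatrace:::polylineLength(cl)) /
            lsatrace:::polylineLength(cl), 0.10)
  # mean distance of traced points to the ground-truth centerline < 1 voxel
  expect_lt(mean(lsatrace:::pairwiseMinDist(br[[1]]@points, cl)), 0.1)
  # turning cap: consecutive step directions never exceed the configured max
  p <- br[[1]]@points
  dirs <- diff(p) / sqrt(rowSums(diff(p)^2))
  angles <- acos(pmin(pmax(rowSums(dirs[-1, , drop = FALSE] *
                                   dirs[-nrow(dirs), , drop = FALSE]),
                           -1), 1))
  expect_lte(max(angles), 60 * pi / 180 + 1e-9)
})

test_that("stepping in an empty mask stops immediately", {
  forest <- tinyStepForest()
  empty <- VesselMask(array(FALSE, c(20, 20, 20)), 0.1)
  v <- MRAVolume(array(60, c(20, 20, 20)), 0.1)
  cyl <- cylinder(c(1, 1, 1), c(1, 0, 0), 0.2, 0.3)
  expect_null(stepCylinder(cyl, c(1, 0, 0), empty, v, forest))
})

test_that("the spherical shell classifies tube topology", {
  ph <- straightTubePhantom(radius = 0.3, gridShape = c(50, 50, 50))
  mask <- ph$truth$mask
  mid <- c(2.4, 2.45, 2.45)
  alongTube <- detectBifurcation(mid, 0.3, mask)
  expect_equal(alongTube$nComponents, 2L)  # two continuations mid-tube
  withIncoming <- detectBifurcation(mid, 0.3, mask, incomingDir = c(1, 0, 0))
  expect_equal(nrow(withIncoming$directions), 1L)  # only the continuation
  # tube endpoint: a single (incoming) component, no children
  tip <- detectBifurcation(c(4.35, 2.45, 2.45), 0.3, mask,
                           incomingDir = c(1, 0, 0))
  expect_lte(nrow(tip$directions), 0L + (tip$nComponents > 1))
  # Y-junction center: three components, two outgoing
  phY <- yJunctionPhantom()
  ctr <- phY$truth$bifurcations[1, ]
  y <- detectBifurcation(ctr, 0.3, phY$truth$mask, incomingDir = c(1, 0, 0))
  expect_equal(y$nComponents, 3L)
  expect_equal(nrow(y$directions), 2L)
})

test_that("tracing a Y phantom yields one primary and two secondary branches", {
  forest <- tinyStepForest()
  phY <- yJunctionPhantom()
  seeds <- detectSeeds(phY$truth$mask)
  br <- traceTree(seeds, phY$truth$mask, phY$volume, forest)
  expect_length(br, 3)
  orders <- sort(vapply(br, function(b) b@order, integer(1)))
  expect_equal(orders, c(1L, 2L, 2L))
  # the bifurcation is localized within 2 voxels of the ground truth
  gtbif <- phY$truth$bifurcations[1, ]
  childStarts <- t(vapply(br[-1], function(b) b@points[1, ], numeric(3)))
  offs <- sqrt(rowSums(sweep(childStarts, 2, gtbif, `-`)^2))
  expect_lt(max(offs), 0.2)
  # parent links resolve to the primary branch
  expect_true(all(vapply(br[-1], function(b) b@parent, integer(1)) ==
                  br[[1]]@id))
})
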