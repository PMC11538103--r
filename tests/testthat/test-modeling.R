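test_that("Bezier centerlines interpolate their knots with C1 joints", {
  set.seed(1)
  pts <- cbind(cumsum(runif(8, 0.3, 1)), rnorm(8, 2, 0.3), rnorm(8, 2, 0.3))
  cl <- fitCenterline(pts)
  # endpoint property per segment
  seg <- cl@segments[[1]]
  expect_equal(as.vector(lsatrace:::bezierPoint(seg, 0)), unname(seg[1, ]))
  expect_equal(as.vector(lsatrace:::bezierPoint(seg, 1)), unname(seg[4, ]))
  # the curve passes through every input point
  dense <- sampleCenterline(cl, 64L)
  dd <- lsatrace:::pairwiseMinDist(pts, dense$points)
  expect_lt(max(dd), 1e-3)
  # knots exactly
  for (i in seq_along(cl@segments)) {
    expect_equal(unname(cl@segments[[i]][1, ]), unname(pts[i, ]),
                 tolerance = 1e-12)
  }
  # C1: tangent directions agree across joints
  for (i in seq_len(length(cl@segments) - 1)) {
    t1 <- lsatrace:::bezierD1(cl@segments[[i]], 1)
    t2 <- lsatrace:::bezierD1(cl@segments[[i + 1]], 0)
    expect_lt(max(abs(t1 - t2)), 1e-9)
  }
  # duplicate points collapse; fewer than 2 distinct points error
  expect_error(fitCenterline(rbind(c(1, 1, 1), c(1, 1, 1))), "distinct")
})

test_that("arc length is exact on straight lines and convergent on circles", {
  straight <- fitCenterline(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(arcLength(straight), 10, tolerance = 1e-6)
  # collinear multi-point input: length equals the chord
  col <- fitCenterline(cbind(seq(0, 5, by = 0.5), 0, 0))
  expect_lt(abs(arcLength(col) - 5) / 5, 1e-3)
  # 90-degree arc, radius 5: fitted curve stays within 0.05 mm of the arc
  th <- seq(0, pi / 2, length.out = 10)
  arc <- cbind(5 * cos(th), 5 * sin(th), 0)
  clArc <- fitCenterline(arc)
  dense <- sampleCenterline(clArc, 64L)$points
  radialErr <- abs(sqrt(dense[, 1]^2 + dense[, 2]^2) - 5)
  expect_lt(max(radialErr), 0.05)
  expect_lt(abs(arcLength(clArc) - 5 * pi / 2) / (5 * pi / 2), 0.005)
  # full circle from 4 segments (13 knots), radius r
  r <- 3
  th2 <- seq(0, 2 * pi, length.out = 13)
  circ <- fitCenterline(cbind(r * cos(th2), r * sin(th2), 0))
  expect_lt(abs(arcLength(circ) - 2 * pi * r) / (2 * pi * r), 0.005)
  # refinement invariance
  l1 <- lsatrace:::polylineLength(sampleCenterline(clArc, 64L)$points)
  l2 <- lsatrace:::polylineLength(sampleCenterline(clArc, 128L)$points)
  expect_lt(abs(l2 - l1) / l2, 0.001)
})

test_that("curvature is zero on straight branches and 1/r on circles", {
  straight <- fitCenterline(cbind(seq(0, 8, by = 1), 0, 0))
  expect_lt(mean(sampleCenterline(straight, 32L)$curvature), 1e-3)
  th <- seq(0, pi, length.out = 20)
  semi <- fitCenterline(cbind(4 * cos(th), 4 * sin(th), 0))
  k <- sampleCenterline(semi, 32L)$curvature
  expect_lt(abs(mean(k) - 1 / 4) / (1 / 4), 0.05)
})

test_that("diameters are recovered within one voxel across phantom radii", {
  for (r in c(0.2, 0.3, 0.45, 0.6)) {
    ph <- straightTubePhantom(radius = r, spacing = 0.1,
                              gridShape = c(40, 40, 40))
    cl <- fitCenterline(ph$truth$centerlines[[1]][c(TRUE, rep(FALSE, 9)), ])
    dm <- estimateDiameters(cl, ph$truth$mask)
    inner <- dm[seq(3, length(dm) - 2)]  # end caps excluded
    expect_lt(max(abs(inner - 2 * r)), 0.1 + 1e-9)
  }
})

test_that("a single-voxel-wide line yields a voxel-scale diameter", {
  m <- array(FALSE, c(30, 12, 12)); m[3:28, 6, 6] <- TRUE
  mask <- VesselMask(m, 0.1)
  cl <- fitCenterline(rbind(c(0.3, 0.5, 0.5), c(2.6, 0.5, 0.5)))
  dm <- estimateDiameters(cl, mask)
  expect_true(all(dm > 0.03 & dm < 0.22))
})

test_that("a tapering tube yields a monotone decreasing profile", {
  extent <- 3.9
  tube <- tubeSpec(rbind(c(0.4, 2, 2), c(3.5, 2, 2)), c(0.6, 0.3))
  ph <- renderPhantom(phantomSpec(c(40, 40, 40), 0.1, list(tube)))
  cl <- fitCenterline(rbind(c(0.6, 2, 2), c(2, 2, 2), c(3.3, 2, 2)))
  dm <- estimateDiameters(cl, ph$truth$mask, ds = 0.3)
  # allow voxelization wiggle: fit a line, slope must be clearly negative
  slope <- coef(lm(dm ~ seq_along(dm)))[2]
  expect_lt(slope, -0.01)
  expect_lt(max(abs(sort(dm, decreasing = TRUE) - dm)), 0.11)
})

test_that("morphometry reports lengths, diameters, curvature and counts", {
  ph <- straightTubePhantom(radius = 0.3, spacing = 0.1,
                            gridShape = c(60, 30, 30))
  gtc <- ph$truth$centerlines[[1]]
  idx <- unique(c(seq(1, nrow(gtc), by = 8), nrow(gtc)))
  br <- BranchTrack(gtc[idx, ], rep(0.3, length(idx)), id = 1L)
  model <- buildVesselModel(list(br), ph$truth$mask)
  tab <- morphometry(model)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$order, 1)
  gtLen <- lsatrace:::polylineLength(gtc)
  expect_lt(abs(tab$lengthMM - gtLen) / gtLen, 0.02)
  expect_lt(abs(tab$meanDiamMM - 0.6), 0.1)
  expect_lt(tab$meanCurvature, 1e-3)
  expect_equal(attr(tab, "orderCounts"), c(1L, 0L, 0L))
})

test_that("model comparison is exact on self and translated copies", {
  ph <- yJunctionPhantom()
  brs <- lapply(seq_along(ph$truth$centerlines), function(i) {
    cl <- ph$truth$centerlines[[i]]
    idx <- unique(c(seq(1, nrow(cl), by = 6), nrow(cl)))
    BranchTrack(cl[idx, ], ph$truth$radii[[i]][idx], id = as.integer(i),
                order = ph$truth$branchOrders[i])
  })
  model <- buildVesselModel(brs, ph$truth$mask)
  self <- compareModels(model, model)
  expect_equal(max(self$keypointOffsets), 0, tolerance = 1e-9)
  expect_equal(self$lengthDiffs, rep(0, 3))
  expect_equal(self$diameterDiffs, rep(0, 3))
  # rigid 0.05 mm translation: every key-point offset equals 0.05
  shifted <- lapply(brs, function(b) {
    BranchTrack(sweep(b@points, 2, c(0.05, 0, 0), `+`), b@radii,
                id = b@id, order = b@order)
  })
  # same mask: diameters are measured on the same grid
  model2 <- buildVesselModel(shifted, ph$truth$mask)
  cmp <- compareModels(model, model2)
  expect_equal(median(cmp$keypointOffsets), 0.05, tolerance = 1e-6)
  expect_equal(max(abs(cmp$keypointOffsets - 0.05)), 0, tolerance = 1e-6)
})

test_that("Bland-Altman limits equal the hand-computed mean +/- 1.96 SD", {
  x <- c(10.2, 11.5, 9.8, 12.0, 10.9)
  y <- c(10.0, 11.9, 9.5, 11.4, 11.2)
  ba <- blandAltman(x, y)
  d <- x - y
  expect_equal(ba$meanDiff, mean(d))
  expect_equal(ba$lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$upper, mean(d) + 1.96 * sd(d))
})

test_that("tube meshes put vertices at half the diameter from the axis", {
  br <- BranchTrack(cbind(seq(0.5, 3.5, by = 0.5), 1.95, 1.95),
                    rep(0.3, 7), id = 1L)
  ph <- straightTubePhantom(radius = 0.3, spacing = 0.1,
                            gridShape = c(40, 40, 40))
  model <- buildVesselModel(list(br), ph$truth$mask)
  mesh <- exportTubeMesh(model, nSides = 12, ds = 0.25)[[1]]
  # exclude cap centers (last two vertices)
  ring <- mesh$vertices[seq_len(nrow(mesh$vertices) - 2), ]
  radial <- sqrt((ring[, 2] - 1.95)^2 + (ring[, 3] - 1.95)^2)
  expect_equal(radial, mesh$scalars[seq_along(radial)] / 2, tolerance = 1e-6)
  # vertex count scales linearly: rings x sides + 2 caps
  nRings <- nrow(mesh$vertices[, 1, drop = FALSE]) # total
  mesh2 <- exportTubeMesh(model, nSides = 24, ds = 0.25)[[1]]
  expect_equal((nrow(mesh2$vertices) - 2) / (nrow(mesh$vertices) - 2), 2)
})
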