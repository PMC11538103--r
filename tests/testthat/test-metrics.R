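test_that("Dice handles the worked three-voxel case and the degenerate ones", {
  m <- function(cells) {
    a <- array(FALSE, c(4, 4, 4)); a[cells] <- TRUE
    VesselMask(a, 0.1)
  }
  # pred {a,b,c} vs gt {a,b,d}: TP=2, FP=1, FN=1 -> 4/6
  expect_equal(diceCoefficient(m(c(1, 2, 3)), m(c(1, 2, 4))), 4 / 6)
  expect_equal(diceCoefficient(m(1:5), m(1:5)), 1)
  expect_equal(diceCoefficient(m(1:3), m(10:12)), 0)
  expect_equal(diceCoefficient(m(integer(0)), m(integer(0))), 1)
  expect_error(diceCoefficient(m(1), VesselMask(array(FALSE, c(3, 3, 3)), 0.1)),
               "different grids")
})

test_that("Hausdorff distance is the max of the two directed distances", {
  a <- array(FALSE, c(40, 5, 5)); a[5, 2, 2] <- TRUE
  b <- array(FALSE, c(40, 5, 5)); b[5, 2, 2] <- TRUE; b[35, 2, 2] <- TRUE
  P <- VesselMask(a, 0.1); G <- VesselMask(b, 0.1)
  # G contains a point 3 mm away from everything in P
  expect_equal(hausdorffDistance(P, G), 3.0, tolerance = 1e-12)
  expect_equal(hausdorffDistance(G, P), 3.0, tolerance = 1e-12)  # symmetric
  expect_equal(hausdorffDistance(P, P), 0)
  empty <- VesselMask(array(FALSE, c(40, 5, 5)), 0.1)
  expect_error(hausdorffDistance(P, empty), "empty")
})

test_that("dice and hausdorff match brute-force oracles on random masks", {
  set.seed(42)
  for (trial in 1:100) {
    n1 <- sample(1:60, 1); n2 <- sample(1:60, 1)
    p <- randomMask(n1); g <- randomMask(n2)
    expect_identical(diceCoefficient(p, g), bruteDice(p, g))
    expect_equal(hausdorffDistance(p, g), bruteHausdorff(p, g),
                 tolerance = 1e-12)
  }
})

test_that("metrics are symmetric and translation invariant", {
  set.seed(7)
  for (trial in 1:20) {
    p <- randomMask(sample(5:40, 1), c(10, 10, 10))
    g <- randomMask(sample(5:40, 1), c(10, 10, 10))
    expect_identical(diceCoefficient(p, g), diceCoefficient(g, p))
    expect_equal(hausdorffDistance(p, g), hausdorffDistance(g, p))
    # shift both masks by the same voxel offset inside a larger grid
    shift <- function(m) {
      a <- array(FALSE, c(14, 14, 14))
      a[3:12, 3:12, 3:12] <- imgData(m)
      VesselMask(a, spacing(m))
    }
    expect_identical(diceCoefficient(shift(p), shift(g)),
                     diceCoefficient(p, g))
    expect_equal(hausdorffDistance(shift(p), shift(g)),
                 hausdorffDistance(p, g), tolerance = 1e-12)
  }
})

test_that("FP and FN rates follow the printed denominators", {
  grid <- c(10, 10, 10)
  g <- array(FALSE, grid); g[1:10] <- TRUE        # 10 vessel voxels
  gt <- VesselMask(g, 0.1)
  p <- g; p[11:12] <- TRUE                        # 2 spurious
  r <- fpFnRates(VesselMask(p, 0.1), gt)
  expect_equal(r$fpRate, 2 / 10)                  # FP over vessel voxels
  expect_equal(r$fnRate, 0)
  # missing 5 of the vessel voxels: FN over background voxels
  p2 <- g; p2[1:5] <- FALSE
  r2 <- fpFnRates(VesselMask(p2, 0.1), gt)
  expect_equal(r2$fnRate, 5 / (prod(grid) - 10))
  expect_equal(r2$fpRate, 0)
  # perfect prediction
  r3 <- fpFnRates(gt, gt)
  expect_equal(c(r3$fpRate, r3$fnRate), c(0, 0))
  # conventional variants use the opposite denominators
  c2 <- conventionalRates(VesselMask(p2, 0.1), gt)
  expect_equal(c2$fnOverVessel, 5 / 10)
  expect_error(fpFnRates(gt, VesselMask(array(TRUE, grid), 0.1)),
               "background")
})

test_that("the pre-screen partitions the grid into three exhaustive sets", {
  set.seed(9)
  x <- array(runif(15^3, 0, 255), c(15, 15, 15))
  v <- MRAVolume(x, 0.1, intensityScale = "standardized")
  pre <- prescreenCandidates(v, intensityInterval(80, 120))
  lv <- which(imgData(pre$largeVesselMask))
  bg <- which(imgData(pre$backgroundMask))
  cand <- pre$candidates
  expect_length(intersect(lv, bg), 0)
  expect_length(intersect(lv, cand), 0)
  expect_length(intersect(bg, cand), 0)
  expect_setequal(c(lv, bg, cand), seq_along(x))
  # boundary semantics: exactly at a threshold is not a candidate
  v2 <- MRAVolume(array(c(80, 120, 100, rep(50, 24)), c(3, 3, 3)), 0.1,
                  intensityScale = "standardized")
  pre2 <- prescreenCandidates(v2)
  expect_identical(pre2$candidates, 3L)
  expect_error(prescreenCandidates(MRAVolume(x, 0.1)), "standardized")
})

test_that("segMetrics aggregates counts and distances coherently", {
  ph <- straightTubePhantom(gridShape = c(20, 20, 20))
  gt <- ph$truth$mask
  sm <- segMetrics(gt, gt)
  expect_equal(sm@dsc, 1)
  expect_equal(sm@hd, 0)
  expect_equal(sm@fp + sm@fn, 0)
  expect_equal(sm@tp + sm@tn, prod(dim(imgData(gt))))
})
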