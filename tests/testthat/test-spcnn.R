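test_that("patch extraction returns exact cubes with edge replication", {
  set.seed(1)
  v <- MRAVolume(array(runif(20^3, 0, 200), c(20, 20, 20)), 0.1)
  p <- extractPatch(v, c(10, 10, 10), size = 9, normMin = 0, normMax = 200)
  expect_equal(dim(p$values), c(9, 9, 9))
  expect_true(all(p$values >= 0 & p$values <= 1))
  expect_equal(p$values[5, 5, 5], imgData(v)[10, 10, 10] / 200)
  # grid-corner center works via edge replication
  corner <- extractPatch(v, c(1, 1, 1), size = 9)
  expect_equal(dim(corner$values), c(9, 9, 9))
  expect_equal(corner$values[1, 1, 1], corner$values[2, 2, 2])  # replicated
  # constant volume at normMin gives an all-zero patch
  cv <- MRAVolume(array(5, c(11, 11, 11)), 0.1)
  expect_true(all(extractPatch(cv, c(6, 6, 6), 9, normMin = 5,
                               normMax = 10)$values == 0))
  expect_error(extractPatch(v, c(25, 10, 10), 9), "outside")
})

test_that("untrained network outputs lie strictly in (0, 1) and are deterministic", {
  cfg <- spcnnConfig(featureMaps = 4, nBlocks = 2, denseUnits = 8, seed = 5)
  net <- buildSPCNN(cfg, patchSize = 9)
  set.seed(2)
  X <- matrix(runif(6 * 9^3), 6)
  p1 <- predictSPCNN(net, X)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, predictSPCNN(net, X))   # inference is deterministic
  # identical patches give identical outputs
  X2 <- rbind(X[1, ], X[1, ])
  p2 <- predictSPCNN(net, X2)
  expect_identical(p2[1], p2[2])
})

test_that("parameter count matches an independent hand count (2-block toy)", {
  C <- 8; du <- 16
  cfg <- spcnnConfig(featureMaps = C, nBlocks = 2, denseUnits = du)
  net <- buildSPCNN(cfg, patchSize = 9)
  # 9 -conv-> 5 -pool-> 2 -conv-> 1; flatten 1^3 * C
  conv1 <- 27 * 1 * C + C
  bn1 <- 2 * C
  conv2 <- 27 * C * C + C
  bn2 <- 2 * C
  dense1 <- 1^3 * C * du + du
  dense2 <- du * 1 + 1
  expect_equal(spcnnParameterCount(net),
               conv1 + bn1 + conv2 + bn2 + dense1 + dense2)
})

test_that("a too-small patch is rejected with the minimum size", {
  cfg <- spcnnConfig(featureMaps = 4, nBlocks = 3)
  expect_error(buildSPCNN(cfg, patchSize = 1), "minimum is")
})

test_that("plateau schedule steps the learning rate down, bounded below", {
  # 1 improving epoch, then stagnation: drop after each `patience` run
  losses <- c(1, rep(1.2, 25))
  lr <- plateauSchedule(losses, initialLr = 1e-4, factor = 0.1,
                        patience = 10, minLr = 1e-8)
  expect_equal(lr[1:11], rep(1e-4, 11))
  expect_equal(lr[12:21], rep(1e-5, 10))
  expect_equal(lr[22:26], rep(1e-6, 5))
  # never below minLr
  lr2 <- plateauSchedule(rep(1, 100), initialLr = 1e-4, factor = 0.1,
                         patience = 2, minLr = 1e-8)
  expect_gte(min(lr2), 1e-8)
  expect_equal(tail(lr2, 1), 1e-8)
})

test_that("training errors on single-class data and respects the epoch caps", {
  cache <- tinyTrainedCNN()
  ds <- cache$data
  net <- buildSPCNN(spcnnConfig(featureMaps = 4, nBlocks = 2,
                                denseUnits = 8), patchSize = 9)
  posOnly <- ds
  posOnly@labels <- rep(1L, length(ds@labels))
  expect_error(trainSPCNN(net, posOnly, epochs = 1), "both classes")
  expect_lte(nrow(cache$net@history), 40)  # early stop bound
})

test_that("the scaled-down network separates tube patches from noise", {
  cache <- tinyTrainedCNN()
  net <- cache$net; ds <- cache$data
  te <- ds@split == "test"
  p <- predictSPCNN(net, ds@patches[te, , drop = FALSE])
  acc <- mean((p >= 0.5) == (ds@labels[te] == 1))
  expect_gt(acc, 0.8)
  expect_true(net@trained)
  # training is reproducible under the config seed
  expect_true(all(c("trainLoss", "testLoss", "trainAcc", "testAcc", "lr")
                  %in% names(net@history)))
})

test_that("segmentVolume composes the classifier with the pre-screen", {
  ph <- straightTubePhantom(noiseSd = 10, gridShape = c(24, 24, 24), seed = 4)
  v <- ph$volume
  pre <- prescreenCandidates(v)
  # classifier that accepts everything: mask = candidates + large vessels
  allMask <- segmentVolume(v, constantClassifier(1), threshold = 0.5)
  expect_setequal(which(imgData(allMask)),
                  union(pre$candidates, which(imgData(pre$largeVesselMask))))
  # classifier that rejects everything: only the large-vessel mask remains
  noneMask <- segmentVolume(v, constantClassifier(0), threshold = 0.5)
  expect_identical(which(imgData(noneMask)),
                   which(imgData(pre$largeVesselMask)))
  # small-vessels-only excludes the large-vessel mask
  small <- segmentVolume(v, constantClassifier(1), smallVesselsOnly = TRUE)
  expect_setequal(which(imgData(small)), pre$candidates)
})
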