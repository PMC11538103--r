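test_that("bias correction is the identity on a bias-free constant volume", {
  v <- MRAVolume(array(100, c(20, 20, 20)), 0.2)
  out <- correctBias(v)
  expect_lt(max(abs(imgData(out) - imgData(v))) / 100, 0.01)
})

test_that("bias correction halves the background coefficient of variation", {
  spec <- phantomSpec(c(48, 48, 48), 0.1,
                      list(tubeSpec(rbind(c(0.5, 2.35, 2.35),
                                          c(4.2, 2.35, 2.35)), 0.3)),
                      noiseSd = 2,
                      biasCoeffs = c(x = 0.3, yy = -0.25, xz = 0.2),
                      seed = 7)
  ph <- renderPhantom(spec)
  bg <- !imgData(ph$truth$mask)
  cov0 <- sd(imgData(ph$volume)[bg]) / mean(imgData(ph$volume)[bg])
  corr <- correctBias(ph$volume)
  cov1 <- sd(imgData(corr)[bg]) / mean(imgData(corr)[bg])
  expect_lt(cov1, 0.5 * cov0)
  # mean preserved within 1%
  expect_lt(abs(mean(imgData(corr)) - mean(imgData(ph$volume))) /
            mean(imgData(ph$volume)), 0.01)
})

test_that("non-positive volumes are shifted, corrected, and shifted back", {
  set.seed(1)
  base <- array(rnorm(20^3, 0, 5), c(20, 20, 20))  # includes negatives
  v <- MRAVolume(base, 0.1)
  out <- correctBias(v)
  expect_lt(abs(mean(imgData(out)) - mean(base)), abs(mean(base)) * 0.01 + 0.1)
  expect_true(min(imgData(out)) < 0)  # the shift was reversed
})

test_that("mean filtering leaves constants alone and kernel 1 is identity", {
  v <- MRAVolume(array(42, c(12, 12, 12)), 0.1)
  expect_equal(imgData(denoiseVolume(v, preprocessConfig(denoiseKernel = 3))),
               imgData(v))
  set.seed(2)
  w <- MRAVolume(array(rnorm(12^3), c(12, 12, 12)), 0.1)
  expect_identical(imgData(denoiseVolume(w, preprocessConfig(denoiseKernel = 1))),
                   imgData(w))
})

test_that("a 3^3 mean filter attenuates white noise by about sqrt(27)", {
  set.seed(3)
  x <- array(rnorm(40^3, 0, 8), c(40, 40, 40))
  v <- MRAVolume(x, 0.1)
  f <- denoiseVolume(v, preprocessConfig(denoiseKernel = 3))
  inner <- imgData(f)[5:36, 5:36, 5:36]  # avoid the replicated edges
  expect_lt(abs(sd(inner) - 8 / sqrt(27)) / (8 / sqrt(27)), 0.15)
})

test_that("isotropic resampling preserves extent, identity, and constants", {
  set.seed(4)
  v <- MRAVolume(array(rnorm(30 * 30 * 20, 100, 10), c(30, 30, 20)),
                 c(0.2, 0.2, 0.2))
  # identity when the target equals the (isotropic) source spacing
  expect_identical(imgData(resampleIsotropic(v, 0.2)), imgData(v))
  # doubling resolution roughly doubles each axis dimension
  up <- resampleIsotropic(v, 0.1)
  expect_true(all(abs(dim(imgData(up)) - 2 * dim(imgData(v))) <= 1))
  expect_equal(spacing(up), rep(0.1, 3))
  # physical extent within one target voxel
  extIn <- (dim(imgData(v)) - 1) * spacing(v)
  extOut <- (dim(imgData(up)) - 1) * spacing(up)
  expect_true(all(abs(extIn - extOut) <= 0.1 + 1e-9))
  # constant volume stays constant
  cv <- MRAVolume(array(7, c(10, 10, 10)), c(0.3, 0.3, 0.3))
  expect_true(all(abs(imgData(resampleIsotropic(cv, 0.2)) - 7) < 1e-12))
  expect_error(resampleIsotropic(v, 0.005), "memory guard")
})

test_that("anisotropic acquisition grids resample to the working resolution", {
  v <- MRAVolume(array(runif(20 * 20 * 12), c(20, 20, 12)),
                 c(0.23, 0.23, 0.36))
  out <- resampleIsotropic(v, 0.10)
  expect_equal(spacing(out), rep(0.10, 3))
  extIn <- (dim(imgData(v)) - 1) * spacing(v)
  extOut <- (dim(imgData(out)) - 1) * spacing(out)
  expect_true(all(abs(extIn - extOut) <= 0.10 + 1e-9))
})

test_that("standardization maps the robust window onto [0, 255]", {
  x <- array(seq(0, 1000, length.out = 21^3), c(21, 21, 21))
  v <- MRAVolume(x, 0.1)
  s <- standardizeIntensity(v)
  # symmetric distribution: the midpoint maps to 127.5
  expect_equal(imgData(s)[which(x == 500)], 127.5, tolerance = 1e-6)
  expect_equal(min(imgData(s)), 0)
  expect_equal(max(imgData(s)), 255)
  expect_identical(intensityScale(s), "standardized")
  # idempotent on an already standardized volume
  expect_identical(imgData(standardizeIntensity(s)), imgData(s))
  # constant volume maps to the midpoint, flagged
  cv <- standardizeIntensity(MRAVolume(array(5, c(8, 8, 8)), 0.1))
  expect_true(all(imgData(cv) == 127.5))
  expect_identical(attr(cv, "flag"), "constant-volume")
})

test_that("the full preprocessing chain emits a standardized working volume", {
  spec <- phantomSpec(c(30, 30, 30), 0.2,
                      list(tubeSpec(rbind(c(0.5, 2.9, 2.9), c(5.3, 2.9, 2.9)),
                                    0.4)),
                      noiseSd = 3, biasCoeffs = c(x = 0.2), seed = 5)
  ph <- renderPhantom(spec)
  out <- preprocessVolume(ph$volume, preprocessConfig(targetSpacing = 0.1))
  expect_identical(intensityScale(out), "standardized")
  expect_equal(spacing(out), rep(0.1, 3))
  expect_true(all(imgData(out) >= 0 & imgData(out) <= 255))
})
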