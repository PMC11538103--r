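# builders for constructed branch fixtures (straight lines in mm)
lineBranch <- function(from, to, n = 12, r = 0.25, id = 1L,
                       parent = NA_integer_, order = 1L) {
  tt <- seq(0, 1, length.out = n)
  pts <- outer(rep(1, n), from) + outer(tt, to - from)
  BranchTrack(pts, rep(r, n), id = as.integer(id),
              parent = as.integer(parent), order = as.integer(order))
}

fullMask <- function(gridShape = c(50, 50, 50), spacing = 0.1) {
  VesselMask(array(TRUE, gridShape), spacing)
}

test_that("duplicate branches collapse to the longer one", {
  a <- lineBranch(c(0.5, 2, 2), c(4, 2, 2), id = 1)
  b <- lineBranch(c(0.5, 2, 2), c(4, 2, 2), id = 2)
  out <- removeDuplicates(list(a, b), screeningConfig(), voxelMM = 0.1)
  expect_length(out, 1)
  expect_equal(out[[1]]@id, 1L)  # deterministic tie-break: earlier id
  # branches sharing only one point are both retained
  c1 <- lineBranch(c(2, 2, 2), c(4, 3.5, 2), id = 3)
  out2 <- removeDuplicates(list(a, c1), screeningConfig(), voxelMM = 0.1)
  expect_length(out2, 2)
})

test_that("a partially retracing branch keeps its novel tail as a child", {
  a <- lineBranch(c(0.5, 2, 2), c(4, 2, 2), n = 30, id = 1)
  # b retraces ~80% of a, then diverges with a short novel tail
  bPts <- rbind(a@points[1:24, ],
                outer(rep(1, 5), a@points[24, ]) +
                  outer(seq(0.1, 0.5, by = 0.1), c(0.3, 1, 0)))
  b <- BranchTrack(bPts, rep(0.25, nrow(bPts)), id = 2L)
  out <- removeDuplicates(list(a, b), screeningConfig(overlapThreshold = 0.7),
                          voxelMM = 0.1)
  ids <- vapply(out, function(x) x@id, integer(1))
  expect_setequal(ids, c(1L, 2L))
  tail_ <- out[[which(ids == 2L)]]
  expect_equal(tail_@parent, 1L)          # re-attached as a child of a
  expect_lt(nrow(tail_@points), nrow(bPts))
})

test_that("artifact-zone screening removes tortuous branches near large vessels", {
  lvArr <- array(FALSE, c(50, 50, 50)); lvArr[1:6, , ] <- TRUE
  lv <- VesselMask(lvArr, 0.1)
  msk <- fullMask()
  far <- lineBranch(c(2.5, 1, 1), c(4.5, 1, 1), id = 1)
  # jittery branch inside the dilated rim with tortuosity > 2
  set.seed(5)
  n <- 40
  jit <- cbind(rep(0.85, n) + rnorm(n, 0, 0.02),
               seq(1, 2, length.out = n) + 0.35 * sin(seq(0, 14, length.out = n)),
               rep(2, n))
  artifact <- BranchTrack(jit, rep(0.2, n), id = 2L)
  expect_gt(lsatrace:::branchTortuosity(artifact), 2)
  out <- removeArtifactBranches(list(far, artifact), lv, msk,
                                screeningConfig())
  expect_equal(vapply(out, function(b) b@id, integer(1)), 1L)
  # empty large-vessel mask: identity
  none <- VesselMask(array(FALSE, c(50, 50, 50)), 0.1)
  expect_length(removeArtifactBranches(list(far, artifact), none, msk,
                                       screeningConfig()), 2)
})

test_that("noise screening removes short and unsupported branches", {
  msk <- fullMask()
  short <- lineBranch(c(1, 1, 1), c(1.9, 1, 1), id = 1)   # 0.9 mm < 2 mm
  keep <- lineBranch(c(1, 2, 2), c(4, 2, 2), id = 2)
  out <- removeNoiseBranches(list(short, keep), msk, screeningConfig())
  expect_equal(vapply(out, function(b) b@id, integer(1)), 2L)
  # a branch with half its points outside the mask fails the support test
  halfArr <- array(FALSE, c(50, 50, 50)); halfArr[, 1:25, ] <- TRUE
  halfMask <- VesselMask(halfArr, 0.1)
  straddling <- lineBranch(c(2, 1.2, 2), c(2, 3.8, 2), id = 3)
  out2 <- removeNoiseBranches(list(straddling, keep), halfMask,
                              screeningConfig(minMaskSupport = 0.8))
  expect_equal(vapply(out2, function(b) b@id, integer(1)), 2L)
  # all valid: identity with order preserved
  out3 <- removeNoiseBranches(list(keep), msk, screeningConfig())
  expect_identical(vapply(out3, function(b) b@id, integer(1)), 2L)
})

test_that("screening a planted tree removes exactly the injected branches", {
  phY <- yJunctionPhantom()
  mask <- phY$truth$mask
  truthBranches <- lapply(1:3, function(i) {
    cl <- phY$truth$centerlines[[i]]
    idx <- unique(c(seq(1, nrow(cl), by = 5), nrow(cl)))
    BranchTrack(cl[idx, ], pmax(phY$truth$radii[[i]][idx], 0.05),
                id = as.integer(i),
                parent = if (i == 1) NA_integer_ else 1L,
                order = phY$truth$branchOrders[i])
  })
  lvArr <- array(FALSE, dim(imgData(mask))); lvArr[1:4, , ] <- TRUE
  lv <- VesselMask(lvArr, 0.1)
  set.seed(11)
  precision <- numeric(0); recall <- numeric(0)
  for (trial in 1:20) {
    # inject 5 false branches: 2 duplicates (partial retraces, as repeated
    # tracking produces), 1 artifact-zone, 2 short
    partial <- function(b, frac, id) {
      keep <- seq_len(max(3, floor(nrow(b@points) * frac)))
      BranchTrack(b@points[keep, ] +
                    matrix(rnorm(3 * length(keep), 0, 0.01), ncol = 3),
                  b@radii[keep], id = id)
    }
    dup1 <- partial(truthBranches[[1]], 0.9, 10L)
    dup2 <- partial(truthBranches[[2]], 0.9, 11L)
    n <- 30
    jit <- cbind(rep(0.25, n) + rnorm(n, 0, 0.02),
                 seq(1, 1.8, length.out = n) +
                   0.3 * sin(seq(0, 12, length.out = n)),
                 rep(2.45, n))
    artifact <- BranchTrack(jit, rep(0.2, n), id = 12L)
    s1 <- lineBranch(c(1, 1, 1) + runif(3, 0, 0.3),
                     c(1.8, 1, 1) + runif(3, 0, 0.3), id = 13L)
    s2 <- lineBranch(c(3, 4, 1) + runif(3, 0, 0.3),
                     c(3, 4, 1.8) + runif(3, 0, 0.3), id = 14L)
    branches <- c(truthBranches, list(dup1, dup2, artifact, s1, s2))
    out <- screenBranches(branches, mask, lv, screeningConfig())
    ids <- vapply(out, function(b) b@id, integer(1))
    tp <- sum(ids %in% 1:3)
    precision <- c(precision, tp / max(length(ids), 1))
    recall <- c(recall, tp / 3)
    # idempotence
    out2 <- screenBranches(out, mask, lv, screeningConfig())
    expect_equal(vapply(out2, function(b) b@id, integer(1)), ids)
  }
  expect_gte(mean(precision), 0.9)
  expect_gte(mean(recall), 0.9)
})

test_that("screening never invents branches and handles empty input", {
  expect_length(screenBranches(list(), fullMask()), 0)
  phY <- yJunctionPhantom()
  branches <- lapply(1:3, function(i) {
    cl <- phY$truth$centerlines[[i]]
    idx <- unique(c(seq(1, nrow(cl), by = 5), nrow(cl)))
    BranchTrack(cl[idx, ], pmax(phY$truth$radii[[i]][idx], 0.05),
                id = as.integer(i),
                parent = if (i == 1) NA_integer_ else 1L,
                order = phY$truth$branchOrders[i])
  })
  out <- screenBranches(branches, phY$truth$mask)
  expect_true(all(vapply(out, function(b) b@id, integer(1)) %in% 1:3))
  # orders recomputed from the surviving tree
  expect_equal(sort(vapply(out, function(b) b@order, integer(1))),
               c(1L, 2L, 2L))
})
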