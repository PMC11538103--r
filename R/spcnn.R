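#' Small-patch CNN configuration
#'
#' Defaults follow the training protocol of the framework: 3D convolutions of
#' kernel 3 and stride 2 (zero padding 1) each followed by batch
#' normalization and ReLU, one 2x2x2 max-pool after the first block, a
#' constant feature-map count through the downsampling steps until the dense
#' layers, a single sigmoid output trained by summed cross-entropy with Adam
#' (initial learning rate 1e-4, reduced by a factor 0.1 after 10 epochs
#' without test-loss improvement, never below 1e-8), batch size 25, at most
#' 80 epochs with early stop at 40.
#'
#' `featureMaps` is the scale knob: 128 is the full-size network; small
#' values (8-16) give a CPU-trainable network with the same architecture.
#'
#' @param featureMaps Feature maps per conv layer (default 128).
#' @param nBlocks Number of conv blocks (default 3).
#' @param denseUnits Width of the hidden dense layer (default 256).
#' @param convKernel,convStride,poolKernel Fixed architecture constants
#'   (3, 2, 2).
#' @param initialLr,minLr,lrFactor,lrPatience Adam/plateau schedule settings.
#' @param batchSize Minibatch size (default 25).
#' @param maxEpochs,earlyStopEpoch Epoch budget (80) and early stop (40).
#' @param seed Integer seed for initialization and shuffling.
#' @return An `spcnnConfig` list.
#' @export
spcnnConfig <- function(featureMaps = 128L, nBlocks = 3L, denseUnits = 256L,
                        convKernel = 3L, convStride = 2L, poolKernel = 2L,
                        initialLr = 1e-4, minLr = 1e-8, lrFactor = 0.1,
                        lrPatience = 10L, batchSize = 25L, maxEpochs = 80L,
                        earlyStopEpoch = 40L, seed = 1L) {
  stopifnot(featureMaps >= 1, nBlocks >= 1, denseUnits >= 1, batchSize >= 1,
            lrFactor > 0, lrFactor < 1, initialLr > 0, minLr > 0)
  structure(list(feature_maps = as.integer(featureMaps),
                 n_blocks = as.integer(nBlocks),
                 dense_units = as.integer(denseUnits),
                 conv_kernel = as.integer(convKernel),
                 conv_stride = as.integer(convStride),
                 pool_kernel = as.integer(poolKernel),
                 initial_lr = initialLr, min_lr = minLr,
                 lr_factor = lrFactor, lr_patience = as.integer(lrPatience),
                 batch_size = as.integer(batchSize),
                 max_epochs = as.integer(maxEpochs),
                 early_stop_epoch = as.integer(earlyStopEpoch),
                 seed = as.integer(seed)),
            class = "spcnnConfig")
}

## spatial sizes through the stack; conv: out = floor((s-1)/2)+1 (pad 1,
## kernel 3, stride 2); pool k2 s2: out = floor(s/2)
spcnnShapes <- function(patchSize, config) {
  s <- patchSize
  shapes <- list()
  for (b in seq_len(config$n_blocks)) {
    s <- (s - 1) %/% 2 + 1
    shapes[[length(shapes) + 1]] <- list(type = "conv", out = s)
    if (s < 1) return(NULL)
    if (b == 1) {
      s <- s %/% 2
      shapes[[length(shapes) + 1]] <- list(type = "pool", out = s)
      if (s < 1) return(NULL)
    }
  }
  shapes
}

minPatchSize <- function(config) {
  for (p in seq(3, 201, by = 2)) {
    if (!is.null(spcnnShapes(p, config))) return(p)
  }
  NA_integer_
}

## im2col gather indices for one conv layer: (out^3 x 27) linear indices into
## the zero-padded (s+2)^3 spatial grid
convColIndex <- function(s) {
  o <- (s - 1) %/% 2 + 1
  pd <- s + 2
  ctr <- as.matrix(expand.grid(i = seq(1, by = 2, length.out = o),
                               j = seq(1, by = 2, length.out = o),
                               k = seq(1, by = 2, length.out = o)))
  rel <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  idx <- matrix(0L, nrow(ctr), 27)
  for (r in 1:27) {
    ii <- ctr + matrix(rel[r, ], nrow(ctr), 3, byrow = TRUE)
    idx[, r] <- linIndex(ii, rep(pd, 3))
  }
  idx
}

#' Build an (untrained) small-patch CNN
#'
#' @param config An [spcnnConfig()].
#' @param patchSize Input cube side in voxels (default 25). An error naming
#'   the minimum feasible size is raised when the patch is too small for the
#'   configured downsampling depth.
#' @return An untrained [SPCNN-class].
#' @export
buildSPCNN <- function(config = spcnnConfig(), patchSize = 25L) {
  patchSize <- as.integer(patchSize)
  shapes <- spcnnShapes(patchSize, config)
  if (is.null(shapes))
    stop(sprintf(
      "patch size %d too small for %d conv blocks; minimum is %d",
      patchSize, config$n_blocks, minPatchSize(config)))
  C <- config$feature_maps
  set.seed(deriveSeed(config$seed, "spcnn-init"))
  params <- list(); state <- list(layers = list())
  s <- patchSize; cin <- 1L; li <- 0L
  for (b in seq_len(config$n_blocks)) {
    li <- li + 1L
    fanIn <- 27 * cin
    params[[sprintf("convW%d", b)]] <-
      matrix(rnorm(fanIn * C, 0, sqrt(2 / fanIn)), fanIn, C)
    params[[sprintf("convB%d", b)]] <- rep(0, C)
    params[[sprintf("bnG%d", b)]] <- rep(1, C)
    params[[sprintf("bnB%d", b)]] <- rep(0, C)
    state$layers[[li]] <- list(type = "conv", block = b, inSize = s,
                               colIdx = convColIndex(s), cin = cin)
    state[[sprintf("bnMean%d", b)]] <- rep(0, C)
    state[[sprintf("bnVar%d", b)]] <- rep(1, C)
    s <- (s - 1) %/% 2 + 1
    cin <- C
    if (b == 1) {
      li <- li + 1L
      state$layers[[li]] <- list(type = "pool", inSize = s)
      s <- s %/% 2
    }
  }
  flat <- s^3 * C
  params$denseW1 <- matrix(rnorm(flat * config$dense_units, 0,
                                 sqrt(2 / flat)), flat, config$dense_units)
  params$denseB1 <- rep(0, config$dense_units)
  params$denseW2 <- matrix(rnorm(config$dense_units, 0,
                                 sqrt(2 / config$dense_units)),
                           config$dense_units, 1)
  params$denseB2 <- 0
  state$finalSize <- s
  new("SPCNN", config = unclass(config), params = params, state = state,
      patchSize = patchSize, trained = FALSE,
      history = data.frame())
}

#' Number of trainable parameters of an SPCNN
#' @param net An [SPCNN-class].
#' @return Integer parameter count (conv weights/biases, batch-norm
#'   scale/shift, dense weights/biases).
#' @export
spcnnParameterCount <- function(net) {
  sum(vapply(net@params, length, numeric(1)))
}

## ---- forward / backward engine -------------------------------------------
## activations carried as arrays (s, s, s, C, N); conv works on im2col
## matrices (out^3 * N) x (27 * Cin)

spcnnGather <- function(a, colIdx) {
  d <- dim(a)                       # (s,s,s,C,N)
  s <- d[1]; C <- d[4]; N <- d[5]; pd <- s + 2
  ap <- array(0, c(pd, pd, pd, C, N))
  ap[2:(s + 1), 2:(s + 1), 2:(s + 1), , ] <- a
  Pm <- matrix(ap, nrow = pd^3)
  G <- Pm[as.vector(colIdx), , drop = FALSE]     # (o3*27) x (C*N)
  o3 <- nrow(colIdx)
  dim(G) <- c(o3, 27, C, N)
  G <- aperm(G, c(1, 4, 2, 3))                   # (o3, N, 27, C)
  dim(G) <- c(o3 * N, 27 * C)
  G
}

spcnnScatter <- function(dXcol, colIdx, s, C, N) {
  o3 <- nrow(colIdx); pd <- s + 2
  dim(dXcol) <- c(o3, N, 27, C)
  G <- aperm(dXcol, c(1, 3, 4, 2))               # (o3, 27, C, N)
  dim(G) <- c(o3 * 27, C * N)
  grp <- as.vector(colIdx)
  rs <- rowsum(G, group = grp)
  dPm <- matrix(0, pd^3, C * N)
  dPm[as.integer(rownames(rs)), ] <- rs
  dp <- array(dPm, c(pd, pd, pd, C, N))
  dp[2:(s + 1), 2:(s + 1), 2:(s + 1), , , drop = FALSE]
}

spcnnForward <- function(net, X, training = FALSE) {
  cfg <- net@config; P <- net@params; S <- net@state
  N <- nrow(X); ps <- net@patchSize
  a <- array(t(X), c(ps, ps, ps, 1, N))
  cache <- list(N = N)
  eps <- 1e-5; mom <- 0.9
  runUpd <- list()
  for (li in seq_along(S$layers)) {
    ly <- S$layers[[li]]
    if (ly$type == "conv") {
      b <- ly$block
      Xcol <- spcnnGather(a, ly$colIdx)
      Z <- sweep(Xcol %*% P[[sprintf("convW%d", b)]], 2,
                 P[[sprintf("convB%d", b)]], `+`)
      if (training) {
        mu <- colMeans(Z)
        vr <- colMeans(Z^2) - mu^2
        runUpd[[sprintf("bnMean%d", b)]] <-
          mom * S[[sprintf("bnMean%d", b)]] + (1 - mom) * mu
        runUpd[[sprintf("bnVar%d", b)]] <-
          mom * S[[sprintf("bnVar%d", b)]] + (1 - mom) * vr
      } else {
        mu <- S[[sprintf("bnMean%d", b)]]
        vr <- S[[sprintf("bnVar%d", b)]]
      }
      invstd <- 1 / sqrt(vr + eps)
      xhat <- sweep(sweep(Z, 2, mu, `-`), 2, invstd, `*`)
      Zbn <- sweep(sweep(xhat, 2, P[[sprintf("bnG%d", b)]], `*`), 2,
                   P[[sprintf("bnB%d", b)]], `+`)
      A <- pmax(Zbn, 0)
      o3 <- nrow(ly$colIdx); C <- cfg$feature_maps
      o <- round(o3^(1 / 3))
      if (training)
        cache[[sprintf("conv%d", b)]] <-
          list(Xcol = Xcol, xhat = xhat, invstd = invstd, reluMask = Zbn > 0,
               inDim = dim(a))
      dim(A) <- c(o3, N, C)
      a <- aperm(A, c(1, 3, 2))
      dim(a) <- c(o, o, o, C, N)
    } else {                        # max pool k2 s2
      d <- dim(a); f <- d[1] %/% 2
      sel <- seq(1, 2 * f, by = 2)
      out <- NULL; arg <- NULL; i <- 0L
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        i <- i + 1L
        sub <- a[sel + dx, sel + dy, sel + dz, , , drop = FALSE]
        if (is.null(out)) {
          out <- sub; arg <- array(1L, dim = dim(sub))
        } else {
          upd <- sub > out
          out[upd] <- sub[upd]; arg[upd] <- i
        }
      }
      if (training)
        cache[[sprintf("pool%d", li)]] <- list(arg = arg, inDim = d, f = f)
      a <- out
    }
  }
  flat <- matrix(a, ncol = N)                      # flat x N
  Xd <- t(flat)
  H <- sweep(Xd %*% P$denseW1, 2, P$denseB1, `+`)
  Hr <- pmax(H, 0)
  z <- as.vector(Hr %*% P$denseW2) + P$denseB2
  p <- 1 / (1 + exp(-z))
  p <- clamp(p, 1e-12, 1 - 1e-12)
  if (training) {
    cache$Xd <- Xd; cache$H <- H; cache$Hr <- Hr
    cache$flatDim <- dim(a)
  }
  list(p = p, cache = cache, runUpd = runUpd)
}

spcnnBackward <- function(net, fwd, y) {
  cfg <- net@config; P <- net@params; S <- net@state
  cache <- fwd$cache; N <- cache$N
  grads <- list()
  dz <- matrix(fwd$p - y, ncol = 1)                # summed cross-entropy
  grads$denseW2 <- t(cache$Hr) %*% dz
  grads$denseB2 <- sum(dz)
  dH <- dz %*% t(P$denseW2)
  dH[cache$H <= 0] <- 0
  grads$denseW1 <- t(cache$Xd) %*% dH
  grads$denseB1 <- colSums(dH)
  dXd <- dH %*% t(P$denseW1)
  da <- array(t(dXd), cache$flatDim)

  for (li in rev(seq_along(S$layers))) {
    ly <- S$layers[[li]]
    if (ly$type == "pool") {
      pc <- cache[[sprintf("pool%d", li)]]
      dIn <- array(0, pc$inDim)
      f <- pc$f; sel <- seq(1, 2 * f, by = 2)
      i <- 0L
      for (dz_ in 0:1) for (dy in 0:1) for (dx in 0:1) {
        i <- i + 1L
        m <- pc$arg == i
        sub <- dIn[sel + dx, sel + dy, sel + dz_, , , drop = FALSE]
        sub[m] <- da[m]
        dIn[sel + dx, sel + dy, sel + dz_, , ] <- sub
      }
      da <- dIn
    } else {
      b <- ly$block
      cc <- cache[[sprintf("conv%d", b)]]
      C <- ncol(cc$xhat)
      o3 <- nrow(ly$colIdx)
      dA <- aperm(array(da, c(o3, C, N)), c(1, 3, 2))
      dim(dA) <- c(o3 * N, C)
      dA[!cc$reluMask] <- 0
      ## batch-norm backward
      g <- P[[sprintf("bnG%d", b)]]
      grads[[sprintf("bnG%d", b)]] <- colSums(dA * cc$xhat)
      grads[[sprintf("bnB%d", b)]] <- colSums(dA)
      dxhat <- sweep(dA, 2, g, `*`)
      m <- nrow(dxhat)
      t1 <- sweep(dxhat, 2, colMeans(dxhat), `-`)
      t2 <- sweep(cc$xhat, 2, colMeans(dxhat * cc$xhat), `*`)
      dZ <- sweep(t1 - t2, 2, cc$invstd, `*`)
      grads[[sprintf("convW%d", b)]] <- t(cc$Xcol) %*% dZ
      grads[[sprintf("convB%d", b)]] <- colSums(dZ)
      dXcol <- dZ %*% t(P[[sprintf("convW%d", b)]])
      da <- spcnnScatter(dXcol, ly$colIdx, cc$inDim[1], cc$inDim[4], N)
    }
  }
  grads
}

#' Learning-rate trace of the plateau schedule
#'
#' Given a sequence of per-epoch test losses, returns the learning rate in
#' force at each epoch: the rate is multiplied by `factor` whenever the test
#' loss has failed to improve for `patience` consecutive epochs, and never
#' falls below `minLr`.
#'
#' @param testLosses Numeric vector of per-epoch test losses.
#' @param initialLr,factor,patience,minLr Schedule parameters.
#' @return Numeric vector of learning rates, same length as `testLosses`.
#' @export
plateauSchedule <- function(testLosses, initialLr = 1e-4, factor = 0.1,
                            patience = 10L, minLr = 1e-8) {
  lr <- initialLr
  best <- Inf; wait <- 0L
  out <- numeric(length(testLosses))
  for (i in seq_along(testLosses)) {
    out[i] <- lr
    if (testLosses[i] < best - 1e-12) {
      best <- testLosses[i]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- max(lr * factor, minLr)
        wait <- 0L
      }
    }
  }
  out
}

## loss/accuracy over a dataset in chunks (inference mode)
spcnnEvaluate <- function(net, X, y, chunk = 1024L) {
  n <- nrow(X); loss <- 0; correct <- 0
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- spcnnForward(net, X[s:e, , drop = FALSE])$p
    loss <- loss - sum(y[s:e] * log(p) + (1 - y[s:e]) * log(1 - p))
    correct <- correct + sum((p >= 0.5) == (y[s:e] == 1))
  }
  list(loss = loss, acc = correct / n)
}

#' Train the small-patch CNN
#'
#' Minimizes summed cross-entropy with Adam under the plateau learning-rate
#' schedule, recording per-epoch train/test loss and accuracy. Training stops
#' at `earlyStopEpoch` (default 40) or `maxEpochs`. Runs are reproducible for
#' a fixed config seed.
#'
#' @param net An [SPCNN-class] from [buildSPCNN()].
#' @param data A [PatchSet-class]; the training split must contain both
#'   classes.
#' @param epochs Optional override of the epoch budget (still capped by the
#'   early stop).
#' @param verbose Print per-epoch progress.
#' @return The trained [SPCNN-class] with `history` filled in.
#' @export
trainSPCNN <- function(net, data, epochs = NULL, verbose = FALSE) {
  cfg <- net@config
  tr <- data@split == "train"
  Xtr <- data@patches[tr, , drop = FALSE]; ytr <- data@labels[tr]
  Xte <- data@patches[!tr, , drop = FALSE]; yte <- data@labels[!tr]
  if (length(unique(ytr)) < 2)
    stop("training split must contain both classes")
  nEpochs <- min(epochs %||% cfg$max_epochs, cfg$early_stop_epoch)

  set.seed(deriveSeed(cfg$seed, "spcnn-train"))
  adamM <- lapply(net@params, function(p) p * 0)
  adamV <- lapply(net@params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8; t <- 0
  testLosses <- numeric(0)
  hist <- list()

  for (ep in seq_len(nEpochs)) {
    lr <- tail(plateauSchedule(c(testLosses, Inf), cfg$initial_lr,
                               cfg$lr_factor, cfg$lr_patience, cfg$min_lr), 1)
    ord <- sample(nrow(Xtr))
    epLoss <- 0; epCorrect <- 0
    for (s in seq(1, length(ord), by = cfg$batch_size)) {
      e <- min(s + cfg$batch_size - 1L, length(ord))
      bi <- ord[s:e]
      fwd <- spcnnForward(net, Xtr[bi, , drop = FALSE], training = TRUE)
      for (nm in names(fwd$runUpd)) net@state[[nm]] <- fwd$runUpd[[nm]]
      yb <- ytr[bi]
      epLoss <- epLoss - sum(yb * log(fwd$p) + (1 - yb) * log(1 - fwd$p))
      epCorrect <- epCorrect + sum((fwd$p >= 0.5) == (yb == 1))
      grads <- spcnnBackward(net, fwd, yb)
      t <- t + 1
      for (nm in names(grads)) {
        adamM[[nm]] <- beta1 * adamM[[nm]] + (1 - beta1) * grads[[nm]]
        adamV[[nm]] <- beta2 * adamV[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- adamM[[nm]] / (1 - beta1^t)
        vhat <- adamV[[nm]] / (1 - beta2^t)
        net@params[[nm]] <- net@params[[nm]] - lr * mhat / (sqrt(vhat) + adamEps)
      }
    }
    te <- if (nrow(Xte)) spcnnEvaluate(net, Xte, yte) else
      list(loss = epLoss / max(nrow(Xtr), 1), acc = NA_real_)
    testLosses <- c(testLosses, te$loss)
    hist[[ep]] <- data.frame(epoch = ep, trainLoss = epLoss,
                             trainAcc = epCorrect / nrow(Xtr),
                             testLoss = te$loss, testAcc = te$acc, lr = lr)
    if (verbose)
      message(sprintf(
        "epoch %d: train loss %.3f acc %.3f | test loss %.3f acc %.3f | lr %g",
        ep, epLoss, epCorrect / nrow(Xtr), te$loss, te$acc, lr))
  }
  net@trained <- TRUE
  net@history <- do.call(rbind, hist)
  net@state$normBounds <- c(data@normMin, data@normMax)
  net
}

#' Classify patches with a (trained) SPCNN
#'
#' Inference is deterministic: batch-norm uses the stored running statistics
#' and outputs are strictly inside (0, 1) by the sigmoid.
#'
#' @param net An [SPCNN-class].
#' @param X n x patchSize^3 matrix of normalized patches (values in [0, 1]).
#' @param chunk Patches per forward batch.
#' @return Numeric vector of vessel probabilities.
#' @export
predictSPCNN <- function(net, X, chunk = 1024L) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  n <- nrow(X)
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e] <- spcnnForward(net, X[s:e, , drop = FALSE])$p
  }
  out
}

#' Save / load an SPCNN checkpoint (single file, config embedded)
#'
#' @param net An [SPCNN-class].
#' @param path Checkpoint file path.
#' @return `loadSPCNN` returns the [SPCNN-class].
#' @export
saveSPCNN <- function(net, path) saveRDS(net, path)

#' @rdname saveSPCNN
#' @export
loadSPCNN <- function(path) readRDS(path)
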