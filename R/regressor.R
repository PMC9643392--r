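#' Regressor architecture and training configuration
#'
#' Training defaults follow the reference protocol: batches of 12 patches,
#' 200 training and 500 validation iterations per epoch, Adam at an initial
#' learning rate of 1e-4 decreased by 30 percent after ten epochs without
#' validation improvement, decoupled weight decay, and early stopping after
#' ten stagnant epochs. The architecture (dense-block layout, growth rate,
#' compression) is configurable; \code{\link{deskConfig}} provides a small
#' CPU-trainable reference layout.
#'
#' @param inputSize patch edge length in pixels.
#' @param inputSpacing patch spacing in micrometres per pixel.
#' @param blockLayout integer vector, convolution layers per dense block.
#' @param growthRate channels added by each dense-block layer.
#' @param stemChannels channels of the initial convolution.
#' @param stemPool average-pool once right after the stem?
#' @param compression channel-keep fraction of each transition layer.
#' @param batchSize patches per training iteration.
#' @param trainIters,valIters iterations per epoch.
#' @param lrInit initial learning rate.
#' @param lrDecayFactor fractional decrease on plateau (0.30 means the
#'   learning rate is multiplied by 0.70).
#' @param lrPatience epochs without validation improvement before a decay.
#' @param earlyStopPatience stagnant epochs before training stops.
#' @param weightDecay decoupled weight-decay coefficient.
#' @param maxEpochs hard epoch cap.
#' @param normMean,normSd fixed input normalization constants.
#' @param seed seed for weight initialization.
#' @return configuration list.
#' @export
regressorConfig <- function(inputSize = 512, inputSpacing = 0.5,
                            blockLayout = c(4, 4, 4), growthRate = 12,
                            stemChannels = 16, stemPool = TRUE,
                            compression = 0.5, batchSize = 12,
                            trainIters = 200, valIters = 500,
                            lrInit = 1e-4, lrDecayFactor = 0.30,
                            lrPatience = 10, earlyStopPatience = 10,
                            weightDecay = 1e-4, maxEpochs = 100,
                            normMean = 0.65, normSd = 0.25, seed = 1L) {
  cfg <- list(inputSize = inputSize, inputSpacing = inputSpacing,
              blockLayout = blockLayout, growthRate = growthRate,
              stemChannels = stemChannels, stemPool = stemPool,
              compression = compression, batchSize = batchSize,
              trainIters = trainIters, valIters = valIters,
              lrInit = lrInit, lrDecayFactor = lrDecayFactor,
              lrPatience = lrPatience, earlyStopPatience = earlyStopPatience,
              weightDecay = weightDecay, maxEpochs = maxEpochs,
              normMean = normMean, normSd = normSd, seed = seed)
  stopIfNot(all(c(inputSize, growthRate, batchSize, trainIters,
                  valIters, lrPatience, earlyStopPatience) > 0),
            "all counts must be positive")
  stopIfNot(lrDecayFactor > 0 && lrDecayFactor < 1,
            "lrDecayFactor must lie in (0, 1)")
  cfg
}

#' Desk-scale reference configuration
#'
#' A small dense-net layout (three blocks of two layers, growth 8) on
#' 64-pixel patches at 0.5 micrometres per pixel, trainable on one CPU in
#' minutes while preserving the reference training protocol (batch 12,
#' plateau schedule, early stopping).
#'
#' @param ... overrides passed to \code{\link{regressorConfig}}.
#' @export
deskConfig <- function(...) {
  args <- list(inputSize = 64, inputSpacing = 0.5,
               blockLayout = c(2, 2, 2), growthRate = 8,
               stemChannels = 12, stemPool = TRUE, compression = 0.5,
               trainIters = 100, valIters = 28, lrInit = 1e-3,
               weightDecay = 1e-4, maxEpochs = 25)
  args[names(list(...))] <- list(...)
  do.call(regressorConfig, args)
}

#' Build a dense-block regressor
#'
#' Constructs the network: a stem convolution, densely connected blocks in
#' which every layer receives the concatenation of all preceding feature
#' maps of its block, channel-reducing 1x1 transition layers with average
#' pooling between blocks, global average pooling and a single linear
#' output. Weights are He-initialized under the config seed; the output
#' bias starts at 2, the midpoint of the score range.
#'
#' @param config list from \code{\link{regressorConfig}}.
#' @return a \linkS4class{PleoRegressor}.
#' @export
buildRegressor <- function(config = regressorConfig()) {
  nPool <- as.integer(config$stemPool) + length(config$blockLayout) - 1L
  stopIfNot(config$inputSize %% (2^nPool) == 0 &&
            config$inputSize / 2^nPool >= 2,
            "input size incompatible with the pooling layout",
            class = "pleoConfigError")
  withSeed(config$seed, {
    he <- function(cout, K) matrix(rnorm(cout * K, 0, sqrt(2 / K)), cout, K)
    layers <- list()
    C <- config$stemChannels
    layers[[1]] <- list(type = "conv", k = 3L, W = he(C, 27L),
                        b = rep(0, C))
    layers[[2]] <- list(type = "relu")
    if (config$stemPool) layers[[length(layers) + 1]] <-
        list(type = "pool", f = 2L)
    g <- config$growthRate
    for (bi in seq_along(config$blockLayout)) {
      convs <- list()
      for (l in seq_len(config$blockLayout[bi])) {
        K <- 9L * C
        convs[[l]] <- list(W = he(g, K), b = rep(0, g))
        C <- C + g
      }
      layers[[length(layers) + 1]] <-
        list(type = "denseblock", k = 3L, growth = g, convs = convs)
      if (bi < length(config$blockLayout)) {
        Cout <- max(1L, floor(C * config$compression))
        layers[[length(layers) + 1]] <-
          list(type = "transition", f = 2L, W = he(Cout, C),
               b = rep(0, Cout))
        C <- Cout
      }
    }
    layers[[length(layers) + 1]] <- list(type = "gap")
    layers[[length(layers) + 1]] <-
      list(type = "linear", W = matrix(rnorm(C, 0, sqrt(1 / C)), 1, C),
           b = 2)
    new("PleoRegressor", config = config, layers = layers)
  })
}

#' Smooth-L1 (Huber-style) regression loss
#'
#' \code{0.5 d^2 / beta} for \code{|d| < beta}, else \code{|d| - 0.5 beta},
#' with \code{d = prediction - target}: quadratic near zero, linear in the
#' tails, continuous and once-differentiable at \code{|d| = beta}.
#'
#' @param prediction,target numeric vectors.
#' @param beta transition point (> 0).
#' @return elementwise non-negative losses.
#' @export
smoothL1 <- function(prediction, target, beta = 1) {
  stopIfNot(beta > 0, "beta must be > 0")
  d <- prediction - target
  ifelse(abs(d) < beta, 0.5 * d^2 / beta, abs(d) - 0.5 * beta)
}

smoothL1Grad <- function(prediction, target, beta = 1) {
  d <- prediction - target
  ifelse(abs(d) < beta, d / beta, sign(d))
}

#' Augmentation parameters
#'
#' @param dihedral apply a random one of the 8 flips/rotations?
#' @param stainAlpha relative scaling range of the per-stain optical
#'   density channels (hematoxylin/eosin decomposition), e.g. 0.15 scales
#'   each channel by a factor in [0.85, 1.15].
#' @param stainBeta additive offset range on the stain channels.
#' @param blurSigmaMax maximum Gaussian blur sigma in pixels (sigma is
#'   drawn uniformly from [0, blurSigmaMax]).
#' @export
augmentParams <- function(dihedral = TRUE, stainAlpha = 0.15,
                          stainBeta = 0.03, blurSigmaMax = 1.0) {
  list(dihedral = dihedral, stainAlpha = stainAlpha,
       stainBeta = stainBeta, blurSigmaMax = blurSigmaMax)
}

dihedralTransform <- function(patch, k) {
  # k in 1..8: rotations 0/90/180/270, each optionally h-flipped
  rot <- (k - 1) %% 4
  flip <- k > 4
  out <- patch
  if (flip) out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
  for (r in seq_len(rot)) {
    out <- aperm(out, c(2, 1, 3))
    out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
  }
  out
}

#' Augment a training patch
#'
#' Random composition of one of the 8 dihedral transforms, a stain-space
#' jitter (the image is decomposed into hematoxylin/eosin optical-density
#' channels which are scaled and offset within the configured ranges), and
#' a Gaussian blur with random sigma. With all ranges at zero and dihedral
#' disabled the transform is the identity.
#'
#' @param patch square numeric array \code{H x W x 3} in [0, 1].
#' @param params list from \code{\link{augmentParams}}.
#' @param seed optional integer seed.
#' @return augmented patch of the same shape.
#' @export
augmentPatch <- function(patch, params = augmentParams(), seed = NULL) {
  d <- dim(patch)
  stopIfNot(d[1] == d[2], "patch must be square")
  withSeed(seed, {
    out <- patch
    if (params$dihedral)
      out <- dihedralTransform(out, sample.int(8, 1))
    if (params$stainAlpha > 0 || params$stainBeta > 0) {
      sv <- stainVectors()
      od <- -log(pmax(out, 1 / 255))
      odm <- matrix(od, ncol = 3)
      P <- t(sv) %*% solve(sv %*% t(sv))
      conc <- odm %*% P
      resid <- odm - conc %*% sv
      alpha <- runif(2, 1 - params$stainAlpha, 1 + params$stainAlpha)
      beta <- runif(2, -params$stainBeta, params$stainBeta)
      conc <- sweep(sweep(conc, 2, alpha, "*"), 2, beta, "+")
      odm <- conc %*% sv + resid
      out <- array(exp(-odm), dim = d)
    }
    if (params$blurSigmaMax > 0) {
      s <- runif(1, 0, params$blurSigmaMax)
      if (s > 0.05) {
        for (c in 1:3) out[, , c] <- EBImage::gblur(out[, , c], s)
      }
    }
    clamp(out, 0, 1)
  })
}

#' Patch sampler over an in-memory pool
#'
#' Returns a function \code{f(n)} yielding \code{list(x, y)} batches.
#' \code{"random"} mode draws with replacement from the pool using the
#' ambient RNG stream (so a seeded training run is reproducible);
#' \code{"cycle"} mode iterates deterministically, which keeps the
#' validation pool fixed across epochs.
#'
#' @param x patch array \code{H x W x 3 x N}.
#' @param y numeric reference scores of length N.
#' @param mode \code{"random"} or \code{"cycle"}.
#' @param augment optional \code{\link{augmentParams}} list applied to each
#'   drawn patch.
#' @export
makePatchSampler <- function(x, y, mode = c("random", "cycle"),
                             augment = NULL) {
  mode <- match.arg(mode)
  N <- dim(x)[4]
  stopIfNot(N == length(y), "x and y must have matching lengths")
  pos <- 0L
  function(n) {
    idx <- if (mode == "random") sample.int(N, n, replace = TRUE)
    else {
      i <- ((pos + seq_len(n) - 1L) %% N) + 1L
      pos <<- (pos + n) %% N
      i
    }
    xb <- x[, , , idx, drop = FALSE]
    if (!is.null(augment))
      for (b in seq_len(n))
        xb[, , , b] <- augmentPatch(xb[, , , b], augment)
    list(x = xb, y = y[idx])
  }
}

#' Plateau learning-rate schedule with early stopping
#'
#' Tracks the best validation loss; after \code{lrPatience} epochs without
#' improvement the learning rate is multiplied by
#' \code{1 - lrDecayFactor} (and the decay counter resets), and after
#' \code{earlyStopPatience} epochs without improvement training stops.
#' \code{plateauInit} builds the state; \code{plateauUpdate} consumes one
#' epoch's validation loss and returns the updated state with fields
#' \code{lr}, \code{decayed} (did this epoch trigger a decay), \code{stop},
#' \code{improved} and \code{bestEpoch}.
#'
#' @param lrInit initial learning rate.
#' @param lrDecayFactor,lrPatience,earlyStopPatience see
#'   \code{\link{regressorConfig}}.
#' @export
plateauInit <- function(lrInit, lrDecayFactor = 0.30, lrPatience = 10,
                        earlyStopPatience = 10) {
  list(lr = lrInit, factor = 1 - lrDecayFactor, lrPatience = lrPatience,
       stopPatience = earlyStopPatience, best = Inf, bestEpoch = 0L,
       epoch = 0L, sinceBest = 0L, sinceDecay = 0L,
       decayed = FALSE, stop = FALSE, improved = FALSE)
}

#' @rdname plateauInit
#' @param state schedule state.
#' @param valLoss the epoch's validation loss.
#' @export
plateauUpdate <- function(state, valLoss) {
  state$epoch <- state$epoch + 1L
  state$decayed <- FALSE
  if (valLoss < state$best) {
    state$best <- valLoss
    state$bestEpoch <- state$epoch
    state$sinceBest <- 0L
    state$sinceDecay <- 0L
    state$improved <- TRUE
  } else {
    state$improved <- FALSE
    state$sinceBest <- state$sinceBest + 1L
    state$sinceDecay <- state$sinceDecay + 1L
    if (state$sinceDecay >= state$lrPatience) {
      state$lr <- state$lr * state$factor
      state$sinceDecay <- 0L
      state$decayed <- TRUE
    }
  }
  state$stop <- state$sinceBest >= state$stopPatience
  state
}

#' Train the dense-block regressor
#'
#' Runs epochs of \code{trainIters} batches of \code{batchSize} patches,
#' minimizing the smooth-L1 loss between the (unclamped) network output and
#' the continuous reference scores with Adam plus decoupled weight decay.
#' After each epoch the validation loss is computed over \code{valIters}
#' batches, the plateau schedule is updated, and the parameters of the best
#' validation epoch are snapshotted and returned.
#'
#' @param model a \linkS4class{PleoRegressor} (architecture + init).
#' @param trainSource,valSource batch samplers, functions \code{f(n)}
#'   returning \code{list(x = array(H, W, 3, n), y = numeric(n))}; see
#'   \code{\link{makePatchSampler}}.
#' @param seed optional integer seed for the whole run.
#' @param verbose print per-epoch progress?
#' @return list with \code{model} (best-epoch snapshot) and \code{history}
#'   (data.frame: epoch, trainLoss, valLoss, lr, best).
#' @export
trainRegressor <- function(model, trainSource, valSource, seed = NULL,
                           verbose = FALSE) {
  cfg <- model@config
  withSeed(seed, {
    layers <- model@layers
    state <- adamInit(layers)
    sched <- plateauInit(cfg$lrInit, cfg$lrDecayFactor, cfg$lrPatience,
                         cfg$earlyStopPatience)
    bestLayers <- layers
    hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                       valLoss = numeric(0), lr = numeric(0),
                       best = logical(0))
    t <- 0L
    for (epoch in seq_len(cfg$maxEpochs)) {
      tl <- numeric(cfg$trainIters)
      for (it in seq_len(cfg$trainIters)) {
        batch <- trainSource(cfg$batchSize)
        X <- patchesToInput(batch$x, cfg$normMean, cfg$normSd)
        fw <- nnForward(layers, X, cfg$inputSize, cfg$inputSize,
                        cfg$batchSize)
        loss <- mean(smoothL1(fw$pred, batch$y))
        if (!is.finite(loss))
          stop(errorCondition("non-finite training loss",
                              class = c("pleoNaNLossError", "error")))
        tl[it] <- loss
        dPred <- smoothL1Grad(fw$pred, batch$y) / cfg$batchSize
        bw <- nnBackward(layers, fw$caches, dPred, cfg$batchSize)
        t <- t + 1L
        st <- adamStep(layers, bw$grads, state, sched$lr, t,
                       cfg$weightDecay)
        layers <- st$layers; state <- st$state
      }
      vl <- numeric(cfg$valIters)
      for (it in seq_len(cfg$valIters)) {
        batch <- valSource(cfg$batchSize)
        X <- patchesToInput(batch$x, cfg$normMean, cfg$normSd)
        fw <- nnForward(layers, X, cfg$inputSize, cfg$inputSize,
                        cfg$batchSize)
        vl[it] <- mean(smoothL1(fw$pred, batch$y))
      }
      lrBefore <- sched$lr
      sched <- plateauUpdate(sched, mean(vl))
      if (sched$improved) bestLayers <- layers
      hist <- rbind(hist, data.frame(
        epoch = epoch, trainLoss = mean(tl), valLoss = mean(vl),
        lr = lrBefore, best = sched$improved))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e%s",
                        epoch, mean(tl), mean(vl), lrBefore,
                        if (sched$improved) " *" else ""))
      if (sched$stop) break
    }
    list(model = new("PleoRegressor", config = cfg, layers = bestLayers),
         history = hist, bestEpoch = sched$bestEpoch)
  })
}

# Batched raw (unclamped) forward pass.
predictRaw <- function(model, patches) {
  cfg <- model@config
  d <- dim(patches)
  B <- if (length(d) == 4) d[4] else 1L
  X <- patchesToInput(patches, cfg$normMean, cfg$normSd)
  nnForward(model@layers, X, cfg$inputSize, cfg$inputSize, B)$pred
}

#' Batched patch prediction
#'
#' @param model a \linkS4class{PleoRegressor} or \linkS4class{ConstantModel}.
#' @param patches array \code{H x W x 3 x B} (or a list of patches).
#' @param chunk internal batching size.
#' @return numeric scores clamped to [1, 3].
#' @export
predictPatches <- function(model, patches, chunk = 64L) {
  if (is.list(patches))
    patches <- array(unlist(patches, use.names = FALSE),
                     dim = c(dim(patches[[1]]), length(patches)))
  if (length(dim(patches)) == 3) dim(patches) <- c(dim(patches), 1L)
  B <- dim(patches)[4]
  if (is(model, "ConstantModel")) return(rep(model@value, B))
  out <- numeric(B)
  for (s in seq(1L, B, by = chunk)) {
    e <- min(s + chunk - 1L, B)
    out[s:e] <- predictRaw(model, patches[, , , s:e, drop = FALSE])
  }
  clamp(out, 1, 3)
}

#' @rdname predictPatch
setMethod("predictPatch", "PleoRegressor", function(model, patch) {
  d <- dim(patch)
  stopIfNot(length(d) == 3 && d[1] == model@config$inputSize &&
            d[2] == model@config$inputSize && d[3] == 3,
            "patch does not match the configured input size",
            class = "pleoShapeError")
  clamp(predictRaw(model, patch), 1, 3)
})

#' @rdname predictPatch
setMethod("predictPatch", "ConstantModel", function(model, patch)
  model@value)

#' Constant-output model
#'
#' @param value the constant score returned for every patch.
#' @return a \linkS4class{ConstantModel}.
#' @export
constantModel <- function(value) new("ConstantModel", value = value)

#' Score a region of interest
#'
#' Samples \code{nPatches} overlapping patches from areas of high tumor
#' nuclear density (via the detection-driven density map) and averages
#' their predicted scores, mitigating occasional off-target single-patch
#' predictions.
#'
#' @param model patch scorer.
#' @param roi ROI raster (\code{H x W x 3} array) or a
#'   \linkS4class{SyntheticSlide}.
#' @param dets a \linkS4class{DetectionSet} registered to the ROI.
#' @param nPatches number of sampled patches.
#' @param seed optional integer seed.
#' @param sigma,stride density-map parameters (pixels).
#' @return the mean continuous score in [1, 3].
#' @export
scoreRoi <- function(model, roi, dets, nPatches = 16, seed = NULL,
                     sigma = 16, stride = 4) {
  if (is(roi, "SyntheticSlide")) roi <- slideImage(roi)
  size <- if (is(model, "ConstantModel")) 64L else model@config$inputSize
  stopIfNot(min(dim(roi)[1:2]) >= size, "ROI smaller than the patch size")
  d <- detections(dets)
  if (!any(d$label == "tumor")) noTumorError()
  dm <- densityMap(dets, sigma = sigma, stride = stride,
                   labelFilter = "tumor")
  centers <- samplePatchCenters(dm, nPatches, size, seed = seed)
  patches <- lapply(seq_len(nPatches), function(i)
    cropImage(roi, round(centers$x[i] - size / 2),
              round(centers$y[i] - size / 2), size, size))
  mean(predictPatches(model, patches))
}

#' Grad-CAM saliency for the regression output
#'
#' Gradient-weighted class activation mapping for the scalar score: the
#' gradients of the output with respect to the feature maps of a dense
#' block are global-average-pooled into channel weights, the weighted
#' feature-map sum is rectified, upsampled to patch resolution and
#' max-normalized to [0, 1]. A constant model (all-zero gradients) yields
#' an all-zero map flagged with \code{attr(map, "zeroGradient")}.
#'
#' In classification Grad-CAM one differentiates the score of the class of
#' interest; the regression analog used here (\code{direction =
#' "predicted"}) differentiates the output in the direction of the
#' predicted half of the severity spectrum: for predictions at or above the
#' midpoint 2 the evidence that raises the score, below it the evidence
#' that lowers it. \code{"increase"} always uses the raising direction.
#'
#' @param model a \linkS4class{PleoRegressor}.
#' @param patch input patch \code{H x W x 3}.
#' @param blockIndex which dense block to target; the default is the
#'   penultimate block, whose feature maps retain finer spatial resolution
#'   than the last one.
#' @param direction \code{"predicted"} or \code{"increase"}.
#' @return \code{H x W} saliency matrix in [0, 1].
#' @export
gradCAM <- function(model, patch, blockIndex = NULL,
                    direction = c("predicted", "increase")) {
  direction <- match.arg(direction)
  cfg <- model@config
  layers <- model@layers
  dbIdx <- which(vapply(layers, function(l) l$type == "denseblock",
                        logical(1)))
  if (is.null(blockIndex)) blockIndex <- max(1L, length(dbIdx) - 1L)
  target <- dbIdx[blockIndex]
  X <- patchesToInput(patch, cfg$normMean, cfg$normSd)
  fw <- nnForward(layers, X, cfg$inputSize, cfg$inputSize, 1L,
                  keepActs = TRUE)
  sgn <- if (direction == "increase" || fw$pred >= 2) 1 else -1
  bw <- nnBackward(layers, fw$caches, sgn, 1L, captureAt = target)
  act <- fw$caches[[target]]$out
  grad <- bw$captured
  Hm <- fw$caches[[target]]$H
  Wm <- fw$caches[[target]]$W
  alpha <- rowMeans(grad)
  cam <- as.numeric(t(alpha) %*% act)
  cam <- pmax(cam, 0)
  camM <- matrix(cam, Hm, Wm)
  f <- cfg$inputSize / Hm
  up <- camM[rep(seq_len(Hm), each = f), rep(seq_len(Wm), each = f)]
  m <- max(up)
  if (m <= 0) {
    out <- matrix(0, cfg$inputSize, cfg$inputSize)
    attr(out, "zeroGradient") <- TRUE
    return(out)
  }
  up / m
}
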