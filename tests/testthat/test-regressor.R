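tinyConfig <- function(...) deskConfig(inputSize = 16,
                                       blockLayout = c(1, 1),
                                       growthRate = 4, stemChannels = 6,
                                       ...)

test_that("the regressor honors shape, constant-head and seed contracts", {
  cfg <- deskConfig()
  m <- buildRegressor(cfg)
  p <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- predictPatch(m, p)
  expect_length(out, 1)
  expect_true(out >= 1 && out <= 3)
  # zero the head, set bias 2 -> exactly 2 everywhere
  m2 <- m
  m2@layers[[length(m2@layers)]]$W[] <- 0
  m2@layers[[length(m2@layers)]]$b <- 2
  expect_identical(predictPatch(m2, p), 2)
  expect_identical(predictPatch(m2, array(runif(64 * 64 * 3),
                                          c(64, 64, 3))), 2)
  # identical seeds give identical initial predictions
  m3 <- buildRegressor(cfg)
  expect_identical(predictPatch(m, p), predictPatch(m3, p))
  expect_error(predictPatch(m, array(0, c(32, 32, 3))),
               class = "pleoShapeError")
  expect_error(buildRegressor(deskConfig(inputSize = 60)),
               class = "pleoConfigError")
})

test_that("smooth-L1 matches its closed form and limits", {
  expect_equal(smoothL1(2, 2), 0)
  expect_equal(smoothL1(2.5, 2), 0.125)
  expect_equal(smoothL1(4, 2), 1.5)
  expect_error(smoothL1(1, 1, beta = 0))
  d <- seq(-4, 4, by = 0.1)
  l <- smoothL1(d + 2, 2)
  expect_true(all(l >= 0))
  expect_equal(l, rev(l))                       # symmetric in sign
  expect_true(all(diff(l[d >= 0]) >= 0))        # monotone in |d|
  expect_equal(smoothL1(100, 0), 100 - 0.5)     # L1 - beta/2 tail
})

test_that("augmentation composes dihedral, stain and blur as configured", {
  p <- renderPatch(generateNucleusField(2, 6000, c(0, 0, 48, 48),
                                        "tumor", 0.5, seed = 1),
                   48, 0.5, seed = 2)
  idPar <- augmentParams(dihedral = FALSE, stainAlpha = 0, stainBeta = 0,
                         blurSigmaMax = 0)
  expect_identical(augmentPatch(p, idPar, seed = 3), p)
  dhPar <- augmentParams(dihedral = TRUE, stainAlpha = 0, stainBeta = 0,
                         blurSigmaMax = 0)
  forms <- lapply(1:8, function(k) pleospectrum:::dihedralTransform(p, k))
  out <- augmentPatch(p, dhPar, seed = 4)
  expect_true(any(vapply(forms, identical, logical(1), x = out)))
  # dihedral transforms permute pixels, preserving every intensity
  # statistic a severity cue could use
  expect_equal(sort(as.numeric(out)), sort(as.numeric(p)))
  full <- augmentPatch(p, augmentParams(), seed = 5)
  expect_identical(dim(full), dim(p))
  expect_true(all(full >= 0 & full <= 1))
  expect_identical(augmentPatch(p, augmentParams(), seed = 5), full)
})

test_that("plateau schedule decays and stops after exactly 10 stagnant epochs", {
  st <- plateauInit(1e-3, 0.30, 10, 10)
  st <- plateauUpdate(st, 1.0)     # epoch 1 improves (best)
  decayEpochs <- integer(0); stopEpoch <- NA_integer_
  for (e in 2:12) {
    st <- plateauUpdate(st, 1.0)   # frozen loss
    if (st$decayed) decayEpochs <- c(decayEpochs, e)
    if (st$stop && is.na(stopEpoch)) stopEpoch <- e
  }
  expect_identical(decayEpochs, 11L)
  expect_identical(stopEpoch, 11L)
  expect_equal(st$lr, 1e-3 * 0.7)
  expect_identical(st$bestEpoch, 1L)
})

test_that("an improving loss resets both plateau counters", {
  st <- plateauInit(1e-3, 0.30, 3, 5)
  for (l in c(1, 0.9, 0.95, 0.95, 0.8)) st <- plateauUpdate(st, l)
  expect_equal(st$lr, 1e-3)
  expect_identical(st$sinceBest, 0L)
  expect_identical(st$bestEpoch, 5L)
})

test_that("training runs are reproducible and track history invariants", {
  cfg <- tinyConfig(trainIters = 6, valIters = 2, maxEpochs = 4,
                    batchSize = 4)
  mk <- function(n, seed) withr::with_seed(seed, {
    y <- runif(n, 1, 3)
    x <- array(runif(16 * 16 * 3 * n) * 0.2, c(16, 16, 3, n))
    for (i in seq_len(n)) x[, , , i] <- x[, , , i] + (y[i] - 1) / 4
    list(x = x, y = y)
  })
  tr <- mk(40, 1); va <- mk(12, 2)
  run <- function() trainRegressor(
    buildRegressor(cfg), makePatchSampler(tr$x, tr$y),
    makePatchSampler(va$x, va$y, mode = "cycle"), seed = 7)
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@layers, f2$model@layers)
  h <- f1$history
  expect_true(all(diff(h$lr) <= 0))
  expect_identical(f1$bestEpoch, h$epoch[which.min(h$valLoss)])
  p <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(predictPatch(f1$model, p), predictPatch(f2$model, p))
})

test_that("training aborts on a non-finite loss", {
  cfg <- tinyConfig(trainIters = 2, valIters = 1, maxEpochs = 1,
                    batchSize = 2)
  bad <- function(n) list(x = array(NA_real_, c(16, 16, 3, n)),
                          y = rep(2, n))
  expect_error(trainRegressor(buildRegressor(cfg), bad, bad, seed = 1),
               class = "pleoNaNLossError")
})

test_that("ROI scoring pools patch predictions and flags missing tumor", {
  roi <- smallRoi(2, size = 96, seed = 41)
  dets <- detectCells(slideImage(roi), "oracle", truth = nuclei(roi),
                      spacing = 0.5)
  s <- scoreRoi(constantModel(2), roi, dets, nPatches = 8, seed = 1)
  expect_identical(s, 2)
  noTumor <- new("DetectionSet",
                 detections = transform(detections(dets),
                                        label = "normal"),
                 imageSize = dets@imageSize, spacing = 0.5,
                 sourceId = "t")
  expect_error(scoreRoi(constantModel(2), roi, noTumor, nPatches = 4),
               class = "pleoNoTumorError")
})

test_that("Grad-CAM obeys its contract and flags zero gradients", {
  cfg <- tinyConfig()
  m <- buildRegressor(cfg)
  p <- array(runif(16 * 16 * 3), c(16, 16, 3))
  cam <- gradCAM(m, p)
  expect_identical(dim(cam), c(16L, 16L))
  expect_true(all(cam >= 0 & cam <= 1))
  mz <- m
  mz@layers[[length(mz@layers)]]$W[] <- 0
  mz@layers[[length(mz@layers)]]$b <- 2
  camz <- gradCAM(mz, p)
  expect_true(all(camz == 0))
  expect_true(isTRUE(attr(camz, "zeroGradient")))
})

test_that("model checkpoints round trip through JSON exactly", {
  cfg <- tinyConfig()
  m <- buildRegressor(cfg)
  f <- withr::local_tempfile(fileext = ".json")
  writeModel(m, f)
  m2 <- readModel(f)
  p <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(predictPatch(m2, p), predictPatch(m, p))
  expect_equal(m2@config$blockLayout, cfg$blockLayout)
})

test_that("area-averaging downsampling halves resolution and preserves means", {
  img <- array(runif(32 * 48 * 3), c(32, 48, 3))
  half <- downsampleByTwo(img)
  expect_identical(dim(half), c(16L, 24L, 3L))
  expect_equal(mean(half), mean(img))
  expect_equal(half[1, 1, 1], mean(img[1:2, 1:2, 1]))
  expect_error(downsampleByTwo(array(0, c(3, 4, 3))))
})

test_that("ROI score variance shrinks as more patches are pooled", {
  cfg <- tinyConfig()
  m <- buildRegressor(cfg)   # random weights: patch-to-patch variation
  roi <- generateSlide(invasiveLayout(96, 2), size = 96, spacing = 0.5,
                       seed = 51)
  dets <- detectCells(slideImage(roi), "oracle", truth = nuclei(roi),
                      spacing = 0.5)
  run <- function(np) vapply(1:24, function(s)
    scoreRoi(m, roi, dets, nPatches = np, seed = 200 + s), numeric(1))
  expect_lt(var(run(64)), var(run(8)))
})

test_that("the regressor learns an easy brightness-coded task", {
  cfg <- tinyConfig(trainIters = 30, valIters = 8, maxEpochs = 8,
                    batchSize = 8)
  mk <- function(n, seed) withr::with_seed(seed, {
    y <- runif(n, 1, 3)
    x <- array(runif(16 * 16 * 3 * n, 0, 0.2), c(16, 16, 3, n))
    for (i in seq_len(n)) x[, , , i] <- x[, , , i] + (y[i] - 1) / 2 * 0.5
    list(x = x, y = y)
  })
  tr <- mk(160, 61); va <- mk(48, 62)
  fit <- trainRegressor(buildRegressor(cfg),
                        makePatchSampler(tr$x, tr$y),
                        makePatchSampler(va$x, va$y, mode = "cycle"),
                        seed = 63)
  h <- fit$history
  expect_lt(min(h$valLoss), 0.1 * h$valLoss[1])
})
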