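test_that("tile grids cover the slide with the coverage-completion rule", {
  g1 <- tileGrid(c(512, 512), 512, 448)
  expect_equal(g1@xs, 0)
  expect_equal(g1@ys, 0)
  g2 <- tileGrid(c(512, 576), 512, 448)
  expect_equal(g2@xs, c(0, 64))
  g3 <- tileGrid(c(512, 600), 512, 448)
  expect_equal(g3@xs, c(0, 64, 88))
  expect_equal(max(g3@xs) + 512, 600)
  expect_error(tileGrid(c(512, 512), 512, 512))
  # every pixel covered
  covered <- rep(FALSE, 600)
  for (x in g3@xs) covered[(x + 1):(x + 512)] <- TRUE
  expect_true(all(covered))
})

test_that("constant tile scores are conserved through block pooling", {
  img <- array(0.8, c(1024, 1024, 3))
  dets <- new("DetectionSet",
              detections = data.frame(x = 500, y = 500, label = "tumor",
                                      confidence = 1),
              imageSize = c(1024, 1024), spacing = 0.5, sourceId = "s")
  res <- scoreSlide(constantModel(2), img, dets, tileSize = 512,
                    overlap = 448, block = 64, minTumorCount = 0)
  sc <- blockScores(res$map)
  expect_true(all(sc[!is.na(sc)] == 2))
  expect_identical(res$score, 2)
  # interior blocks are covered by (512/64)^2 = 64 tiles
  cnt <- tileCounts(res$map)
  expect_identical(cnt[8, 8], 64L)
})

test_that("block scores stay within the range of the tile scores", {
  cfg <- deskConfig(inputSize = 16, blockLayout = c(1, 1),
                    growthRate = 4, stemChannels = 6)
  m <- buildRegressor(cfg)
  img <- renderPatch(generateNucleusField(2.5, 8000, c(0, 0, 64, 64),
                                          "tumor", 0.5, seed = 3),
                     64, 0.5, seed = 4)
  dets <- new("DetectionSet",
              detections = data.frame(x = 32, y = 32, label = "tumor",
                                      confidence = 1),
              imageSize = c(64, 64), spacing = 0.5, sourceId = "s")
  res <- scoreSlide(m, img, dets, tileSize = 16, overlap = 8, block = 8,
                    minTumorCount = 0)
  g <- tileGrid(c(64, 64), 16, 8)
  tilesXY <- expand.grid(x = g@xs, y = g@ys)
  ts <- predictPatches(m, lapply(seq_len(nrow(tilesXY)), function(t)
    img[(tilesXY$y[t] + 1):(tilesXY$y[t] + 16),
        (tilesXY$x[t] + 1):(tilesXY$x[t] + 16), , drop = FALSE]))
  sc <- blockScores(res$map)
  expect_gte(min(sc, na.rm = TRUE), min(ts) - 1e-9)
  expect_lte(max(sc, na.rm = TRUE), max(ts) + 1e-9)
})

test_that("a slide with no tumor blocks raises the no-tumor error", {
  img <- array(0.8, c(256, 256, 3))
  dets <- new("DetectionSet",
              detections = data.frame(x = 10, y = 10, label = "normal",
                                      confidence = 1),
              imageSize = c(256, 256), spacing = 0.5, sourceId = "s")
  expect_error(scoreSlide(constantModel(2), img, dets, tileSize = 64,
                          overlap = 32, block = 32, minTumorCount = 1),
               class = "pleoNoTumorError")
})

test_that("quantization uses exact thirds with a closed top bracket", {
  sch <- quantizationScheme(3)
  expect_identical(quantize(1.50, sch), 1L)
  expect_identical(quantize(2.00, sch), 2L)
  expect_identical(quantize(3.00, sch), 3L)
  expect_identical(quantize(5 / 3, sch), 2L)
  expect_error(quantize(3.5, sch))
  # monotone and surjective over a [1,3] sweep, for several p
  for (p in c(2, 3, 5)) {
    s <- seq(1, 3, length.out = 301)
    q <- quantize(s, quantizationScheme(p))
    expect_true(all(diff(q) >= 0))
    expect_setequal(unique(q), seq_len(p))
  }
})

test_that("heatmaps anchor green/yellow/red and vary monotonically", {
  mk <- function(v) new("BlockScoreMap", scores = v,
                        counts = matrix(1L, nrow(v), ncol(v)),
                        tumorMask = matrix(TRUE, nrow(v), ncol(v)),
                        blockSize = 8)
  hm <- renderHeatmap(mk(matrix(2, 2, 2)), upscale = 1)
  expect_equal(unname(hm[1, 1, ]), c(1, 1, 0))      # yellow
  hm13 <- renderHeatmap(mk(matrix(c(1, 3), 1)), upscale = 1)
  expect_equal(unname(hm13[1, 1, ]), c(0, 1, 0))    # green anchor
  expect_equal(unname(hm13[1, 2, ]), c(1, 0, 0))    # red anchor
  ramp <- matrix(seq(1, 3, length.out = 21), 1)
  hr <- renderHeatmap(mk(ramp), upscale = 1)
  expect_true(all(diff(hr[1, , 1]) >= 0))   # red channel rises
  expect_true(all(diff(hr[1, , 2]) <= 0))   # green channel falls
  miss <- mk(matrix(c(2, NA), 1))
  miss@counts[1, 2] <- 0L
  hmm <- renderHeatmap(miss, upscale = 1)
  expect_equal(unname(hmm[1, 2, ]), rep(0.85, 3))
})

test_that("block score maps reject zero-count scored blocks", {
  expect_error(new("BlockScoreMap", scores = matrix(2, 1, 1),
                   counts = matrix(0L, 1, 1),
                   tumorMask = matrix(TRUE, 1, 1), blockSize = 64),
               "zero contributing tiles")
})

test_that("slide outputs round trip through the writers", {
  img <- array(0.8, c(256, 256, 3))
  dets <- new("DetectionSet",
              detections = data.frame(x = c(100, 110, 120),
                                      y = c(100, 110, 120),
                                      label = "tumor", confidence = 1),
              imageSize = c(256, 256), spacing = 0.5, sourceId = "s")
  res <- scoreSlide(constantModel(1.5), img, dets, tileSize = 64,
                    overlap = 32, block = 32, minTumorCount = 1)
  dir <- withr::local_tempdir()
  bsPath <- file.path(dir, "blocks.csv")
  writeBlockScores(res$map, bsPath, slideScore = res$score)
  tab <- read.csv(bsPath)
  expect_true(all(tab$score == 1.5))
  js <- jsonlite::read_json(paste0(bsPath, ".json"))
  expect_equal(js$slideScore, 1.5)
  hmPath <- file.path(dir, "heat.png")
  writeHeatmap(renderHeatmap(res$map), hmPath)
  expect_true(file.exists(hmPath))
  expect_true(file.exists(paste0(hmPath, ".json")))
})
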