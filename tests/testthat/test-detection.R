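test_that("oracle mode passes ground truth through at confidence 1", {
  roi <- smallRoi(2, size = 128, seed = 21)
  tr <- nuclei(roi)
  det <- detectCells(slideImage(roi), "oracle", truth = tr, spacing = 0.5)
  d <- detections(det)
  expect_identical(nrow(d), nrow(tr))
  expect_equal(d$x, tr$x)
  expect_equal(d$y, tr$y)
  expect_identical(d$label, tr$label)
  expect_true(all(d$confidence == 1))
  expect_error(detectCells(slideImage(roi), "oracle"), "truth")
})

test_that("blob mode reaches 0.8 recall at a 10 px radius", {
  matched <- 0L; total <- 0L
  for (s in c(1, 2, 3)) for (k in 1:7) {
    roi <- smallRoi(s, size = 192, seed = 100 * s + k)
    det <- detectCells(slideImage(roi), "blob", spacing = 0.5)
    m <- matchDetections(det, nuclei(roi), radius = 10)
    matched <- matched + m$nMatched
    total <- total + nrow(nuclei(roi))
  }
  expect_gte(matched / total, 0.8)
})

test_that("a background-only image yields an empty DetectionSet", {
  bg <- renderPatch(emptyNucleiDf(), 128, 0.5, seed = 2)
  det <- detectCells(bg, "blob", spacing = 0.5)
  expect_identical(nrow(detections(det)), 0L)
  expect_error(detectCells(bg, "wat"))
})

test_that("density maps are unimodal, linear and mass-conserving", {
  mk <- function(df) new("DetectionSet", detections = df,
                         imageSize = c(128, 128), spacing = 0.5,
                         sourceId = "t")
  one <- mk(data.frame(x = 64, y = 64, label = "tumor", confidence = 1))
  dm <- densityMap(one, sigma = 8, stride = 4, labelFilter = "tumor")
  v <- densityValues(dm)
  peak <- which(v == max(v), arr.ind = TRUE)
  expect_equal(unname((peak[1, ] - 1) * 4), c(64, 64))
  expect_equal(sum(v) * 16, 1, tolerance = 0.01)
  none <- mk(data.frame(x = numeric(0), y = numeric(0),
                        label = character(0), confidence = numeric(0)))
  expect_true(all(densityValues(densityMap(none, 8, 4, "all")) == 0))
  # mirror symmetry: grid columns sit at x = 0..124, so reflection is
  # x -> 124 - x; detections at 28 and 96 are mirror images
  two <- mk(data.frame(x = c(28, 96), y = c(64, 64), label = "tumor",
                       confidence = 1))
  v2 <- densityValues(densityMap(two, sigma = 8, stride = 4,
                                 labelFilter = "tumor"))
  expect_lt(max(abs(v2 - v2[, rev(seq_len(ncol(v2)))])), 1e-6)
  # linearity in detections
  a <- mk(data.frame(x = c(20, 50), y = c(30, 70), label = "tumor",
                     confidence = 1))
  b <- mk(data.frame(x = 90, y = 100, label = "tumor", confidence = 1))
  ab <- mk(rbind(detections(a), detections(b)))
  expect_equal(densityValues(densityMap(ab, 8, 4, "tumor")),
               densityValues(densityMap(a, 8, 4, "tumor")) +
                 densityValues(densityMap(b, 8, 4, "tumor")))
})

test_that("patch centres follow the density mass", {
  df <- data.frame(x = runif(45, 130, 250), y = runif(45, 130, 250),
                   label = "tumor", confidence = 1)
  df <- rbind(df, data.frame(x = runif(5, 0, 120), y = runif(5, 0, 120),
                             label = "tumor", confidence = 1))
  dets <- new("DetectionSet", detections = df, imageSize = c(256, 256),
              spacing = 0.5, sourceId = "t")
  dm <- densityMap(dets, sigma = 8, stride = 4, labelFilter = "tumor")
  ctr <- samplePatchCenters(dm, 500, 16, seed = 3)
  inQuad <- mean(ctr$x >= 128 & ctr$y >= 128)
  expect_gte(inQuad, 0.8)
  expect_true(all(ctr$x >= 8 & ctr$x <= 248 & ctr$y >= 8 & ctr$y <= 248))
})

test_that("uniform density yields uniform centres (chi-square alpha 0.01)", {
  v <- matrix(1, 33, 33)
  dm <- new("DensityMap", values = v, stride = 4, sigma = 8,
            labelFilter = "all", imageSize = c(128, 128))
  ctr <- samplePatchCenters(dm, 2000, 32, seed = 4)
  # valid centre range [16, 112]; bin into a 4x4 grid
  bx <- cut(ctr$x, seq(16, 112, length.out = 5), include.lowest = TRUE)
  by <- cut(ctr$y, seq(16, 112, length.out = 5), include.lowest = TRUE)
  p <- suppressWarnings(chisq.test(table(bx, by))$p.value)
  expect_gt(p, 0.01)
})

test_that("an all-zero density map refuses to sample", {
  dm <- new("DensityMap", values = matrix(0, 33, 33), stride = 4,
            sigma = 8, labelFilter = "tumor", imageSize = c(128, 128))
  expect_error(samplePatchCenters(dm, 10, 32, seed = 1),
               class = "pleoNoTumorError")
})

test_that("tumor block masks count and threshold monotonically", {
  df <- data.frame(x = c(rep(10, 5), 100), y = c(rep(10, 5), 100),
                   label = c(rep("tumor", 5), "normal"), confidence = 1)
  dets <- new("DetectionSet", detections = df, imageSize = c(128, 128),
              spacing = 0.5, sourceId = "t")
  m3 <- tumorBlockMask(dets, block = 64, minCount = 3)
  expect_true(m3[1, 1])
  expect_identical(sum(m3), 1L)
  allNormal <- new("DetectionSet",
                   detections = transform(df, label = "normal"),
                   imageSize = c(128, 128), spacing = 0.5, sourceId = "t")
  expect_false(any(tumorBlockMask(allNormal, 64, 1)))
  m1 <- tumorBlockMask(dets, block = 64, minCount = 1)
  m5 <- tumorBlockMask(dets, block = 64, minCount = 5)
  expect_true(all(!m5 | m1))  # true-block set shrinks with minCount
})

test_that("detection CSV round trips bit-exactly", {
  roi <- smallRoi(2, size = 96, seed = 31)
  det <- detectCells(slideImage(roi), "blob", spacing = 0.5,
                     sourceId = "roi31")
  f <- withr::local_tempfile(fileext = ".csv")
  writeDetections(det, f)
  back <- readDetections(f)
  expect_identical(detections(back), detections(det))
  expect_identical(back@sourceId, "roi31")
  expect_equal(back@imageSize, det@imageSize)
})
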