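test_that("nucleus fields are deterministic under a fixed seed", {
  a <- generateNucleusField(2, 6000, c(0, 0, 128, 128), "tumor", 0.5,
                            seed = 11)
  b <- generateNucleusField(2, 6000, c(0, 0, 128, 128), "tumor", 0.5,
                            seed = 11)
  expect_identical(a, b)
  c <- generateNucleusField(2, 6000, c(0, 0, 128, 128), "tumor", 0.5,
                            seed = 12)
  expect_false(identical(a, c))
})

test_that("morphology summaries are monotone in severity", {
  grid <- c(1, 1.5, 2, 2.5, 3)
  stats <- t(vapply(grid, function(s) {
    nf <- do.call(rbind, lapply(1:6, function(k)
      generateNucleusField(s, 6000, c(0, 0, 256, 256), "tumor", 0.5,
                           seed = 40 + k)))
    area <- pi * nf$major * nf$minor
    c(meanArea = mean(area), cvArea = sd(area) / mean(area),
      meanEcc = mean(sqrt(1 - (nf$minor / nf$major)^2)),
      meanContrast = mean(nf$contrast))
  }, numeric(4)))
  for (j in 1:4) expect_true(all(diff(stats[, j]) > 0))
})

test_that("area CV at s=3 exceeds s=1 across seed ensemble", {
  cv <- function(s, seed) {
    nf <- generateNucleusField(s, 6000, c(0, 0, 256, 256), "tumor", 0.5,
                               seed = seed)
    a <- pi * nf$major * nf$minor
    sd(a) / mean(a)
  }
  cv1 <- vapply(1:20, function(k) cv(1, k), numeric(1))
  cv3 <- vapply(1:20, function(k) cv(3, k), numeric(1))
  expect_true(all(cv3 > cv1))
})

test_that("a region too small to hold a nucleus warns and returns empty", {
  expect_warning(
    nf <- generateNucleusField(2, 10, c(0, 0, 4, 4), "tumor", 0.5,
                               seed = 1),
    class = "pleoEmptyRegionWarning")
  expect_identical(nrow(nf), 0L)
})

test_that("rendered patches honor the shape contract and determinism", {
  img <- renderPatch(emptyNucleiDf(), 512, 0.5, seed = 1)
  expect_identical(dim(img), c(512L, 512L, 3L))
  nf <- generateNucleusField(2, 6000, c(0, 0, 96, 96), "tumor", 0.5,
                             seed = 5)
  a <- renderPatch(nf, 96, 0.5, seed = 7)
  b <- renderPatch(nf, 96, 0.5, seed = 7)
  expect_identical(a, b)
})

test_that("a nucleus-free render matches the configured stain background", {
  st <- stainParams()
  img <- renderPatch(emptyNucleiDf(), 256, 0.5, stain = st, seed = 3)
  sv <- pleospectrum:::stainVectors()
  expected <- exp(-st$backgroundOD * sv["eosin", ])
  for (c in 1:3)
    expect_lt(abs(mean(img[, , c]) - expected[c]), 3 * st$noiseSd)
  # medians are robust to the one-sided clipping at the white point
  for (c in 1:3)
    expect_lt(abs(median(img[, , c]) - expected[c]), 3 * st$noiseSd / 10)
})

test_that("ROI pairs have the documented geometry and morphology contrast", {
  pair <- generateRoiPair(3, seed = 2, size = 2560, spacing = 0.25)
  expect_identical(dim(slideImage(pair$tumor)), c(2560L, 2560L, 3L))
  expect_identical(dim(slideImage(pair$normal)), c(2560L, 2560L, 3L))
  tArea <- with(nuclei(pair$tumor), mean(pi * major * minor))
  nArea <- with(nuclei(pair$normal), mean(pi * major * minor))
  expect_gt(tArea, nArea)
  expect_true(all(nuclei(pair$tumor)$label == "tumor"))
  expect_true(all(nuclei(pair$normal)$label == "normal"))
})

test_that("slides respect layout severity, benign forcing and determinism", {
  lay <- data.frame(x0 = c(0, 136), y0 = c(0, 0), x1 = c(128, 256),
                    y1 = c(128, 128), label = c("invasive", "invasive"),
                    severity = c(1, 3))
  sl <- generateSlide(lay, size = c(128, 256), spacing = 0.5, seed = 4)
  sev <- severityField(sl)@values
  expect_setequal(unique(sev[!is.na(sev)]), c(1, 3))
  lay2 <- data.frame(x0 = 0, y0 = 0, x1 = 128, y1 = 128,
                     label = "benign", severity = NA)
  sl2 <- generateSlide(lay2, size = 128, spacing = 0.5, seed = 4)
  expect_true(all(nuclei(sl2)$label == "normal"))
  expect_identical(slideImage(generateSlide(lay, size = c(128, 256),
                                            spacing = 0.5, seed = 4)),
                   slideImage(sl))
})

test_that("overlapping layout regions are rejected", {
  lay <- data.frame(x0 = c(0, 64), y0 = c(0, 0), x1 = c(128, 160),
                    y1 = c(128, 128), label = "invasive", severity = 2)
  expect_error(generateSlide(lay, size = c(128, 192), spacing = 0.5),
               class = "pleoLayoutError")
})

test_that("slide validity rejects tumor nuclei inside benign regions", {
  sl <- smallRoi(1, size = 64, seed = 1)
  bad <- nuclei(sl)
  bad$label <- "tumor"
  regions <- regionLayout(sl)
  regions$label <- "benign"
  expect_error(new("SyntheticSlide", image = slideImage(sl),
                   spacing = 0.5, nuclei = bad,
                   severity = severityField(sl), regions = regions),
               "benign")
})
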