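test_that("reference scores are panel means with exact hand values", {
  p <- PanelScores(matrix(rep(2L, 10), 1))
  expect_equal(unname(referenceScore(p, 1)), 2)
  p2 <- PanelScores(matrix(c(1L, 2L, 2L), 1))
  expect_equal(unname(referenceScore(p2, 1)), 5 / 3, tolerance = 1e-9)
  p3 <- PanelScores(matrix(c(1L, 3L), 1))
  expect_equal(unname(referenceScore(p3, 1)), 2)
  expect_error(referenceScore(p3, "nope"), class = "pleoLookupError")
})

test_that("reference scores are rater-permutation invariant and bounded", {
  set.seed(8)
  for (k in 1:20) {
    s <- matrix(sample(1:3, 40, replace = TRUE), 4, 10)
    r1 <- referenceScore(PanelScores(s))
    r2 <- referenceScore(PanelScores(s[, sample(10)]))
    expect_equal(unname(r1), unname(r2))
    expect_true(all(r1 >= apply(s, 1, min) & r1 <= apply(s, 1, max)))
  }
})

test_that("majority vote follows the documented tie-breaking cascade", {
  expect_identical(majorityVote(c(2, 2, 2)), 2L)
  expect_identical(majorityVote(c(1, 2, 2)), 2L)
  # confidence sums 6 vs 2 break the 2-2 tie toward category 1
  expect_identical(
    majorityVote(c(1, 1, 2, 2), c("certain", "certain", "not_certain",
                                  "not_certain")), 1L)
  # residual tie: nearest the panel mean (2.0 -> category 2)
  expect_identical(majorityVote(c(1, 2, 2, 3, 1, 3)), 2L)
  # full tie at equal distance: lower category
  expect_identical(majorityVote(c(1, 2)), 1L)
  expect_error(majorityVote(integer(0)))
  # output is always one of the scored categories
  set.seed(9)
  for (k in 1:50) {
    sc <- sample(1:3, sample(1:9, 1), replace = TRUE)
    expect_true(majorityVote(sc) %in% sc ||
                  majorityVote(sc) %in% unique(sc))
  }
})

test_that("leave-one-out majority excludes exactly the compared rater", {
  s <- matrix(rep(2L, 30), 3, 10)
  p <- PanelScores(s)
  expect_true(all(leaveOneOutMajority(p, 1) == 2L))
  p2 <- PanelScores(matrix(c(1L, 1L, 2L), 1,
                           dimnames = list("i", c("A", "B", "C"))))
  expect_identical(unname(leaveOneOutMajority(p2, "C")), 1L)
  # [1,2,2] minus B leaves the {1,2} tie for the documented cascade
  p3 <- PanelScores(matrix(c(1L, 2L, 2L), 1,
                           dimnames = list("i", c("A", "B", "C"))))
  expect_identical(unname(leaveOneOutMajority(p3, "B")), 1L)
  p1 <- PanelScores(matrix(1L, 1, 1))
  expect_error(leaveOneOutMajority(p1, 1))
})

test_that("quadratic kappa hits its exact anchor values", {
  expect_equal(quadraticKappa(c(1, 2, 3, 2, 1), c(1, 2, 3, 2, 1)), 1)
  expect_equal(quadraticKappa(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_warning(k <- quadraticKappa(c(1, 1, 1), c(1, 1, 1)),
                 class = "pleoUndefinedKappaWarning")
  expect_true(is.na(k))
})

test_that("quadratic kappa is symmetric", {
  set.seed(10)
  for (k in 1:25) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(suppressWarnings(quadraticKappa(a, b)),
                 suppressWarnings(quadraticKappa(b, a)))
  }
})

test_that("pairwise kappa reports have the right shape and perfect cases", {
  s <- matrix(sample(1:3, 60, replace = TRUE), 20, 3)
  p <- PanelScores(cbind(s, s[, 1]))
  kr <- pairwiseKappaReport(p)
  expect_equal(unname(kr$kappa[1, 4]), 1)
  # zero-noise simulated panel: all defined pairwise kappas are 1
  truth <- seq(1, 3, length.out = 30)
  pz <- simulatePanel(truth, zeroNoisePanel(10), seed = 1)
  kz <- pairwiseKappaReport(pz)$kappa
  off <- kz[upper.tri(kz)]
  expect_true(all(is.na(off) | abs(off - 1) < 1e-12))
  # panel + extra rater: (R+1)^2 cells and R+1 majority entries
  extra <- sample(1:3, 20, replace = TRUE)
  kr2 <- pairwiseKappaReport(PanelScores(s), extraRater = extra)
  expect_identical(dim(kr2$kappa), c(4L, 4L))
  expect_length(kr2$majority, 4L)
  expect_length(kr2$meanKappa, 4L)
})

test_that("simulated panels quantize bias and noise as specified", {
  p <- simulatePanel(rep(1.2, 5), zeroNoisePanel(4), seed = 2)
  expect_true(all(scoreMatrix(p) == 1L))
  pb <- simulatePanel(2.0, data.frame(rater = "P_1", bias = 0.8,
                                      noiseSd = 0), seed = 2)
  expect_identical(unname(scoreMatrix(pb)[1, 1]), 3L)
  truth <- withr::with_seed(99, runif(10, 1, 3))
  b <- simulatePanel(truth, raterPanel(5), seed = 3)
  d <- simulatePanel(truth, raterPanel(5), seed = 3)
  expect_identical(scoreMatrix(b), scoreMatrix(d))
  expect_identical(confidenceMatrix(b), confidenceMatrix(d))
})

test_that("panel CSV round trips scores and confidences", {
  p <- simulatePanel(runif(8, 1, 3), raterPanel(4), seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  writePanel(p, f)
  q <- readPanel(f)
  expect_identical(scoreMatrix(q)[itemNames(p), raterNames(p)],
                   scoreMatrix(p))
  expect_identical(confidenceMatrix(q)[itemNames(p), raterNames(p)],
                   confidenceMatrix(p))
})
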