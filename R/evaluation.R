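#' Regression metrics: MAE, MSE, explained variance
#'
#' \code{MAE = mean(|e|)}, \code{MSE = mean(e^2)},
#' \code{EV = 1 - Var(e)/Var(reference)} with \code{e = prediction -
#' reference}. A constant reference has zero variance, making EV undefined;
#' this is flagged (\code{NA} plus a warning) rather than silently mapped
#' to a number.
#'
#' @param predictions,references equal-length finite numeric vectors.
#' @return list with \code{mae}, \code{mse}, \code{ev}, \code{n}.
#' @export
regressionMetrics <- function(predictions, references) {
  stopIfNot(length(predictions) == length(references) &&
            length(predictions) >= 2, "need equal lengths >= 2")
  stopIfNot(all(is.finite(predictions)) && all(is.finite(references)),
            "inputs must be finite")
  e <- predictions - references
  ev <- if (var(references) == 0) {
    warning(warningCondition("EV undefined: zero reference variance",
                             class = c("pleoUndefinedEVWarning", "warning")))
    NA_real_
  } else 1 - var(e) / var(references)
  list(mae = mean(abs(e)), mse = mean(e^2), ev = ev,
       n = length(predictions))
}

#' Resampled metrics over repeated evaluation sets
#'
#' Draws \code{nSets} evaluation sets of \code{nPerSet} patches from a
#' held-out pool (disjoint sets when the pool is large enough, otherwise
#' sampling with replacement, flagged in the result), scores them with the
#' model, and reports the mean and standard deviation of each metric
#' across sets.
#'
#' @param model patch scorer.
#' @param x patch pool, array \code{H x W x 3 x N}.
#' @param y reference scores of length N.
#' @param nPerSet,nSets set size and number of sets.
#' @param seed optional integer seed.
#' @return list with \code{mean}, \code{sd} (per-metric vectors),
#'   \code{perSet} (data.frame) and \code{replacement} flag.
#' @export
resampledMetrics <- function(model, x, y, nPerSet = 1000, nSets = 4,
                             seed = NULL) {
  N <- dim(x)[4]
  withSeed(seed, {
    replacement <- N < nPerSet * nSets
    idx <- if (replacement)
      lapply(seq_len(nSets), function(s) sample.int(N, nPerSet,
                                                    replace = TRUE))
    else {
      perm <- sample.int(N)
      lapply(seq_len(nSets), function(s)
        perm[(s - 1) * nPerSet + seq_len(nPerSet)])
    }
    per <- do.call(rbind, lapply(idx, function(ii) {
      m <- regressionMetrics(
        predictPatches(model, x[, , , ii, drop = FALSE]), y[ii])
      data.frame(mae = m$mae, mse = m$mse, ev = m$ev)
    }))
    list(mean = colMeans(per), sd = apply(per, 2, sd), perSet = per,
         replacement = replacement)
  })
}

#' Signed score-difference table
#'
#' Histogram of the signed category differences \code{a - b} over
#' \{-2, ..., +2\} for three-category scores; the counts always sum to the
#' number of items.
#'
#' @param a,b equal-length category vectors in 1..3.
#' @return named integer vector of counts for differences -2..2.
#' @export
scoreDifferenceTable <- function(a, b) {
  stopIfNot(length(a) == length(b), "vectors must have equal length")
  stopIfNot(all(a %in% 1:3) && all(b %in% 1:3), "categories must be 1..3")
  d <- factor(a - b, levels = -2:2)
  out <- table(d)
  stats::setNames(as.integer(out), names(out))
}

#' ROI-study experiment configuration
#'
#' Desk-scale mirror of the ROI study: 125 tumor ROIs from 39 slide
#' groups, split slide-wise into 52 training / 28 validation / 45
#' evaluation ROIs; a 10-rater simulated panel provides the average-pooled
#' continuous reference scores the regressor is trained on.
#'
#' @param nRois,nSlides ROI and slide-group counts.
#' @param splitRois target ROI counts (train, val, test).
#' @param roiSize ROI edge length in pixels.
#' @param spacing micrometres per pixel.
#' @param patchesPerTrainRoi,patchesPerValRoi,patchesPerTestRoi patches
#'   sampled per ROI for the three partitions.
#' @param raters rater panel, see \code{\link{raterPanel}}.
#' @param regressor regressor configuration, see \code{\link{deskConfig}}.
#' @param aiMode \code{"train"} fits the regressor; \code{"oracle"} scores
#'   every item with its generating severity (closed-loop check).
#' @param nRoiPatches patches per ROI for ROI-level scoring.
#' @export
roiExperimentConfig <- function(nRois = 125, nSlides = 39,
                                splitRois = c(52, 28, 45), roiSize = 320,
                                spacing = 0.5, patchesPerTrainRoi = 58,
                                patchesPerValRoi = 12,
                                patchesPerTestRoi = 12,
                                raters = raterPanel(10),
                                regressor = deskConfig(),
                                aiMode = c("train", "oracle"),
                                nRoiPatches = 16) {
  list(nRois = nRois, nSlides = nSlides, splitRois = splitRois,
       roiSize = roiSize, spacing = spacing,
       patchesPerTrainRoi = patchesPerTrainRoi,
       patchesPerValRoi = patchesPerValRoi,
       patchesPerTestRoi = patchesPerTestRoi, raters = raters,
       regressor = regressor, aiMode = match.arg(aiMode),
       nRoiPatches = nRoiPatches)
}

# Sample density-guided patches from a generated ROI; returns the patch
# array and per-patch generating severity.
samplePatchesFromRoi <- function(roi, n, patchSize) {
  dets <- detectCells(slideImage(roi), "oracle", truth = nuclei(roi),
                      spacing = spacing(roi))
  dm <- densityMap(dets, sigma = 16, stride = 4, labelFilter = "tumor")
  centers <- samplePatchCenters(dm, n, patchSize)
  img <- slideImage(roi)
  arr <- array(0, c(patchSize, patchSize, 3, n))
  for (i in seq_len(n))
    arr[, , , i] <- cropImage(img, round(centers$x[i] - patchSize / 2),
                              round(centers$y[i] - patchSize / 2),
                              patchSize, patchSize)
  arr
}

#' Run the ROI-study experiment on synthetic data
#'
#' Generates ROIs with known severities grouped into slide-like groups,
#' simulates the rater panel and builds average-pooled reference scores,
#' trains the regressor on density-sampled patches from the training ROIs
#' (slide-wise split), then evaluates: patch-level regression metrics and
#' Spearman correlation against the generating severity on held-out
#' patches, ROI-level scores, and the pairwise quadratic-kappa report of
#' the panel plus the quantized AI scores (with the leave-one-out majority
#' column).
#'
#' @param config list from \code{\link{roiExperimentConfig}}.
#' @param seed integer seed for the whole experiment.
#' @param verbose print training progress?
#' @return report list; see Details.
#' @details The report contains \code{split} (per-ROI partition and
#'   severity), \code{panel}, \code{references}, \code{model},
#'   \code{history}, \code{patchMetrics} (incl. \code{spearman}),
#'   \code{roiScores} (per test ROI: severity, reference, AI score,
#'   quantized categories) and \code{kappaReport}.
#' @export
runRoiExperiment <- function(config = roiExperimentConfig(), seed = 1,
                             verbose = FALSE) {
  withSeed(seed, {
    nR <- config$nRois
    severities <- runif(nR, 1, 3)
    slideOf <- sort(rep_len(seq_len(config$nSlides), nR))
    # slide-wise split with ROI counts close to the target proportions
    slidePerm <- sample.int(config$nSlides)
    target <- cumsum(config$splitRois)
    part <- integer(nR)
    roiCum <- 0L; si <- 1L
    for (s in slidePerm) {
      members <- which(slideOf == s)
      roiCum <- roiCum + length(members)
      part[members] <- si
      if (si < 3L && roiCum >= target[si]) si <- si + 1L
    }
    panel <- simulatePanel(severities, config$raters)
    refs <- referenceScore(panel)
    ps <- config$regressor$inputSize
    drawPool <- function(ids, perRoi) {
      xs <- vector("list", length(ids)); ys <- vector("list", length(ids))
      for (k in seq_along(ids)) {
        i <- ids[k]
        roi <- generateSlide(
          data.frame(x0 = 0, y0 = 0, x1 = config$roiSize,
                     y1 = config$roiSize, label = "invasive",
                     severity = severities[i]),
          size = config$roiSize, spacing = config$spacing)
        xs[[k]] <- samplePatchesFromRoi(roi, perRoi, ps)
        ys[[k]] <- rep(i, perRoi)
      }
      list(x = array(unlist(xs, use.names = FALSE),
                     dim = c(ps, ps, 3, length(ids) * perRoi)),
           roi = unlist(ys))
    }
    trainIds <- which(part == 1); valIds <- which(part == 2)
    testIds <- which(part == 3)
    trainPool <- drawPool(trainIds, config$patchesPerTrainRoi)
    valPool <- drawPool(valIds, config$patchesPerValRoi)
    testPool <- drawPool(testIds, config$patchesPerTestRoi)
    if (config$aiMode == "train") {
      trainSrc <- makePatchSampler(trainPool$x, refs[trainPool$roi],
                                   mode = "random",
                                   augment = augmentParams())
      valSrc <- makePatchSampler(valPool$x, refs[valPool$roi],
                                 mode = "cycle")
      fit <- trainRegressor(buildRegressor(config$regressor),
                            trainSrc, valSrc, verbose = verbose)
      model <- fit$model; history <- fit$history
      patchPred <- predictPatches(model, testPool$x)
    } else {
      model <- NULL; history <- NULL
      patchPred <- severities[testPool$roi]
    }
    patchSev <- severities[testPool$roi]
    pm <- regressionMetrics(patchPred, patchSev)
    pm$spearman <- cor(patchPred, patchSev, method = "spearman")
    aiRoi <- vapply(testIds, function(i) {
      if (config$aiMode == "oracle") return(severities[i])
      roi <- generateSlide(
        data.frame(x0 = 0, y0 = 0, x1 = config$roiSize,
                   y1 = config$roiSize, label = "invasive",
                   severity = severities[i]),
        size = config$roiSize, spacing = config$spacing)
      dets <- detectCells(slideImage(roi), "oracle", truth = nuclei(roi),
                          spacing = config$spacing)
      scoreRoi(model, roi, dets, nPatches = config$nRoiPatches)
    }, numeric(1))
    roiScores <- data.frame(
      roi = testIds, severity = severities[testIds],
      reference = refs[testIds], ai = aiRoi,
      aiCat = quantize(aiRoi), truthCat = quantize(severities[testIds]),
      refCat = quantize(refs[testIds]))
    testPanel <- PanelScores(scoreMatrix(panel)[testIds, , drop = FALSE],
                             if (length(confidenceMatrix(panel)))
                               confidenceMatrix(panel)[testIds, ,
                                                       drop = FALSE]
                             else NULL)
    kr <- pairwiseKappaReport(testPanel, extraRater = roiScores$aiCat)
    kappaTruth <- suppressWarnings(
      quadraticKappa(roiScores$aiCat, roiScores$truthCat))
    list(split = data.frame(roi = seq_len(nR), slide = slideOf,
                            severity = severities,
                            partition = c("train", "val",
                                          "test")[part]),
         panel = panel, references = refs, model = model,
         history = history, patchMetrics = pm, roiScores = roiScores,
         kappaReport = kr, kappaTruth = kappaTruth,
         testPool = testPool, severities = severities)
  })
}

#' Slide-study experiment configuration
#'
#' Desk-scale mirror of the slide study: homogeneous (or layered)
#' synthetic slides scored end-to-end by overlapping-tile inference and
#' compared against a 4-rater simulated panel.
#'
#' @param severities per-slide severities.
#' @param slideSize slide edge length in pixels.
#' @param spacing micrometres per pixel.
#' @param tileOverlapFrac tile overlap as a fraction of the tile size.
#' @param block block edge length in pixels.
#' @param minTumorCount tumor-mask threshold (detections per block).
#' @param detector \code{"oracle"} or \code{"blob"}.
#' @param raters rater panel for the comparison.
#' @param renderHeatmaps render a heatmap for each slide?
#' @export
slideExperimentConfig <- function(severities = rep(c(1, 2, 3), each = 4),
                                  slideSize = 512, spacing = 0.5,
                                  tileOverlapFrac = 0.5, block = 32,
                                  minTumorCount = 3,
                                  detector = c("oracle", "blob"),
                                  raters = raterPanel(4),
                                  renderHeatmaps = FALSE) {
  list(severities = severities, slideSize = slideSize, spacing = spacing,
       tileOverlapFrac = tileOverlapFrac, block = block,
       minTumorCount = minTumorCount, detector = match.arg(detector),
       raters = raters, renderHeatmaps = renderHeatmaps)
}

#' Run the slide-study experiment on synthetic data
#'
#' Generates one homogeneous synthetic slide per requested severity,
#' scores each with \code{\link{scoreSlide}} (tile size = the model input,
#' overlap per config), quantizes the slide scores, and compares them
#' against a simulated rater panel via score-difference tables and the
#' pairwise quadratic-kappa report.
#'
#' @param model trained patch scorer.
#' @param config list from \code{\link{slideExperimentConfig}}.
#' @param seed integer seed.
#' @return report list with \code{slides} (per-slide severity, score,
#'   category, truth category), \code{panel}, \code{differences} (one
#'   score-difference table per rater), \code{kappaReport} and
#'   \code{heatmaps}.
#' @export
runSlideExperiment <- function(model, config = slideExperimentConfig(),
                               seed = 1) {
  withSeed(seed, {
    sev <- config$severities
    tileSize <- if (is(model, "ConstantModel")) 64L else
      model@config$inputSize
    overlap <- round(tileSize * config$tileOverlapFrac)
    scores <- numeric(length(sev))
    heatmaps <- vector("list", length(sev))
    for (i in seq_along(sev)) {
      slide <- generateSlide(
        data.frame(x0 = 0, y0 = 0, x1 = config$slideSize,
                   y1 = config$slideSize, label = "invasive",
                   severity = sev[i]),
        size = config$slideSize, spacing = config$spacing)
      dets <- if (config$detector == "oracle")
        detectCells(slideImage(slide), "oracle", truth = nuclei(slide),
                    spacing = config$spacing)
      else detectCells(slideImage(slide), "blob",
                       spacing = config$spacing)
      res <- scoreSlide(model, slide, dets, tileSize = tileSize,
                        overlap = overlap, block = config$block,
                        minTumorCount = config$minTumorCount)
      scores[i] <- res$score
      if (config$renderHeatmaps) heatmaps[[i]] <- renderHeatmap(res$map)
    }
    cats <- quantize(scores)
    truthCats <- quantize(sev)
    panel <- simulatePanel(sev, config$raters)
    diffs <- lapply(raterNames(panel), function(r)
      scoreDifferenceTable(cats, scoreMatrix(panel)[, r]))
    names(diffs) <- raterNames(panel)
    kr <- tryCatch(pairwiseKappaReport(panel, extraRater = cats),
                   error = function(e) NULL)
    list(slides = data.frame(severity = sev, score = scores,
                             category = cats, truthCat = truthCats),
         panel = panel, differences = diffs, kappaReport = kr,
         heatmaps = heatmaps)
  })
}
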