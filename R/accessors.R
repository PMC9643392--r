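#' Accessors for pleospectrum data containers
#'
#' Slot accessors for the S4 containers: \code{spacing} (micrometres per
#' pixel), \code{nuclei} (ground-truth nucleus records), \code{slideImage},
#' \code{severityField}, \code{regionLayout}, \code{detections},
#' \code{scoreMatrix} / \code{confidenceMatrix} / \code{itemNames} /
#' \code{raterNames} (rater panels), \code{blockScores} / \code{tileCounts} /
#' \code{tumorMask} / \code{blockSize} (block score maps), and
#' \code{densityValues}.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("spacing", "SyntheticSlide", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "DetectionSet", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "SeverityField", function(x) x@spacing)
#' @rdname accessors
setMethod("nuclei", "SyntheticSlide", function(x) x@nuclei)
#' @rdname accessors
setMethod("slideImage", "SyntheticSlide", function(x) x@image)
#' @rdname accessors
setMethod("severityField", "SyntheticSlide", function(x) x@severity)
#' @rdname accessors
setMethod("regionLayout", "SyntheticSlide", function(x) x@regions)
#' @rdname accessors
setMethod("detections", "DetectionSet", function(x) x@detections)
#' @rdname accessors
setMethod("scoreMatrix", "PanelScores", function(x) x@scores)
#' @rdname accessors
setMethod("confidenceMatrix", "PanelScores", function(x) x@confidence)
#' @rdname accessors
setMethod("itemNames", "PanelScores", function(x) rownames(x@scores))
#' @rdname accessors
setMethod("raterNames", "PanelScores", function(x) colnames(x@scores))
#' @rdname accessors
setMethod("blockScores", "BlockScoreMap", function(x) x@scores)
#' @rdname accessors
setMethod("tileCounts", "BlockScoreMap", function(x) x@counts)
#' @rdname accessors
setMethod("tumorMask", "BlockScoreMap", function(x) x@tumorMask)
#' @rdname accessors
setMethod("blockSize", "BlockScoreMap", function(x) x@blockSize)
#' @rdname accessors
setMethod("blockSize", "SeverityField", function(x) x@blockSize)
#' @rdname accessors
setMethod("densityValues", "DensityMap", function(x) x@values)

setMethod("show", "SyntheticSlide", function(object) {
  d <- dim(object@image)
  cat(sprintf(
    "SyntheticSlide: %d x %d px @ %.3g um/px, %d nuclei, %d region(s)\n",
    d[1], d[2], object@spacing, nrow(object@nuclei), nrow(object@regions)))
})

setMethod("show", "DetectionSet", function(object) {
  d <- object@detections
  cat(sprintf(
    "DetectionSet '%s': %d detections (%d tumor, %d normal) on %d x %d px\n",
    object@sourceId, nrow(d), sum(d$label == "tumor"),
    sum(d$label == "normal"), object@imageSize[1], object@imageSize[2]))
})

setMethod("show", "PanelScores", function(object) {
  cat(sprintf("PanelScores: %d items x %d raters%s\n",
              nrow(object@scores), ncol(object@scores),
              if (length(object@confidence)) " (with confidences)" else ""))
})

setMethod("show", "BlockScoreMap", function(object) {
  s <- object@scores
  cat(sprintf(
    "BlockScoreMap: %d x %d blocks of %d px, %d scored, %d tumor blocks\n",
    nrow(s), ncol(s), as.integer(object@blockSize), sum(!is.na(s)),
    sum(object@tumorMask)))
})

setMethod("show", "PleoRegressor", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@layers, function(l) {
    if (l$type == "denseblock")
      sum(vapply(l$convs, function(cv) length(cv$W) + length(cv$b),
                 numeric(1)))
    else length(l$W) + length(l$b)
  }, numeric(1)))
  cat(sprintf(
    "PleoRegressor: input %d px @ %.3g um/px, blocks [%s], growth %d, %d parameters\n",
    cfg$inputSize, cfg$inputSpacing,
    paste(cfg$blockLayout, collapse = ","), cfg$growthRate, as.integer(np)))
})

setMethod("show", "ConstantModel", function(object)
  cat(sprintf("ConstantModel: always predicts %.4g\n", object@value)))

setMethod("show", "DensityMap", function(object) {
  cat(sprintf(
    "DensityMap (%s): %d x %d grid, stride %d px, sigma %.3g px, mass %.2f\n",
    object@labelFilter, nrow(object@values), ncol(object@values),
    as.integer(object@stride), object@sigma,
    sum(object@values) * object@stride^2))
})

setMethod("show", "TileGrid", function(object) {
  cat(sprintf(
    "TileGrid: %d x %d tiles of %d px (overlap %d) on %d x %d px\n",
    length(object@ys), length(object@xs), as.integer(object@tileSize),
    as.integer(object@overlap), object@imageSize[1], object@imageSize[2]))
})

setMethod("show", "QuantizationScheme", function(object) {
  cat(sprintf("QuantizationScheme: %d brackets, edges %s\n", object@p,
              paste(sprintf("%.4g", object@edges), collapse = " | ")))
})
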