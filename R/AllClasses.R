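#' @import methods
#' @importFrom stats rnorm runif rpois rlnorm var cor sd quantile
#' @importFrom utils head tail read.csv
#' @useDynLib pleospectrum, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Per-block ground-truth severity field
#'
#' A grid of continuous pleomorphism severities in [1, 3], piecewise constant
#' over the regions of a synthetic slide, sampled at a fixed block resolution.
#' Blocks outside any tissue region are \code{NA}.
#'
#' @slot values numeric matrix of severities (rows = y blocks, cols = x
#'   blocks); \code{NA} marks background.
#' @slot blockSize block edge length in pixels.
#' @slot spacing physical sampling resolution, micrometres per pixel.
#' @export
setClass("SeverityField",
  representation(values = "matrix", blockSize = "numeric",
                 spacing = "numeric"),
  validity = function(object) {
    v <- object@values
    if (any(!is.na(v) & (v < 1 - 1e-9 | v > 3 + 1e-9)))
      return("severity values must lie within [1, 3]")
    if (object@blockSize < 1) return("blockSize must be >= 1")
    TRUE
  })

#' Synthetic H&E-like slide with full nuclear ground truth
#'
#' A raster image together with the nucleus records that were rendered into
#' it, the per-block severity field that drove their morphology, and the
#' region layout (invasive / benign / background).
#'
#' @slot image numeric array \code{H x W x 3}, values in [0, 1].
#' @slot spacing micrometres per pixel.
#' @slot nuclei data.frame with one row per rendered nucleus: \code{x},
#'   \code{y} (0-based pixel centre), \code{major}, \code{minor} (semi-axes,
#'   pixels), \code{orientation} (radians), \code{label} (\code{"tumor"} or
#'   \code{"normal"}), \code{contrast} (chromatin contrast in [0, 1]).
#' @slot severity a \linkS4class{SeverityField}.
#' @slot regions data.frame of half-open region rectangles: \code{x0},
#'   \code{y0}, \code{x1}, \code{y1}, \code{label}, \code{severity}.
#' @export
setClass("SyntheticSlide",
  representation(image = "array", spacing = "numeric", nuclei = "data.frame",
                 severity = "SeverityField", regions = "data.frame"),
  validity = function(object) {
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L)
      return("image must be an H x W x 3 array")
    nn <- object@nuclei
    if (nrow(nn)) {
      if (any(nn$x < 0 | nn$x >= d[2] | nn$y < 0 | nn$y >= d[1]))
        return("all nucleus centers must lie inside the image bounds")
      if (any(nn$major < nn$minor) || any(nn$minor <= 0))
        return("semi-axes must satisfy major >= minor > 0")
      if (!all(nn$label %in% c("tumor", "normal")))
        return("nucleus labels must be 'tumor' or 'normal'")
    }
    rg <- object@regions
    if (nrow(rg) && nrow(nn)) {
      for (i in seq_len(nrow(rg))) {
        if (rg$label[i] != "benign") next
        inside <- nn$x >= rg$x0[i] & nn$x < rg$x1[i] &
                  nn$y >= rg$y0[i] & nn$y < rg$y1[i]
        if (any(nn$label[inside] != "normal"))
          return("benign regions may contain only normal-labeled nuclei")
      }
    }
    TRUE
  })

#' Labeled point detections of epithelial cells
#'
#' The output contract of the detection stage: point locations labeled
#' tumor or normal with a confidence in [0, 1].
#'
#' @slot detections data.frame with columns \code{x}, \code{y} (0-based
#'   pixel coordinates), \code{label}, \code{confidence}.
#' @slot imageSize integer vector \code{c(H, W)} of the source raster.
#' @slot spacing micrometres per pixel.
#' @slot sourceId identifier of the source image.
#' @export
setClass("DetectionSet",
  representation(detections = "data.frame", imageSize = "numeric",
                 spacing = "numeric", sourceId = "character"),
  validity = function(object) {
    d <- object@detections
    if (nrow(d)) {
      if (!all(d$label %in% c("tumor", "normal")))
        return("labels must be 'tumor' or 'normal'")
      if (any(d$x < 0 | d$x >= object@imageSize[2] |
              d$y < 0 | d$y >= object@imageSize[1]))
        return("all detection centers must lie inside the image bounds")
      if (any(d$confidence < 0 | d$confidence > 1))
        return("confidences must lie in [0, 1]")
    }
    TRUE
  })

#' Nuclear density map
#'
#' Sum of isotropic Gaussian kernels centred at (label-filtered) detections,
#' sampled on a regular stride grid. Used to steer patch sampling towards
#' areas of high nuclear composition.
#'
#' @slot values non-negative numeric matrix (rows = y grid, cols = x grid);
#'   grid node (i, j) sits at pixel (x = (j-1)*stride, y = (i-1)*stride).
#' @slot stride grid stride in pixels.
#' @slot sigma Gaussian kernel standard deviation in pixels.
#' @slot labelFilter one of \code{"tumor"}, \code{"normal"}, \code{"all"}.
#' @slot imageSize integer vector \code{c(H, W)}.
#' @export
setClass("DensityMap",
  representation(values = "matrix", stride = "numeric", sigma = "numeric",
                 labelFilter = "character", imageSize = "numeric"),
  validity = function(object) {
    if (any(object@values < 0)) return("density values must be non-negative")
    if (object@stride < 1) return("stride must be >= 1")
    if (object@sigma <= 0) return("sigma must be > 0")
    TRUE
  })

#' Discrete panel scores from a rater panel
#'
#' Per-rater pleomorphism scores in {1, 2, 3} for a set of items (ROIs or
#' slides), with optional ordinal confidences
#' (\code{not_certain} < \code{fairly_certain} < \code{certain}).
#'
#' @slot scores integer matrix, items x raters, entries in {1, 2, 3}.
#' @slot confidence character matrix of the same shape (or 0 x 0 when the
#'   panel recorded no confidences).
#' @export
setClass("PanelScores",
  representation(scores = "matrix", confidence = "matrix"),
  validity = function(object) {
    s <- object@scores
    if (!all(s %in% c(1L, 2L, 3L)))
      return("all scores must be 1, 2 or 3")
    cf <- object@confidence
    if (length(cf)) {
      if (!identical(dim(cf), dim(s)))
        return("confidence matrix must match the score matrix shape")
      ok <- is.na(cf) | cf %in% c("not_certain", "fairly_certain", "certain")
      if (!all(ok))
        return("confidences must be not_certain / fairly_certain / certain")
    }
    TRUE
  })

#' Per-block continuous score map from overlapping-tile inference
#'
#' Each block holds the average of the continuous scores of all overlapping
#' tiles that covered it, the number of contributing tiles, and a tumor mask
#' restricting the slide score to invasive tumor.
#'
#' @slot scores numeric matrix of block scores in [1, 3]; \code{NA} where no
#'   tile contributed.
#' @slot counts integer matrix of contributing-tile counts.
#' @slot tumorMask logical matrix marking tumor blocks.
#' @slot blockSize block edge length in pixels.
#' @export
setClass("BlockScoreMap",
  representation(scores = "matrix", counts = "matrix", tumorMask = "matrix",
                 blockSize = "numeric"),
  validity = function(object) {
    s <- object@scores; n <- object@counts
    if (!identical(dim(s), dim(n)) ||
        !identical(dim(s), dim(object@tumorMask)))
      return("scores, counts and tumorMask must share one shape")
    if (any(n == 0 & !is.na(s)))
      return("blocks with zero contributing tiles must be NA, never 0-valued")
    if (any(!is.na(s) & (s < 1 - 1e-9 | s > 3 + 1e-9)))
      return("block scores must lie within [1, 3]")
    TRUE
  })

#' Even quantization of the severity range [1, 3]
#'
#' Partition of [1, 3] into \code{p} equal brackets with exact edges
#' \code{1 + 2k/p}; brackets are left-closed / right-open, with the final
#' bracket right-closed so that 3 maps to category \code{p}.
#'
#' @slot p number of categories.
#' @slot edges numeric vector of the p + 1 bracket edges.
#' @export
setClass("QuantizationScheme",
  representation(p = "integer", edges = "numeric"),
  validity = function(object) {
    if (object@p < 2) return("p must be >= 2")
    e <- object@edges
    if (length(e) != object@p + 1L || abs(e[1] - 1) > 1e-12 ||
        abs(e[length(e)] - 3) > 1e-12)
      return("edges must run from 1 to 3 with p + 1 entries")
    TRUE
  })

#' Overlapping tile grid over a slide raster
#'
#' Tile origins are multiples of \code{tileSize - overlap}; when the last
#' stride does not land flush with the image edge an extra tile shifted to
#' end exactly at the edge is appended, so every pixel is covered.
#'
#' @slot xs,ys 0-based tile origins along x and y.
#' @slot tileSize,overlap tile edge and overlap in pixels.
#' @slot imageSize integer vector \code{c(H, W)}.
#' @export
setClass("TileGrid",
  representation(xs = "numeric", ys = "numeric", tileSize = "numeric",
                 overlap = "numeric", imageSize = "numeric"))

#' Dense-block convolutional regressor
#'
#' A convolutional network of densely connected blocks separated by
#' channel-reducing transition layers, ending in global average pooling and
#' a single linear output. Parameters live in \code{layers}; the
#' architecture and training hyper-parameters live in \code{config}.
#'
#' @slot config list, see \code{\link{regressorConfig}}.
#' @slot layers list of layer parameter sets.
#' @export
setClass("PleoRegressor",
  representation(config = "list", layers = "list"))

#' Constant-output model stub
#'
#' Predicts a fixed score for every patch; used to exercise the pooling
#' plumbing (conservation properties) without a trained network.
#'
#' @slot value the constant score.
#' @export
setClass("ConstantModel", representation(value = "numeric"))
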