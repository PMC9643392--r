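#' Overlapping tile grid
#'
#' Tile origins advance by \code{tileSize - overlap}; when the final stride
#' does not land flush with the image edge, one extra tile shifted to end
#' exactly at the edge is appended per axis, so every pixel is covered and
#' every tile has identical size (no padding, no partial tiles).
#'
#' @param imageSize \code{c(H, W)} in pixels.
#' @param tileSize tile edge length (default 512).
#' @param overlap overlap between neighbouring tiles (default 448).
#' @return a \linkS4class{TileGrid}.
#' @export
tileGrid <- function(imageSize, tileSize = 512, overlap = 448) {
  stopIfNot(overlap >= 0 && overlap < tileSize,
            "overlap must satisfy 0 <= overlap < tileSize")
  stopIfNot(tileSize <= min(imageSize),
            "tile larger than the image")
  stride <- tileSize - overlap
  axis <- function(extent) {
    o <- seq(0, extent - tileSize, by = stride)
    if (tail(o, 1) + tileSize < extent) o <- c(o, extent - tileSize)
    o
  }
  new("TileGrid", xs = axis(imageSize[2]), ys = axis(imageSize[1]),
      tileSize = tileSize, overlap = overlap, imageSize = imageSize)
}

#' Score a whole slide by overlapping tiles with block pooling
#'
#' Every tile that intersects the tumor mask is scored once by the patch
#' scorer. Each block then receives the average of the scores of all tiles
#' covering it (area-weighted when a shifted boundary tile covers a block
#' only partially), and the slide score is the unweighted mean over
#' tumor-masked blocks with at least one contributing tile. Blocks no tile
#' contributed to stay missing, never zero.
#'
#' @param model patch scorer (its configured input size sets the tile size
#'   unless \code{tileSize} is given).
#' @param slide slide raster (\code{H x W x 3}) or
#'   \linkS4class{SyntheticSlide}.
#' @param dets a \linkS4class{DetectionSet} registered to the raster.
#' @param tileSize,overlap tile geometry in pixels.
#' @param block block edge length in pixels (default 64).
#' @param minTumorCount tumor detections per block required for the mask
#'   (0 disables masking).
#' @param maskMode \code{"tumor"} averages tumor-masked blocks only (the
#'   intended behaviour); \code{"all"} averages every scored block.
#' @return list with \code{map} (a \linkS4class{BlockScoreMap}) and
#'   \code{score} (the slide score).
#' @export
scoreSlide <- function(model, slide, dets, tileSize = NULL, overlap = NULL,
                       block = 64, minTumorCount = 3,
                       maskMode = c("tumor", "all")) {
  maskMode <- match.arg(maskMode)
  if (is(slide, "SyntheticSlide")) slide <- slideImage(slide)
  d <- dim(slide)
  if (is.null(tileSize))
    tileSize <- if (is(model, "ConstantModel")) 512 else
      model@config$inputSize
  if (is.null(overlap)) overlap <- round(tileSize * 7 / 8)
  grid <- tileGrid(d[1:2], tileSize, overlap)
  mask <- tumorBlockMask(dets, block, minTumorCount)
  nbr <- nrow(mask); nbc <- ncol(mask)
  # tiles to score: any overlapped block is tumor
  tiles <- expand.grid(x = grid@xs, y = grid@ys)
  blockRange <- function(a0, a1, nb)
    max(1, floor(a0 / block) + 1):min(nb, floor((a1 - 1) / block) + 1)
  scored <- vapply(seq_len(nrow(tiles)), function(t) {
    rows <- blockRange(tiles$y[t], tiles$y[t] + tileSize, nbr)
    cols <- blockRange(tiles$x[t], tiles$x[t] + tileSize, nbc)
    any(mask[rows, cols])
  }, logical(1))
  if (!any(scored)) noTumorError("no tumor blocks on this slide")
  tiles <- tiles[scored, , drop = FALSE]
  patches <- lapply(seq_len(nrow(tiles)), function(t)
    cropImage(slide, tiles$x[t], tiles$y[t], tileSize, tileSize))
  scores <- predictPatches(model, patches)
  # running area-weighted mean per block (Welford update: exactly
  # conservative when every contributing tile carries the same score)
  mean_ <- matrix(0, nbr, nbc); wsum <- matrix(0, nbr, nbc)
  cnt <- matrix(0L, nbr, nbc)
  for (t in seq_len(nrow(tiles))) {
    x0 <- tiles$x[t]; y0 <- tiles$y[t]
    rows <- blockRange(y0, y0 + tileSize, nbr)
    cols <- blockRange(x0, x0 + tileSize, nbc)
    # fractional coverage of each block row/col by the tile
    fr <- pmin(y0 + tileSize, (rows) * block) - pmax(y0, (rows - 1) * block)
    fc <- pmin(x0 + tileSize, (cols) * block) - pmax(x0, (cols - 1) * block)
    w <- outer(fr, fc) / block^2
    wNew <- wsum[rows, cols] + w
    mean_[rows, cols] <- mean_[rows, cols] +
      (w / wNew) * (scores[t] - mean_[rows, cols])
    wsum[rows, cols] <- wNew
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  vals <- matrix(NA_real_, nbr, nbc)
  nz <- wsum > 0
  vals[nz] <- mean_[nz]
  map <- new("BlockScoreMap", scores = vals, counts = cnt,
             tumorMask = mask, blockSize = block)
  sel <- if (maskMode == "tumor") mask & cnt > 0 else cnt > 0
  if (!any(sel)) noTumorError("no scored tumor blocks")
  list(map = map, score = mean(vals[sel]))
}

#' Even quantization scheme over [1, 3]
#'
#' @param p number of categories; edges are the exact values
#'   \code{1 + 2k/p} (for p = 3: 1, 5/3, 7/3, 3).
#' @return a \linkS4class{QuantizationScheme}.
#' @export
quantizationScheme <- function(p = 3) {
  p <- as.integer(p)
  new("QuantizationScheme", p = p, edges = 1 + 2 * (0:p) / p)
}

#' Quantize continuous scores into categories
#'
#' Maps each score to the index of its bracket: brackets are left-closed /
#' right-open with the final bracket right-closed, so for three categories
#' [1, 5/3) is 1, [5/3, 7/3) is 2 and [7/3, 3] is 3.
#'
#' @param score numeric vector of scores in [1, 3].
#' @param scheme a \linkS4class{QuantizationScheme}.
#' @return integer categories in 1..p.
#' @export
quantize <- function(score, scheme = quantizationScheme(3)) {
  stopIfNot(all(score >= 1 - 1e-9 & score <= 3 + 1e-9),
            "scores must lie within [1, 3]; clamp upstream")
  score <- clamp(score, 1, 3)
  pmin(findInterval(score, scheme@edges), scheme@p)
}

#' Render a block score map as a severity heatmap
#'
#' Linear green-yellow-red colormap over [1, 3]: score 1 maps to pure
#' green, 2 to yellow and 3 to red; missing blocks take a neutral
#' light-gray. The legend (anchor scores and colors) is attached as an
#' attribute and written as a JSON sidecar by \code{\link{writeHeatmap}}.
#'
#' @param bmap a \linkS4class{BlockScoreMap}.
#' @param upscale output pixels per block (default the block size).
#' @param tumorOnly blank out non-tumor blocks?
#' @return RGB array with a \code{legend} attribute.
#' @export
renderHeatmap <- function(bmap, upscale = NULL, tumorOnly = FALSE) {
  s <- blockScores(bmap)
  stopIfNot(length(s) > 0, "empty block map")
  if (tumorOnly) s[!tumorMask(bmap)] <- NA
  if (is.null(upscale)) upscale <- bmap@blockSize
  col <- severityColor(s)
  nbr <- nrow(s); nbc <- ncol(s)
  out <- array(0, c(nbr * upscale, nbc * upscale, 3))
  ri <- rep(seq_len(nbr), each = upscale)
  ci <- rep(seq_len(nbc), each = upscale)
  for (c in 1:3) {
    ch <- matrix(col[, , c], nbr, nbc)
    out[, , c] <- ch[ri, ci]
  }
  attr(out, "legend") <- list(
    anchors = c(1, 2, 3),
    colors = c("#00FF00", "#FFFF00", "#FF0000"),
    missing = "#D9D9D9")
  out
}

# score matrix -> nbr x nbc x 3 color array (NA -> neutral gray)
severityColor <- function(s) {
  r <- clamp(s - 1, 0, 1)
  g <- 1 - clamp(s - 2, 0, 1)
  b <- s * 0
  miss <- is.na(s)
  r[miss] <- 0.85; g[miss] <- 0.85; b[miss] <- 0.85
  out <- array(0, c(nrow(s), ncol(s), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
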