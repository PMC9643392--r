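#' Detect epithelial cells in a raster
#'
#' Desk-scale detector with the output contract of a point-detection
#' network: labeled point detections (tumor / normal) with confidences.
#' \code{oracle} mode passes ground-truth nucleus records through with
#' confidence 1; \code{blob} mode runs a multi-scale
#' Laplacian-of-Gaussian (difference-of-Gaussians) nucleus detector on the
#' hematoxylin optical-density channel and labels each detection tumor or
#' normal by an estimated-radius threshold calibrated on the severity-1
#' morphology of the synthetic generator.
#'
#' @param image numeric array \code{H x W x 3} in [0, 1].
#' @param mode \code{"oracle"} or \code{"blob"}.
#' @param truth ground-truth nucleus records (required in oracle mode).
#' @param spacing micrometres per pixel.
#' @param sourceId identifier carried into the result.
#' @param threshold blob-response threshold (OD units).
#' @param radiusCutUm tumor/normal radius cut in micrometres; defaults to
#'   1.2 times the severity-1 mean radius of the generator's morphology
#'   map.
#' @return a \linkS4class{DetectionSet}.
#' @export
detectCells <- function(image, mode = c("oracle", "blob"), truth = NULL,
                        spacing = 0.25, sourceId = "image",
                        threshold = 0.08, radiusCutUm = NULL) {
  mode <- match.arg(mode)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (mode == "oracle") {
    stopIfNot(!is.null(truth), "oracle mode requires ground-truth records")
    det <- data.frame(x = truth$x, y = truth$y,
                      label = if (nrow(truth)) truth$label else character(0),
                      confidence = rep(1, nrow(truth)),
                      stringsAsFactors = FALSE)
    return(new("DetectionSet", detections = det, imageSize = c(H, W),
               spacing = spacing, sourceId = sourceId))
  }
  if (is.null(radiusCutUm))
    radiusCutUm <- 1.2 * morphologyMap(1)$radiusMeanUm
  od <- hematoxylinOD(image)
  odS <- EBImage::gblur(od, 1.5)
  bgOD <- stats::median(odS)
  radiiUm <- c(2.2, 2.9, 3.7, 4.7, 6.0, 7.6, 9.5)
  sigmas <- radiiUm / spacing / sqrt(2)
  # the 1.6-sigma blur kernel must fit inside the image
  sigmas <- sigmas[2 * ceiling(3 * 1.6 * sigmas) + 1 <= min(H, W)]
  best <- matrix(-Inf, H, W)
  bestIdx <- matrix(1L, H, W)
  resp <- array(0, c(H, W, length(sigmas)))
  for (s in seq_along(sigmas)) {
    s1 <- EBImage::gblur(od, sigmas[s])
    s2 <- EBImage::gblur(od, 1.6 * sigmas[s])
    r <- (s1 - s2) / 0.6
    resp[, , s] <- r
    upd <- r > best
    best[upd] <- r[upd]
    bestIdx[upd] <- s
  }
  peaks <- best >= threshold & best >= .max_filter(best, 3L) - 1e-12
  idx <- which(peaks, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    det <- data.frame(x = numeric(0), y = numeric(0),
                      label = character(0), confidence = numeric(0))
    return(new("DetectionSet", detections = det, imageSize = c(H, W),
               spacing = spacing, sourceId = sourceId))
  }
  rs <- sqrt(2) * sigmas[bestIdx[idx]]
  vs <- best[idx]
  ord <- order(vs, decreasing = TRUE)
  xs <- idx[ord, 2] - 1; ys <- idx[ord, 1] - 1
  rs <- rs[ord]; vs <- vs[ord]
  # mean-shift centroid refinement on the background-subtracted smoothed
  # OD: LoG peaks of large eccentric nuclei sit off-centre on the ridge
  for (it in 1:3) for (i in seq_along(xs)) {
    r <- 1.3 * rs[i]
    x0 <- max(0, round(xs[i] - r)); x1 <- min(W - 1, round(xs[i] + r))
    y0 <- max(0, round(ys[i] - r)); y1 <- min(H - 1, round(ys[i] + r))
    wv <- pmax(odS[(y0:y1) + 1, (x0:x1) + 1] - bgOD, 0)
    sw <- sum(wv)
    if (sw <= 0) next
    gx <- matrix(x0:x1, nrow = y1 - y0 + 1, ncol = x1 - x0 + 1,
                 byrow = TRUE)
    gy <- matrix(y0:y1, nrow = y1 - y0 + 1, ncol = x1 - x0 + 1)
    xs[i] <- sum(wv * gx) / sw
    ys[i] <- sum(wv * gy) / sw
  }
  keep <- logical(length(vs))
  kx <- numeric(0); ky <- numeric(0); kr <- numeric(0)
  for (i in seq_along(vs)) {  # greedy non-maximum suppression
    if (length(kx)) {
      lim <- 0.6 * (kr + rs[i])
      if (any((kx - xs[i])^2 + (ky - ys[i])^2 < lim^2)) next
    }
    keep[i] <- TRUE
    kx <- c(kx, xs[i]); ky <- c(ky, ys[i]); kr <- c(kr, rs[i])
  }
  # size classifier: half-maximum radius of the smoothed OD radial
  # profile (the LoG argmax scale tracks chromatin clumps, not extent)
  kx <- clamp(xs[keep], 0, W - 1)
  ky <- clamp(ys[keep], 0, H - 1)
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  rmax <- ceiling(10 / spacing / sqrt(2))
  rPx <- vapply(seq_along(kx), function(i) {
    c0 <- odS[round(ky[i]) + 1, round(kx[i]) + 1]
    half <- bgOD + 0.5 * (c0 - bgOD)
    for (r in seq_len(rmax)) {
      px <- pmax(1, pmin(W, round(kx[i] + r * cos(ang)) + 1))
      py <- pmax(1, pmin(H, round(ky[i] + r * sin(ang)) + 1))
      if (mean(odS[cbind(py, px)]) < half) return(r)
    }
    rmax
  }, numeric(1))
  det <- data.frame(
    x = kx, y = ky,
    label = ifelse(rPx * spacing > radiusCutUm, "tumor", "normal"),
    confidence = clamp(vs[keep] / max(vs[keep]), 0, 1),
    stringsAsFactors = FALSE)
  new("DetectionSet", detections = det, imageSize = c(H, W),
      spacing = spacing, sourceId = sourceId)
}

#' Nuclear density map from detections
#'
#' Sum of isotropic, 4-sigma-truncated Gaussian kernels centred at the
#' (label-filtered) detections, sampled on a regular stride grid. The
#' kernels are normalized so the grid sum times stride^2 approximately
#' recovers the number of detections (mass conservation up to truncation
#' and image-border loss).
#'
#' @param dets a \linkS4class{DetectionSet}.
#' @param sigma Gaussian standard deviation in pixels.
#' @param stride grid stride in pixels.
#' @param labelFilter \code{"tumor"}, \code{"normal"} or \code{"all"}.
#' @return a \linkS4class{DensityMap}.
#' @export
densityMap <- function(dets, sigma = 16, stride = 4,
                       labelFilter = c("tumor", "normal", "all")) {
  labelFilter <- match.arg(labelFilter)
  stopIfNot(sigma > 0, "sigma must be > 0")
  stopIfNot(stride >= 1, "stride must be >= 1")
  d <- detections(dets)
  if (labelFilter != "all") d <- d[d$label == labelFilter, , drop = FALSE]
  H <- dets@imageSize[1]; W <- dets@imageSize[2]
  vals <- .density_accumulate(as.numeric(d$x), as.numeric(d$y),
                              as.integer(H), as.integer(W),
                              sigma, as.integer(stride))
  new("DensityMap", values = vals, stride = stride, sigma = sigma,
      labelFilter = labelFilter, imageSize = c(H, W))
}

#' Sample patch centres proportionally to nuclear density
#'
#' Draws patch centres with probability proportional to the density mass of
#' each grid cell, restricted so the patch lies fully inside the image, then
#' jitters uniformly within the (clipped) cell. This operationalizes
#' sampling "from areas with high nuclear composition" without a hard
#' threshold.
#'
#' @param dmap a \linkS4class{DensityMap} with positive total mass over the
#'   valid centre region.
#' @param n number of centres.
#' @param patchSize patch edge length in pixels.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{x}, \code{y} (0-based centres).
#' @export
samplePatchCenters <- function(dmap, n, patchSize, seed = NULL) {
  H <- dmap@imageSize[1]; W <- dmap@imageSize[2]
  half <- patchSize / 2
  stopIfNot(patchSize <= min(H, W), "patch must fit in the image")
  st <- dmap@stride
  v <- dmap@values
  gx <- (seq_len(ncol(v)) - 1) * st
  gy <- (seq_len(nrow(v)) - 1) * st
  # clip each node's cell [g - st/2, g + st/2] to the valid centre range
  xlo <- clamp(gx - st / 2, half, W - half); xhi <- clamp(gx + st / 2, half, W - half)
  ylo <- clamp(gy - st / 2, half, H - half); yhi <- clamp(gy + st / 2, half, H - half)
  wx <- pmax(xhi - xlo, 0); wy <- pmax(yhi - ylo, 0)
  wmat <- outer(wy, wx) * v           # density x clipped cell area
  tot <- sum(wmat)
  if (tot <= 0) noTumorError("density map has no mass in the valid region")
  withSeed(seed, {
    pick <- sample.int(length(wmat), n, replace = TRUE, prob = as.numeric(wmat))
    i <- (pick - 1) %% nrow(wmat) + 1
    j <- (pick - 1) %/% nrow(wmat) + 1
    data.frame(x = runif(n, xlo[j], xhi[j]), y = runif(n, ylo[i], yhi[i]))
  })
}

#' Tumor block mask from detections
#'
#' Marks a block true when at least \code{minCount} tumor-labeled
#' detections fall inside it; \code{minCount = 0} marks every block. The
#' mask is monotone non-increasing in \code{minCount}.
#'
#' @param dets a \linkS4class{DetectionSet}.
#' @param block block edge length in pixels.
#' @param minCount minimum tumor detections per block.
#' @return logical matrix (rows = y blocks, cols = x blocks).
#' @export
tumorBlockMask <- function(dets, block = 64, minCount = 3) {
  stopIfNot(block >= 1, "block must be >= 1")
  H <- dets@imageSize[1]; W <- dets@imageSize[2]
  nbr <- ceiling(H / block); nbc <- ceiling(W / block)
  if (minCount <= 0) return(matrix(TRUE, nbr, nbc))
  d <- detections(dets)
  d <- d[d$label == "tumor", , drop = FALSE]
  counts <- matrix(0L, nbr, nbc)
  if (nrow(d)) {
    bi <- floor(d$y / block) + 1
    bj <- floor(d$x / block) + 1
    for (t in seq_len(nrow(d)))
      counts[bi[t], bj[t]] <- counts[bi[t], bj[t]] + 1L
  }
  counts >= minCount
}

#' Match detections to ground truth and compute recall/precision
#'
#' Greedy-by-confidence matching of detections to ground-truth nucleus
#' centres within a fixed pixel radius; each truth point matches at most
#' one detection.
#'
#' @param dets a \linkS4class{DetectionSet}.
#' @param truth ground-truth nucleus records.
#' @param radius matching radius in pixels (default 10 px).
#' @return list with \code{recall}, \code{precision}, \code{nMatched}.
#' @export
matchDetections <- function(dets, truth, radius = 10) {
  d <- detections(dets)
  if (nrow(d) == 0 || nrow(truth) == 0)
    return(list(recall = 0, precision = if (nrow(d)) 0 else NA_real_,
                nMatched = 0L))
  ord <- order(d$confidence, decreasing = TRUE)
  taken <- logical(nrow(truth))
  matched <- 0L
  for (i in ord) {
    d2 <- (truth$x - d$x[i])^2 + (truth$y - d$y[i])^2
    d2[taken] <- Inf
    j <- which.min(d2)
    if (d2[j] <= radius^2) { taken[j] <- TRUE; matched <- matched + 1L }
  }
  list(recall = matched / nrow(truth), precision = matched / nrow(d),
       nMatched = matched)
}
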