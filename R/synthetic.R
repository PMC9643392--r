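#' Severity-to-morphology parameter map
#'
#' Linear map from the continuous pleomorphism severity \code{s} in [1, 3]
#' to the nuclear morphology parameters used by the generator. A severity of
#' 1 emulates nuclei close to normal breast epithelium (small, round,
#' uniform, low chromatin contrast); 3 emulates severely pleomorphic nuclei
#' (enlarged, elongated, highly variable in size, coarse chromatin). All
#' sizes are physical (micrometres) so rasters at different spacings stay
#' consistent.
#'
#' @param severity severity value(s) in [1, 3].
#' @return list with elements \code{radiusMeanUm} (mean equivalent radius),
#'   \code{radiusCV} (coefficient of variation of the radius),
#'   \code{elongationMean} (mean minor/major axis ratio) and
#'   \code{contrastMean} (mean chromatin contrast).
#' @export
morphologyMap <- function(severity) {
  stopIfNot(all(severity >= 1 & severity <= 3),
            "severity must lie within [1, 3]")
  t <- severity - 1
  list(radiusMeanUm   = 3.0 + 1.25 * t,
       radiusCV       = 0.10 + 0.175 * t,
       elongationMean = 0.90 - 0.20 * t,
       contrastMean   = 0.15 + 0.25 * t)
}

#' Generate a hard-core random field of nucleus records
#'
#' Draws a Poisson number of nuclei for the region, samples their morphology
#' from the severity map, and places them by a hard-core process (minimum
#' centre distance 0.8 times the sum of the two minor semi-axes) so nuclei
#' do not overlap pathologically. Mean nuclear area, nuclear-area variance,
#' mean eccentricity and chromatin contrast are all strictly increasing in
#' \code{severity}.
#'
#' @param severity severity in [1, 3] driving the morphology.
#' @param targetDensity target density in nuclei per square millimetre.
#' @param regionBounds half-open pixel rectangle \code{c(x0, y0, x1, y1)},
#'   0-based.
#' @param label \code{"tumor"} or \code{"normal"}. Normal fields use the
#'   severity-1 morphology regardless of \code{severity}.
#' @param spacing micrometres per pixel.
#' @param seed optional integer seed.
#' @return data.frame of nucleus records (\code{x}, \code{y}, \code{major},
#'   \code{minor}, \code{orientation}, \code{label}, \code{contrast});
#'   semi-axes in pixels. Empty (with a warning) when the region is too
#'   small to hold a nucleus.
#' @export
generateNucleusField <- function(severity, targetDensity = 6000,
                                 regionBounds, label = c("tumor", "normal"),
                                 spacing = 0.25, seed = NULL) {
  label <- match.arg(label)
  stopIfNot(severity >= 1 && severity <= 3, "severity must lie in [1, 3]")
  stopIfNot(targetDensity > 0, "targetDensity must be > 0")
  w <- regionBounds[3] - regionBounds[1]
  h <- regionBounds[4] - regionBounds[2]
  stopIfNot(w > 0 && h > 0, "region area must be > 0")
  if (label == "normal") severity <- 1
  mm <- morphologyMap(severity)
  withSeed(seed, {
    areaMM2 <- w * h * spacing^2 / 1e6
    n <- rpois(1, targetDensity * areaMM2)
    empty <- data.frame(x = numeric(0), y = numeric(0), major = numeric(0),
                        minor = numeric(0), orientation = numeric(0),
                        label = character(0), contrast = numeric(0))
    if (n == 0) {
      warning(warningCondition(
        "region too small to place any nucleus",
        class = c("pleoEmptyRegionWarning", "warning")))
      return(empty)
    }
    sdlog <- sqrt(log(1 + mm$radiusCV^2))
    meanlog <- log(mm$radiusMeanUm) - sdlog^2 / 2
    rUm <- rlnorm(n, meanlog, sdlog)
    q <- clamp(rnorm(n, mm$elongationMean, 0.08), 0.30, 1.00)
    rPx <- rUm / spacing
    major <- rPx / sqrt(q)
    minor <- rPx * sqrt(q)
    orientation <- runif(n, 0, pi)
    contrast <- clamp(rnorm(n, mm$contrastMean, 0.05), 0, 1)
    px <- runif(n, regionBounds[1], regionBounds[3])
    py <- runif(n, regionBounds[2], regionBounds[4])
    # greedy hard-core thinning in proposal order
    keep <- logical(n)
    ax <- numeric(n); ay <- numeric(n); am <- numeric(n); k <- 0L
    for (i in seq_len(n)) {
      if (k > 0L) {
        lim <- 0.8 * (am[1:k] + minor[i])
        d2 <- (ax[1:k] - px[i])^2 + (ay[1:k] - py[i])^2
        if (any(d2 < lim^2)) next
      }
      k <- k + 1L
      ax[k] <- px[i]; ay[k] <- py[i]; am[k] <- minor[i]
      keep[i] <- TRUE
    }
    if (!any(keep)) {
      warning(warningCondition(
        "region too small to place any nucleus",
        class = c("pleoEmptyRegionWarning", "warning")))
      return(empty)
    }
    data.frame(x = px[keep], y = py[keep], major = major[keep],
               minor = minor[keep], orientation = orientation[keep],
               label = label, contrast = contrast[keep],
               stringsAsFactors = FALSE)
  })
}

#' Stain and sensor parameters for the renderer
#'
#' @param backgroundOD eosin optical density of the tissue background.
#' @param nucleusOD base hematoxylin optical density inside a nucleus.
#' @param noiseSd Gaussian read-noise standard deviation on the [0, 1]
#'   intensity scale (default 4/255).
#' @param textureWavelengthUm range (micrometres) of the chromatin texture
#'   wavelengths.
#' @return parameter list for \code{\link{renderPatch}}.
#' @export
stainParams <- function(backgroundOD = 0.25, nucleusOD = 0.9,
                        noiseSd = 4 / 255,
                        textureWavelengthUm = c(1.5, 3.5)) {
  list(backgroundOD = backgroundOD, nucleusOD = nucleusOD,
       noiseSd = noiseSd, textureWavelengthUm = textureWavelengthUm)
}

#' Render nucleus records into an H&E-like RGB raster
#'
#' Nuclei are drawn as soft-edged ellipses of hematoxylin optical density,
#' modulated by a per-nucleus chromatin texture whose amplitude is the
#' record's \code{contrast}; the surround carries a uniform eosin optical
#' density. The two OD channels are combined by Beer-Lambert absorption
#' with standard H&E stain vectors, then Gaussian read noise is added.
#' Nuclei extending beyond the canvas are silently clipped.
#'
#' @param nuclei data.frame of nucleus records (possibly empty).
#' @param size raster size in pixels, scalar or \code{c(H, W)}.
#' @param spacing micrometres per pixel.
#' @param stain parameter list from \code{\link{stainParams}}.
#' @param seed optional integer seed (texture + noise).
#' @return numeric array \code{H x W x 3} with values in [0, 1].
#' @export
renderPatch <- function(nuclei, size, spacing = 0.25,
                        stain = stainParams(), seed = NULL) {
  stopIfNot(all(size > 0), "size must be > 0")
  if (length(size) == 1) size <- c(size, size)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  withSeed(seed, {
    odH <- matrix(0, H, W)
    n <- nrow(nuclei)
    if (n > 0) {
      wl <- runif(2 * n, stain$textureWavelengthUm[1],
                  stain$textureWavelengthUm[2]) / spacing
      ang <- runif(2 * n, 0, 2 * pi)
      f <- 2 * pi / wl
      tex <- rbind(rep(0.7, n), (f * cos(ang))[1:n], (f * sin(ang))[1:n],
                   rep(0.5, n), (f * cos(ang))[n + 1:n],
                   (f * sin(ang))[n + 1:n])
      odH <- .render_nuclei_od(odH, nuclei$x, nuclei$y, nuclei$major,
                               nuclei$minor, nuclei$orientation,
                               nuclei$contrast,
                               rep(stain$nucleusOD, n), tex)
    }
    odE <- matrix(stain$backgroundOD, H, W)
    img <- odToRGB(odH, odE)
    img <- img + rnorm(length(img), 0, stain$noiseSd)
    clamp(img, 0, 1)
  })
}

# Build the block-resolution severity field for a region layout.
buildSeverityField <- function(regions, size, blockSize, spacing) {
  nbr <- ceiling(size[1] / blockSize)
  nbc <- ceiling(size[2] / blockSize)
  vals <- matrix(NA_real_, nbr, nbc)
  cx <- (seq_len(nbc) - 0.5) * blockSize
  cy <- (seq_len(nbr) - 0.5) * blockSize
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    rows <- which(cy >= r$y0 & cy < r$y1)
    cols <- which(cx >= r$x0 & cx < r$x1)
    if (length(rows) && length(cols))
      vals[rows, cols] <- r$severity
  }
  new("SeverityField", values = vals, blockSize = blockSize,
      spacing = spacing)
}

#' Generate a synthetic slide from a region layout
#'
#' Builds a mosaic slide raster from non-overlapping rectangular regions.
#' Invasive regions are populated with tumor-labeled nuclei at their stated
#' severity; benign regions are forced to severity-1 morphology with
#' normal-labeled nuclei; everything else is bare background. The returned
#' slide carries the rendered image, every nucleus record, and the
#' piecewise-constant per-block severity field.
#'
#' @param layout data.frame with columns \code{x0}, \code{y0}, \code{x1},
#'   \code{y1} (half-open pixel rects), \code{label} (\code{"invasive"} or
#'   \code{"benign"}) and \code{severity} (ignored for benign regions).
#' @param size slide size in pixels, scalar or \code{c(H, W)}.
#' @param spacing micrometres per pixel.
#' @param seed optional integer seed.
#' @param tumorDensity,normalDensity nuclei per square millimetre.
#' @param blockSize severity-field block resolution in pixels.
#' @param stain renderer parameters, see \code{\link{stainParams}}.
#' @return a \linkS4class{SyntheticSlide}.
#' @export
generateSlide <- function(layout, size = 512, spacing = 0.5, seed = NULL,
                          tumorDensity = 6000, normalDensity = 5000,
                          blockSize = 32, stain = stainParams()) {
  if (length(size) == 1) size <- c(size, size)
  stopIfNot(all(c("x0", "y0", "x1", "y1", "label") %in% names(layout)),
            "layout must have columns x0, y0, x1, y1, label")
  if (is.null(layout$severity)) layout$severity <- NA_real_
  stopIfNot(all(layout$label %in% c("invasive", "benign")),
            "region labels must be 'invasive' or 'benign'")
  layout$severity[layout$label == "benign"] <- 1
  stopIfNot(all(layout$severity >= 1 & layout$severity <= 3),
            "invasive regions need a severity in [1, 3]")
  stopIfNot(all(layout$x0 >= 0 & layout$y0 >= 0 &
                layout$x1 <= size[2] & layout$y1 <= size[1] &
                layout$x0 < layout$x1 & layout$y0 < layout$y1),
            "regions must be non-empty and lie within the slide bounds",
            class = "pleoLayoutError")
  n <- nrow(layout)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sep <- layout$x1[i] <= layout$x0[j] || layout$x1[j] <= layout$x0[i] ||
             layout$y1[i] <= layout$y0[j] || layout$y1[j] <= layout$y0[i]
      stopIfNot(sep, sprintf("regions %d and %d overlap", i, j),
                class = "pleoLayoutError")
    }
  }
  withSeed(seed, {
    parts <- lapply(seq_len(n), function(i) {
      r <- layout[i, ]
      lab <- if (r$label == "benign") "normal" else "tumor"
      dens <- if (lab == "tumor") tumorDensity else normalDensity
      suppressWarnings(generateNucleusField(
        r$severity, dens, c(r$x0, r$y0, r$x1, r$y1), lab, spacing))
    })
    nuc <- do.call(rbind, parts)
    if (is.null(nuc)) nuc <- generateNucleusField(1, 1, c(0, 0, 1, 1),
                                                  "normal")[0, ]
    img <- renderPatch(nuc, size, spacing, stain)
    sev <- buildSeverityField(layout, size, blockSize, spacing)
    new("SyntheticSlide", image = img, spacing = spacing, nuclei = nuc,
        severity = sev, regions = layout)
  })
}

#' Generate a paired tumor / normal region of interest
#'
#' Emulates the paired presentation used for ROI scoring: a tumor ROI
#' rendered at the requested severity next to a normal-epithelium ROI
#' rendered with the severity-1 morphology. Both rasters share the size and
#' spacing; defaults are 2560 x 2560 pixels at 0.25 micrometres per pixel.
#'
#' @param severity tumor severity in [1, 3].
#' @param seed optional integer seed.
#' @param size ROI edge length in pixels.
#' @param spacing micrometres per pixel.
#' @param tumorDensity,normalDensity nuclei per square millimetre.
#' @param stain renderer parameters.
#' @return list with \code{tumor} and \code{normal}
#'   \linkS4class{SyntheticSlide} objects.
#' @export
generateRoiPair <- function(severity, seed = NULL, size = 2560,
                            spacing = 0.25, tumorDensity = 6000,
                            normalDensity = 5000, stain = stainParams()) {
  stopIfNot(severity >= 1 && severity <= 3, "severity must lie in [1, 3]")
  withSeed(seed, {
    tl <- data.frame(x0 = 0, y0 = 0, x1 = size, y1 = size,
                     label = "invasive", severity = severity)
    nl <- data.frame(x0 = 0, y0 = 0, x1 = size, y1 = size,
                     label = "benign", severity = 1)
    list(tumor = generateSlide(tl, size, spacing,
                               tumorDensity = tumorDensity, stain = stain),
         normal = generateSlide(nl, size, spacing,
                                normalDensity = normalDensity,
                                stain = stain))
  })
}
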