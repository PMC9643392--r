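# Readers and writers for the plain-text interchange formats. Doubles are
# serialized with %.17g so CSV round trips are bit-exact.

fmtNum <- function(x) sprintf("%.17g", x)

#' Write / read a detections table
#'
#' CSV with columns \code{x}, \code{y}, \code{label}, \code{confidence};
#' coordinates round-trip bit-exactly.
#'
#' @param dets a \linkS4class{DetectionSet}.
#' @param path output CSV path.
#' @export
writeDetections <- function(dets, path) {
  d <- detections(dets)
  lines <- c("x,y,label,confidence",
             if (nrow(d)) paste(fmtNum(d$x), fmtNum(d$y), d$label,
                                fmtNum(d$confidence), sep = ","))
  writeLines(lines, path)
  meta <- list(imageSize = dets@imageSize, spacing = dets@spacing,
               sourceId = dets@sourceId)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeDetections
#' @param path2 path of a CSV written by \code{writeDetections}.
#' @export
readDetections <- function(path2) {
  d <- read.csv(path2, colClasses = c("numeric", "numeric", "character",
                                      "numeric"))
  meta <- jsonlite::read_json(paste0(path2, ".json"), simplifyVector = TRUE)
  new("DetectionSet", detections = d,
      imageSize = as.numeric(meta$imageSize), spacing = meta$spacing,
      sourceId = meta$sourceId)
}

#' Write / read a rater panel
#'
#' Long-format CSV with columns \code{item_id}, \code{rater_id},
#' \code{score}, \code{confidence} (empty when absent).
#'
#' @param panel a \linkS4class{PanelScores}.
#' @param path output CSV path.
#' @export
writePanel <- function(panel, path) {
  s <- scoreMatrix(panel); cf <- confidenceMatrix(panel)
  rows <- expand.grid(item = rownames(s), rater = colnames(s),
                      stringsAsFactors = FALSE)
  conf <- if (length(cf)) cf[cbind(match(rows$item, rownames(s)),
                                   match(rows$rater, colnames(s)))]
          else rep("", nrow(rows))
  conf[is.na(conf)] <- ""
  sc <- s[cbind(match(rows$item, rownames(s)),
                match(rows$rater, colnames(s)))]
  writeLines(c("item_id,rater_id,score,confidence",
               paste(rows$item, rows$rater, sc, conf, sep = ",")), path)
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  d <- read.csv(path, colClasses = c("character", "character", "integer",
                                     "character"))
  items <- unique(d$item_id); raters <- unique(d$rater_id)
  s <- matrix(NA_integer_, length(items), length(raters),
              dimnames = list(items, raters))
  cf <- matrix(NA_character_, length(items), length(raters),
               dimnames = list(items, raters))
  s[cbind(match(d$item_id, items), match(d$rater_id, raters))] <- d$score
  conf <- d$confidence
  conf[!nzchar(conf)] <- NA_character_
  cf[cbind(match(d$item_id, items), match(d$rater_id, raters))] <- conf
  PanelScores(s, if (all(is.na(cf))) NULL else cf)
}

#' Write nucleus records as CSV
#'
#' Columns \code{x}, \code{y}, \code{major}, \code{minor},
#' \code{orientation_rad}, \code{label}.
#'
#' @param nuclei nucleus records data.frame.
#' @param path output CSV path.
#' @export
writeNuclei <- function(nuclei, path) {
  writeLines(c("x,y,major,minor,orientation_rad,label",
               if (nrow(nuclei))
                 paste(fmtNum(nuclei$x), fmtNum(nuclei$y),
                       fmtNum(nuclei$major), fmtNum(nuclei$minor),
                       fmtNum(nuclei$orientation), nuclei$label,
                       sep = ",")), path)
  invisible(path)
}

#' Write an RGB raster as PNG or TIFF (by file extension)
#'
#' @param image numeric array \code{H x W x 3} (or \code{H x W}) in [0, 1].
#' @param path output path ending in .png, .tif or .tiff.
#' @export
writeImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(clamp(image, 0, 1), path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(clamp(image, 0, 1), path)
  else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' Export a density map as a single-channel TIFF
#'
#' Values are max-normalized to [0, 1] for storage; the scale factor is
#' recorded in a JSON sidecar.
#'
#' @param dmap a \linkS4class{DensityMap}.
#' @param path output TIFF path.
#' @export
writeDensityMap <- function(dmap, path) {
  v <- densityValues(dmap)
  m <- max(v, 1e-12)
  tiff::writeTIFF(v / m, path, bits.per.sample = 16L)
  jsonlite::write_json(list(scale = m, stride = dmap@stride,
                            sigma = dmap@sigma,
                            labelFilter = dmap@labelFilter),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a synthetic slide to disk
#'
#' PNG raster plus CSV nucleus records, CSV severity block grid, and a
#' JSON sidecar (spacing, layout, block size).
#'
#' @param slide a \linkS4class{SyntheticSlide}.
#' @param prefix output path prefix.
#' @export
writeSlide <- function(slide, prefix) {
  writeImage(slideImage(slide), paste0(prefix, ".png"))
  writeNuclei(nuclei(slide), paste0(prefix, "_nuclei.csv"))
  sf <- severityField(slide)
  utils::write.csv(sf@values, paste0(prefix, "_severity.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(spacing = spacing(slide), blockSize = sf@blockSize,
         layout = regionLayout(slide)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Write block scores as CSV (plus the slide score as JSON)
#'
#' Columns \code{block_x}, \code{block_y} (0-based block indices),
#' \code{score}, \code{n_tiles}, \code{is_tumor}.
#'
#' @param bmap a \linkS4class{BlockScoreMap}.
#' @param path output CSV path.
#' @param slideScore optional slide score written to a JSON sidecar.
#' @export
writeBlockScores <- function(bmap, path, slideScore = NULL) {
  s <- blockScores(bmap); n <- tileCounts(bmap); m <- tumorMask(bmap)
  idx <- which(!is.na(s) | n > 0, arr.ind = TRUE)
  writeLines(c("block_x,block_y,score,n_tiles,is_tumor",
               if (nrow(idx))
                 paste(idx[, 2] - 1, idx[, 1] - 1, fmtNum(s[idx]),
                       n[idx], tolower(m[idx]), sep = ",")), path)
  if (!is.null(slideScore))
    jsonlite::write_json(list(slideScore = slideScore),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Write a heatmap PNG plus its legend sidecar
#'
#' @param heatmap array from \code{\link{renderHeatmap}}.
#' @param path output PNG path.
#' @export
writeHeatmap <- function(heatmap, path) {
  writeImage(heatmap, path)
  jsonlite::write_json(attr(heatmap, "legend"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a model checkpoint (JSON, config embedded)
#'
#' Serializes the full parameter set and configuration as JSON text at
#' full double precision, so checkpoints survive text-only transports and
#' round-trip exactly.
#'
#' @param model a \linkS4class{PleoRegressor}.
#' @param path output path.
#' @export
writeModel <- function(model, path) {
  # weights travel as %.17g strings: decimal JSON numbers can lose the
  # last ulp, strings round-trip doubles exactly
  pack <- function(x) fmtNum(as.numeric(x))
  layers <- lapply(model@layers, function(op) {
    if (op$type %in% c("conv", "transition", "linear")) {
      op$W <- pack(op$W); op$b <- pack(op$b)
    } else if (op$type == "denseblock") {
      op$convs <- lapply(op$convs, function(cv)
        list(W = pack(cv$W), b = pack(cv$b)))
    }
    op
  })
  jsonlite::write_json(list(config = model@config, layers = layers),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  model <- buildRegressor(do.call(regressorConfig, p$config))
  layers <- model@layers
  for (i in seq_along(layers)) {
    op <- layers[[i]]
    if (op$type %in% c("conv", "transition", "linear")) {
      layers[[i]]$W <- matrix(as.numeric(p$layers[[i]]$W), nrow(op$W))
      layers[[i]]$b <- as.numeric(p$layers[[i]]$b)
    } else if (op$type == "denseblock") {
      for (l in seq_along(op$convs)) {
        layers[[i]]$convs[[l]]$W <-
          matrix(as.numeric(p$layers[[i]]$convs[[l]]$W),
                 nrow(op$convs[[l]]$W))
        layers[[i]]$convs[[l]]$b <-
          as.numeric(p$layers[[i]]$convs[[l]]$b)
      }
    }
  }
  new("PleoRegressor", config = model@config, layers = layers)
}

#' Write a training history as CSV
#'
#' @param history data.frame from \code{\link{trainRegressor}}.
#' @param path output CSV path.
#' @export
writeTrainingLog <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
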