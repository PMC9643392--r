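# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL uses the ambient stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Ruifrok-Johnson optical-density unit vectors for hematoxylin and eosin.
stainVectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  rbind(hematoxylin = h / sqrt(sum(h^2)), eosin = e / sqrt(sum(e^2)))
}

# Beer-Lambert rendering: two OD channel matrices -> H x W x 3 RGB in [0,1].
odToRGB <- function(odH, odE) {
  sv <- stainVectors()
  img <- array(0, dim = c(nrow(odH), ncol(odH), 3L))
  for (c in 1:3)
    img[, , c] <- exp(-(odH * sv[1, c] + odE * sv[2, c]))
  img
}

# Project an RGB image onto the hematoxylin OD axis.
hematoxylinOD <- function(image) {
  sv <- stainVectors()
  od <- -log(pmax(image, 1 / 255))
  od[, , 1] * sv[1, 1] + od[, , 2] * sv[1, 2] + od[, , 3] * sv[1, 3]
}

# Crop a half-open [x0, x0+w) x [y0, y0+h) window (0-based) from an
# H x W x C array.
cropImage <- function(image, x0, y0, w, h) {
  image[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), , drop = FALSE]
}

stopIfNot <- function(cond, msg, class = "pleoError") {
  if (!cond) stop(errorCondition(msg, class = c(class, "error")))
}

noTumorError <- function(msg = "no tumor detections available") {
  stop(errorCondition(msg, class = c("pleoNoTumorError", "error")))
}

#' Downsample a raster by a factor of two with area averaging
#'
#' Halves the spatial resolution by averaging each 2x2 pixel block, e.g.
#' to bring a 0.25 um/pixel render to the regressor's 0.5 um/pixel input
#' spacing.
#'
#' @param image numeric array \code{H x W x C} (or a matrix) with even
#'   spatial dimensions.
#' @return array (or matrix) of half the spatial size.
#' @export
downsampleByTwo <- function(image) {
  d <- dim(image)
  stopIfNot(d[1] %% 2 == 0 && d[2] %% 2 == 0,
            "spatial dimensions must be even")
  ds <- function(m)
    0.25 * (m[seq(1, d[1], 2), seq(1, d[2], 2)] +
            m[seq(2, d[1], 2), seq(1, d[2], 2)] +
            m[seq(1, d[1], 2), seq(2, d[2], 2)] +
            m[seq(2, d[1], 2), seq(2, d[2], 2)])
  if (length(d) == 2) return(ds(image))
  out <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- ds(image[, , c])
  out
}
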