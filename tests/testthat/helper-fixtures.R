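# Shared fixtures. The trained desk model and its experiment report are
# expensive, so they are built once on first use and cached for the session.

emptyNucleiDf <- function() {
  data.frame(x = numeric(0), y = numeric(0), major = numeric(0),
             minor = numeric(0), orientation = numeric(0),
             label = character(0), contrast = numeric(0))
}

invasiveLayout <- function(size, severity) {
  data.frame(x0 = 0, y0 = 0, x1 = size, y1 = size,
             label = "invasive", severity = severity)
}

smallRoi <- function(severity, size = 128, seed = NULL, spacing = 0.5) {
  generateSlide(invasiveLayout(size, severity), size = size,
                spacing = spacing, seed = seed)
}

# severity-1 "rounds everything to category" helper for constructed panels
zeroNoisePanel <- function(n) {
  data.frame(rater = sprintf("P_%d", seq_len(n)), bias = 0, noiseSd = 0)
}

.fixtureCache <- new.env(parent = emptyenv())

# Reference desk protocol: 125 ROIs in 39 slide groups (52/28/45 split),
# ~3000 training patches, trained desk regressor. One run per session.
deskReport <- function() {
  if (is.null(.fixtureCache$report))
    .fixtureCache$report <- runRoiExperiment(roiExperimentConfig(),
                                             seed = 1)
  .fixtureCache$report
}

deskSlideReport <- function() {
  if (is.null(.fixtureCache$slideReport))
    .fixtureCache$slideReport <- runSlideExperiment(
      deskReport()$model, slideExperimentConfig(), seed = 2)
  .fixtureCache$slideReport
}

# pixel mask of ground-truth nuclei (inner minor-radius squares)
nucleusPixelMask <- function(nucleiDf, size) {
  msk <- matrix(FALSE, size, size)
  for (j in seq_len(nrow(nucleiDf))) {
    xs <- max(1, round(nucleiDf$x[j] - nucleiDf$minor[j])):
          min(size, round(nucleiDf$x[j] + nucleiDf$minor[j]))
    ys <- max(1, round(nucleiDf$y[j] - nucleiDf$minor[j])):
          min(size, round(nucleiDf$y[j] + nucleiDf$minor[j]))
    msk[ys, xs] <- TRUE
  }
  msk
}
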