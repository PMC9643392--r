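#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("nuclei", function(x) standardGeneric("nuclei"))

#' @rdname accessors
#' @export
setGeneric("slideImage", function(x) standardGeneric("slideImage"))

#' @rdname accessors
#' @export
setGeneric("severityField", function(x) standardGeneric("severityField"))

#' @rdname accessors
#' @export
setGeneric("regionLayout", function(x) standardGeneric("regionLayout"))

#' @rdname accessors
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("confidenceMatrix", function(x) standardGeneric("confidenceMatrix"))

#' @rdname accessors
#' @export
setGeneric("itemNames", function(x) standardGeneric("itemNames"))

#' @rdname accessors
#' @export
setGeneric("raterNames", function(x) standardGeneric("raterNames"))

#' @rdname accessors
#' @export
setGeneric("blockScores", function(x) standardGeneric("blockScores"))

#' @rdname accessors
#' @export
setGeneric("tileCounts", function(x) standardGeneric("tileCounts"))

#' @rdname accessors
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))

#' @rdname accessors
#' @export
setGeneric("blockSize", function(x) standardGeneric("blockSize"))

#' @rdname accessors
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

#' Predict the continuous pleomorphism score of a single patch
#'
#' Runs the regressor forward on one patch and clamps the raw output to the
#' score range [1, 3].
#'
#' @param model a \linkS4class{PleoRegressor} or \linkS4class{ConstantModel}.
#' @param patch numeric array \code{H x W x 3} in [0, 1] matching the
#'   configured input size.
#' @return a single score in [1, 3].
#' @export
setGeneric("predictPatch", function(model, patch)
  standardGeneric("predictPatch"))
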