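confidenceLevels <- c("not_certain", "fairly_certain", "certain")

#' Construct a PanelScores object
#'
#' @param scores items x raters matrix (or data.frame) of scores in
#'   {1, 2, 3}; dimnames supply item and rater identifiers.
#' @param confidence optional character matrix of the same shape with
#'   entries \code{not_certain}, \code{fairly_certain}, \code{certain} or
#'   \code{NA}.
#' @return a \linkS4class{PanelScores}.
#' @export
PanelScores <- function(scores, confidence = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (is.null(rownames(scores)))
    rownames(scores) <- sprintf("item_%03d", seq_len(nrow(scores)))
  if (is.null(colnames(scores)))
    colnames(scores) <- sprintf("P_%d", seq_len(ncol(scores)))
  if (is.null(confidence)) {
    confidence <- matrix(character(0), 0, 0)
  } else {
    confidence <- as.matrix(confidence)
    dimnames(confidence) <- dimnames(scores)
  }
  new("PanelScores", scores = scores, confidence = confidence)
}

#' Average-pooled continuous reference score
#'
#' The continuous reference label of an item is the arithmetic mean of the
#' panel's discrete scores for that item, yielding values on the full
#' severity spectrum [1, 3] rather than a forced majority category.
#'
#' @param panel a \linkS4class{PanelScores}.
#' @param item optional item identifier (or index); when omitted the
#'   reference scores of all items are returned as a named vector.
#' @return numeric reference score(s) in [1, 3].
#' @export
referenceScore <- function(panel, item = NULL) {
  s <- scoreMatrix(panel)
  if (!is.null(item)) {
    if (is.character(item))
      stopIfNot(item %in% rownames(s), sprintf("unknown item '%s'", item),
                class = "pleoLookupError")
    else
      stopIfNot(item >= 1 && item <= nrow(s), "item index out of range",
                class = "pleoLookupError")
    s <- s[item, , drop = FALSE]
  }
  rowMeans(s)
}

confidenceWeights <- function(confidence) {
  w <- match(confidence, confidenceLevels)
  w[is.na(w)] <- 2L  # unstated confidence counts as the middle level
  w
}

#' Majority vote with confidence-weighted tie-breaking
#'
#' Returns the modal category of a set of discrete scores. Ties between
#' categories are broken by the larger sum of ordinal confidence weights
#' (not_certain = 1, fairly_certain = 2, certain = 3) among the tied
#' categories; residual ties go to the tied category nearest the panel
#' mean, and then to the lower category.
#'
#' @param scores vector of scores in {1, 2, 3}.
#' @param confidences optional vector of confidence levels aligned 1:1 with
#'   \code{scores}.
#' @return a single category in {1, 2, 3}.
#' @export
majorityVote <- function(scores, confidences = NULL) {
  stopIfNot(length(scores) >= 1, "at least one score is required")
  stopIfNot(all(scores %in% 1:3), "scores must be 1, 2 or 3")
  if (!is.null(confidences))
    stopIfNot(length(confidences) == length(scores),
              "confidences must align 1:1 with scores")
  counts <- tabulate(scores, 3L)
  tied <- which(counts == max(counts))
  if (length(tied) == 1L) return(tied)
  if (!is.null(confidences)) {
    w <- confidenceWeights(confidences)
    wsum <- vapply(tied, function(k) sum(w[scores == k]), numeric(1))
    tied <- tied[wsum == max(wsum)]
    if (length(tied) == 1L) return(tied)
  }
  dist <- abs(tied - mean(scores))
  tied <- tied[dist == min(dist)]
  min(tied)
}

#' Leave-one-out majority categories
#'
#' Per-item majority vote over all raters except the excluded one, so a
#' rater compared against the majority never contributes to it.
#'
#' @param panel a \linkS4class{PanelScores} with at least two raters.
#' @param excludedRater rater identifier or column index to exclude.
#' @return named integer vector of per-item categories.
#' @export
leaveOneOutMajority <- function(panel, excludedRater) {
  s <- scoreMatrix(panel)
  cf <- confidenceMatrix(panel)
  stopIfNot(ncol(s) >= 2, "cannot exclude the only rater")
  if (is.character(excludedRater))
    excludedRater <- match(excludedRater, colnames(s))
  stopIfNot(!is.na(excludedRater) && excludedRater >= 1 &&
            excludedRater <= ncol(s), "unknown rater")
  keep <- setdiff(seq_len(ncol(s)), excludedRater)
  out <- vapply(seq_len(nrow(s)), function(i) {
    conf <- if (length(cf)) cf[i, keep] else NULL
    majorityVote(s[i, keep], conf)
  }, integer(1))
  names(out) <- rownames(s)
  out
}

#' Cohen's quadratic weighted kappa
#'
#' Chance-corrected agreement between two ordinal categorical vectors with
#' quadratic disagreement weights \code{w_ij = (i - j)^2 / (k - 1)^2}:
#' kappa = 1 - (observed weighted disagreement) / (chance-expected weighted
#' disagreement from the marginals). When both raters are constant the
#' chance-expected disagreement is zero and the kappa is undefined; this is
#' signalled explicitly (\code{NA} with a \code{pleoUndefinedKappaWarning})
#' rather than silently mapped to a number.
#'
#' @param a,b equal-length categorical vectors.
#' @param categories ordered category set (default 1:3).
#' @return kappa in [-1, 1], or \code{NA} with a warning when undefined.
#' @export
quadraticKappa <- function(a, b, categories = 1:3) {
  stopIfNot(length(a) == length(b) && length(a) >= 2,
            "a and b must have equal length >= 2")
  stopIfNot(all(a %in% categories) && all(b %in% categories),
            "entries must be within the category set")
  k <- length(categories)
  i <- match(a, categories)
  j <- match(b, categories)
  n <- length(i)
  W <- outer(seq_len(k), seq_len(k), function(x, y) (x - y)^2 / (k - 1)^2)
  O <- matrix(0, k, k)
  for (t in seq_len(n)) O[i[t], j[t]] <- O[i[t], j[t]] + 1
  E <- outer(rowSums(O), colSums(O)) / n
  denom <- sum(E * W)
  if (denom == 0) {
    warning(warningCondition(
      "kappa undefined: both raters are constant (no chance disagreement)",
      class = c("pleoUndefinedKappaWarning", "warning")))
    return(NA_real_)
  }
  1 - sum(O * W) / denom
}

#' Pairwise quadratic-kappa report for a panel (plus an optional extra rater)
#'
#' Computes the symmetric matrix of pairwise quadratic kappas over all
#' raters (and an optional extra score vector, e.g. the quantized
#' predictions of an automated scorer), each rater's mean pairwise kappa
#' (excluding self and the majority column), and each rater's kappa against
#' the leave-one-out majority. Undefined kappas propagate as \code{NA}.
#'
#' @param panel a \linkS4class{PanelScores}.
#' @param extraRater optional vector of categories, one per item.
#' @param extraName column name for the extra rater.
#' @return list with \code{kappa} (square matrix), \code{majority} (named
#'   vector of kappas vs leave-one-out majority) and \code{meanKappa}
#'   (named vector of per-rater mean pairwise kappas).
#' @export
pairwiseKappaReport <- function(panel, extraRater = NULL,
                                extraName = "AI") {
  s <- scoreMatrix(panel)
  stopIfNot(ncol(s) >= 2, "need at least two raters")
  cols <- lapply(seq_len(ncol(s)), function(j) s[, j])
  names(cols) <- colnames(s)
  if (!is.null(extraRater)) {
    stopIfNot(length(extraRater) == nrow(s),
              "extraRater must score every item")
    cols[[extraName]] <- as.integer(extraRater)
  }
  R <- length(cols)
  K <- matrix(NA_real_, R, R, dimnames = list(names(cols), names(cols)))
  for (i in seq_len(R)) {
    K[i, i] <- 1
    for (j in seq_len(R)[-seq_len(i)]) {
      K[i, j] <- K[j, i] <- suppressWarnings(
        quadraticKappa(cols[[i]], cols[[j]]))
    }
  }
  maj <- vapply(seq_len(R), function(i) {
    ref <- if (names(cols)[i] %in% colnames(s))
      leaveOneOutMajority(panel, names(cols)[i])
    else
      vapply(seq_len(nrow(s)), function(r) {
        cf <- confidenceMatrix(panel)
        majorityVote(s[r, ], if (length(cf)) cf[r, ] else NULL)
      }, integer(1))
    suppressWarnings(quadraticKappa(cols[[i]], ref))
  }, numeric(1))
  names(maj) <- names(cols)
  meanK <- vapply(seq_len(R), function(i)
    mean(K[i, -i], na.rm = TRUE), numeric(1))
  names(meanK) <- names(cols)
  list(kappa = K, majority = maj, meanKappa = meanK)
}

#' Default rater panel configuration
#'
#' Fixed per-rater bias and noise parameters emulating a panel with varying
#' strictness and consistency; biases are spread symmetrically in
#' [-0.25, 0.25] severity units and score noise standard deviations in
#' [0.25, 0.45].
#'
#' @param nRaters number of raters.
#' @return data.frame with columns \code{rater}, \code{bias},
#'   \code{noiseSd}.
#' @export
raterPanel <- function(nRaters = 10) {
  data.frame(rater = sprintf("P_%d", seq_len(nRaters)),
             bias = seq(-0.25, 0.25, length.out = nRaters),
             noiseSd = seq(0.25, 0.45, length.out = nRaters),
             stringsAsFactors = FALSE)
}

#' Simulate a discrete rater panel from continuous true severities
#'
#' Rater g scores item i by quantizing
#' \code{clamp(s_i + bias_g + e, 1, 3)} with \code{e ~ N(0, noiseSd_g)}
#' into the three standard brackets. The reported confidence falls with the
#' distance of the perceived severity to the nearest bracket edge (certain
#' beyond 0.20, fairly_certain beyond 0.08, not_certain otherwise).
#'
#' @param trueScores vector of continuous severities in [1, 3].
#' @param raters data.frame as from \code{\link{raterPanel}}.
#' @param seed optional integer seed.
#' @param withConfidence record confidences?
#' @return a \linkS4class{PanelScores}.
#' @export
simulatePanel <- function(trueScores, raters = raterPanel(), seed = NULL,
                          withConfidence = TRUE) {
  stopIfNot(all(trueScores >= 1 & trueScores <= 3),
            "true scores must lie in [1, 3]")
  nI <- length(trueScores); nR <- nrow(raters)
  scheme <- quantizationScheme(3)
  withSeed(seed, {
    sc <- matrix(0L, nI, nR)
    cf <- matrix(NA_character_, nI, nR)
    for (g in seq_len(nR)) {
      perceived <- clamp(trueScores + raters$bias[g] +
                           rnorm(nI, 0, raters$noiseSd[g]), 1, 3)
      sc[, g] <- quantize(perceived, scheme)
      edges <- scheme@edges[2:scheme@p]
      d <- vapply(perceived, function(v) min(abs(v - edges)), numeric(1))
      cf[, g] <- ifelse(d >= 0.20, "certain",
                        ifelse(d >= 0.08, "fairly_certain", "not_certain"))
    }
    rownames(sc) <- names(trueScores)
    colnames(sc) <- raters$rater
    PanelScores(sc, if (withConfidence) cf else NULL)
  })
}
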