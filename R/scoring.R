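## The Dentist metric and its component scores.
##
## The automated score combines precision (penalizes under-drilling) and
## sensitivity (penalizes over-drilling), linearly rescaled onto a common
## range and flipped onto the 0-15 clinical rubric scale:
##
##   D = (1 - (1.5 * Stilde + Ptilde) / 2.5) * 15
##
## which, expanded in the raw confusion counts, is identically
##
##   D = 15 (32 FP TP + 3 FN TP + 35 FN FP) / (4 (TP + FN)(TP + FP)).

P_ANCHOR <- 0.95   # lower rescale anchor for precision
S_ANCHOR <- 0.2    # lower rescale anchor for sensitivity

#' Precision/sensitivity component scores
#'
#' Computes `P = TP/(TP+FP)`, `S = TP/(TP+FN)` and their linear
#' rescalings `Ptilde = (P - 0.95)/0.05` and `Stilde = (S - 0.2)/0.8`.
#' Empirically, student outcomes concentrate in `P` close to (0.96,
#' 0.995] and `S` in (0.2, 1); inputs outside these windows are legal,
#' yield rescaled values outside `[0, 1]`, and raise a warning (never an
#' error, and never clamping).
#'
#' @param counts A [ClassificationCounts-class].
#' @param warn Warn when `P` or `S` falls below its rescale anchor.
#' @return A [ComponentScores-class].
#' @examples
#' componentScores(ClassificationCounts(TP = 1000, TN = 780, FP = 20, FN = 200))
#' @export
componentScores <- function(counts, warn = TRUE) {
  validObject(counts)
  TP <- counts@TP; FP <- counts@FP; FN <- counts@FN
  if (TP + FP == 0)
    stop("precision undefined: TP + FP = 0 (no undrilled voxels in outcome)")
  if (TP + FN == 0)
    stop("sensitivity undefined: TP + FN = 0 (empty ideal outcome)")
  P <- TP / (TP + FP)
  S <- TP / (TP + FN)
  if (warn && (P < P_ANCHOR || S < S_ANCHOR))
    warning(sprintf(
      "component score outside its empirical window (P = %.4f, S = %.4f); %s",
      P, S, "rescaled values and Dentist score will exceed their nominal range"),
      call. = FALSE)
  new("ComponentScores", P = P, S = S,
      Ptilde = (P - P_ANCHOR) / (1 - P_ANCHOR),
      Stilde = (S - S_ANCHOR) / (1 - S_ANCHOR))
}

#' The Dentist score from component scores
#'
#' Evaluates `D = (1 - (1.5 * Stilde + Ptilde) / 2.5) * 15`: a weighted
#' mean of the rescaled sensitivity and precision, flipped to a distance
#' (lower is better) and scaled to the 0-15 expert rubric.  `D = 0` at a
#' perfect outcome (`P = S = 1`) and `D = 15` at the lower rescale
#' anchors (`S = 0.2`, `P = 0.95`).  The value is not clamped.
#'
#' @param components A [ComponentScores-class] (or a
#'   [ClassificationCounts-class], converted via [componentScores()]).
#' @return A single numeric Dentist score.
#' @examples
#' cs <- componentScores(ClassificationCounts(1000, 780, 20, 200))
#' dentistScore(cs)   # ~ 4.2279
#' @export
dentistScore <- function(components) {
  if (is(components, "ClassificationCounts"))
    components <- componentScores(components, warn = FALSE)
  stopifnot(is(components, "ComponentScores"))
  st <- components@Stilde; pt <- components@Ptilde
  if (!is.finite(st) || !is.finite(pt))
    stop("component scores must be finite")
  (1 - (1.5 * st + pt) / 2.5) * 15
}

#' The Dentist score directly from confusion counts
#'
#' Closed form of the same score,
#' `D = 15 (32 FP TP + 3 FN TP + 35 FN FP) / (4 (TP+FN)(TP+FP))`,
#' algebraically identical to [dentistScore()] composed with
#' [componentScores()].
#'
#' @param counts A [ClassificationCounts-class].
#' @return A single numeric Dentist score.
#' @examples
#' dentistScoreFromCounts(ClassificationCounts(1000, 780, 20, 200)) # ~4.2279
#' @export
dentistScoreFromCounts <- function(counts) {
  validObject(counts)
  TP <- counts@TP; FP <- counts@FP; FN <- counts@FN
  if (TP + FP == 0 || TP + FN == 0)
    stop("Dentist score undefined: TP + FP and TP + FN must both be > 0")
  15 * (32 * FP * TP + 3 * FN * TP + 35 * FN * FP) /
    (4 * (TP + FN) * (TP + FP))
}

#' F1 baseline score
#'
#' The harmonic mean of sensitivity and precision,
#' `F1 = 2 TP / (2 TP + FP + FN)`; a similarity (higher is better), used
#' as the established baseline the Dentist score is compared against and
#' as the ranking metric for essential-outcome selection.
#'
#' @param counts A [ClassificationCounts-class].
#' @return F1 in `[0, 1]`.
#' @examples
#' f1Score(ClassificationCounts(1000, 780, 20, 200))  # ~0.9009
#' @export
f1Score <- function(counts) {
  validObject(counts)
  TP <- counts@TP; FP <- counts@FP; FN <- counts@FN
  if (2 * TP + FP + FN == 0)
    stop("F1 undefined: 2*TP + FP + FN = 0")
  2 * TP / (2 * TP + FP + FN)
}
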