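#' Select essential outcomes uniformly covering the score range
#'
#' Reduces a set of scored outcomes to `k` representatives that cover the
#' observed score range as uniformly as possible, the subset handed to
#' expert raters for validation.  The observed range `[min, max]` is
#' partitioned into `k` equal-width bins; from each non-empty bin the
#' sample nearest the bin centre is taken (ties resolved to the lowest
#' index), and every empty bin is back-filled with the globally unused
#' sample nearest that bin's centre.
#'
#' @param scores Finite numeric scores (any orientation).
#' @param k Number of outcomes to select; must not exceed the number of
#'   scores nor the number of *distinct* scores.
#' @return Integer vector of `k` distinct 1-based indices into `scores`,
#'   ordered by bin.
#' @examples
#' set.seed(1)
#' s <- runif(240)
#' sel <- selectEssentialOutcomes(s, 20)
#' range(s[sel])
#' @export
selectEssentialOutcomes <- function(scores, k) {
  assertFinite(scores, "scores")
  assertCount(k, "k")
  n <- length(scores)
  if (k > n)
    stop("k (", k, ") exceeds the number of scores (", n, ")")
  nDistinct <- length(unique(scores))
  if (k > nDistinct)
    stop("k (", k, ") exceeds the number of distinct scores (",
         nDistinct, ")")
  lo <- min(scores); hi <- max(scores)
  if (hi == lo) return(1L)                  # k == 1 guaranteed here

  width <- (hi - lo) / k
  centers <- lo + (seq_len(k) - 0.5) * width
  bin <- pmin(pmax(ceiling((scores - lo) / width), 1L), k)

  chosen <- integer(0)
  pickNearest <- function(cands, center) {
    d <- abs(scores[cands] - center)
    cands[which.min(d)]                     # which.min takes first = lowest idx
  }
  emptyBins <- integer(0)
  for (b in seq_len(k)) {
    cands <- which(bin == b)
    if (length(cands) == 0L) { emptyBins <- c(emptyBins, b); next }
    chosen <- c(chosen, pickNearest(cands, centers[b]))
  }
  for (b in emptyBins) {
    unused <- setdiff(seq_len(n), chosen)
    chosen <- c(chosen, pickNearest(unused, centers[b]))
  }
  ## report in bin order
  chosen[order(centers[c(setdiff(seq_len(k), emptyBins), emptyBins)])]
}
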