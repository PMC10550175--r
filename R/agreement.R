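## Expert rubric encoding and the inter-rater statistics used to anchor
## the automated score to expert judgment.

#' Total rubric error for one rating
#'
#' Sums the five per-surface error categories (four cardinal walls plus
#' pulp floor, each 0-3), giving a total error between 0 and 15; lower is
#' better.
#'
#' @param rating An [ExpertRating-class].
#' @return Integer in `[0, 15]`.
#' @examples
#' expertTotalError(ExpertRating(c(3, 3, 3, 3, 3)))  # 15
#' @export
expertTotalError <- function(rating) {
  validObject(rating)
  sum(rating@surfaceErrors)
}

#' Mean expert error over multiple raters
#'
#' The per-outcome error used in downstream analyses is the arithmetic
#' mean of the raters' totals; with two raters this can be a
#' half-integer.
#'
#' @param ratings Non-empty list of [ExpertRating-class] objects for one
#'   outcome.
#' @return Single numeric mean total error.
#' @examples
#' meanExpertError(list(ExpertRating(c(1, 1, 2, 1, 1)), # total 6
#'                      ExpertRating(c(2, 1, 2, 1, 1)))) # total 7 -> 6.5
#' @export
meanExpertError <- function(ratings) {
  if (length(ratings) == 0L) stop("at least one rating is required")
  mean(vapply(ratings, expertTotalError, numeric(1)))
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement over the observed category set.  For the
#' ordinal 0-15 rubric totals the default is linear disagreement weights
#' on the numeric category values; `weighting = "none"` gives the
#' classical unweighted kappa.  (For two categories the two coincide.)
#'
#' @param raterA,raterB Equal-length integer/numeric score vectors,
#'   `n >= 2`.
#' @param weighting `"linear"` (default) or `"none"`.
#' @return Kappa in `[-1, 1]`, or an [undefinedValue()] marker when the
#'   marginals are degenerate (a single category observed).
#' @examples
#' cohensKappa(c(0, 1, 0, 1), c(0, 1, 1, 1), weighting = "none")  # 0.5
#' @export
cohensKappa <- function(raterA, raterB, weighting = c("linear", "none")) {
  weighting <- match.arg(weighting)
  if (length(raterA) != length(raterB))
    stop("rater score vectors must have equal length")
  if (length(raterA) < 2L) stop("need n >= 2 paired scores")
  assertFinite(raterA, "raterA"); assertFinite(raterB, "raterB")

  cats <- sort(unique(c(raterA, raterB)))
  k <- length(cats)
  if (k == 1L)
    return(undefinedValue("only one category observed; kappa undefined"))
  n <- length(raterA)
  O <- table(factor(raterA, levels = cats), factor(raterB, levels = cats)) / n
  pa <- rowSums(O); pb <- colSums(O)
  E <- outer(pa, pb)
  W <- if (weighting == "linear") {
    abs(outer(cats, cats, "-")) / (max(cats) - min(cats))
  } else {
    1 - diag(k)
  }
  do <- sum(W * O); de <- sum(W * E)
  if (de == 0)
    return(undefinedValue("degenerate marginals (expected disagreement 0)"))
  1 - do / de
}

#' Two-rater intraclass correlation
#'
#' Two-way random-effects ICC from the classical mean-squares
#' decomposition (subjects crossed with raters).  `ICC(2,1)` is the
#' absolute-agreement reliability of a single rating (the default);
#' `ICC(2,k)` the reliability of the mean of the k ratings.
#'
#' @param raterA,raterB Scores for the same `n >= 3` subjects.
#' @param model `"ICC(2,1)"` or `"ICC(2,k)"`.
#' @return The ICC (at most 1), or an [undefinedValue()] marker when the
#'   between-subject variance is zero.
#' @examples
#' iccTwoRater(c(1, 3, 5, 7), c(2, 4, 5, 8))
#' @export
iccTwoRater <- function(raterA, raterB, model = c("ICC(2,1)", "ICC(2,k)")) {
  model <- match.arg(model)
  if (length(raterA) != length(raterB))
    stop("rater score vectors must have equal length")
  n <- length(raterA)
  if (n < 3L) stop("need n >= 3 subjects")
  assertFinite(raterA, "raterA"); assertFinite(raterB, "raterB")

  X <- cbind(raterA, raterB)
  k <- 2L
  g <- mean(X)
  subjMean <- rowMeans(X)
  raterMean <- colMeans(X)
  SSR <- k * sum((subjMean - g)^2)             # between subjects
  SSC <- n * sum((raterMean - g)^2)            # between raters
  SST <- sum((X - g)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR == 0)
    return(undefinedValue("zero between-subject variance; ICC undefined"))
  icc <- if (model == "ICC(2,1)") {
    (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  } else {
    (MSR - MSE) / (MSR + (MSC - MSE) / n)
  }
  icc
}

#' Information-based measure of disagreement (IBMD)
#'
#' Mean over paired observations of
#' `log(|x_i - y_i| + 1) / log(max(x_i, y_i) + 1)` (natural logarithms),
#' with the pair term defined as 0 when `x_i = y_i = 0`.  Zero iff the
#' raters agree on every pair; larger values mean more disagreement.
#'
#' @param x,y Equal-length non-negative score vectors.
#' @return A single non-negative numeric.
#' @examples
#' ibmd(c(2), c(4))   # log(3)/log(5)
#' @export
ibmd <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0L) stop("need at least one pair")
  assertFinite(x, "x"); assertFinite(y, "y")
  if (any(x < 0) || any(y < 0)) stop("IBMD requires non-negative scores")
  term <- numeric(length(x))
  nonzero <- pmax(x, y) > 0
  term[nonzero] <- log(abs(x[nonzero] - y[nonzero]) + 1) /
    log(pmax(x[nonzero], y[nonzero]) + 1)
  mean(term)
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation with its two-sided p-value, as used for
#' anchoring the automated score to expert ratings and for the
#' transfer/suitability analyses.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return List with elements `r`, `p` and `n`; `r` and `p` are
#'   [undefinedValue()] markers when either variance is zero.
#' @examples
#' pearsonCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4))$r  # 0.8
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need n >= 3 pairs")
  assertFinite(x, "x"); assertFinite(y, "y")
  if (sd(x) == 0 || sd(y) == 0) {
    u <- undefinedValue("zero variance; correlation undefined")
    return(list(r = u, p = u, n = n))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
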