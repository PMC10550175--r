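#' Agreement report between experts and the automated score
#'
#' Bundles the validation statistics computed on a set of outcomes rated
#' by two experts and by the automated score: inter-expert Cohen's kappa
#' and ICC(2,1), plus the information-based measure of disagreement and
#' the Pearson correlation between the experts' mean error and the
#' automated score.
#'
#' @param expert1,expert2 Total rubric errors (0-15) from each expert,
#'   one per outcome, `n >= 3`.
#' @param auto Automated (Dentist) scores for the same outcomes; may be
#'   `NULL` to report inter-expert agreement only.
#' @param kappaWeighting Passed to [cohensKappa()].
#' @return List with `n`, `kappa`, `icc`, and — when `auto` is given —
#'   `ibmd` (mean expert error vs automated score) and `pearson`
#'   (`r`, `p`).  Undefined statistics appear as [undefinedValue()]
#'   markers.
#' @examples
#' e1 <- c(2, 5, 9, 12, 3, 7); e2 <- c(3, 5, 8, 12, 4, 7)
#' agreementReport(e1, e2, auto = (e1 + e2) / 2 + 0.3)
#' @export
agreementReport <- function(expert1, expert2, auto = NULL,
                            kappaWeighting = "linear") {
  if (length(expert1) != length(expert2))
    stop("expert score vectors must have equal length")
  n <- length(expert1)
  if (n < 3L) stop("need n >= 3 rated outcomes")
  rep <- list(
    n = n,
    kappa = cohensKappa(expert1, expert2, weighting = kappaWeighting),
    icc = iccTwoRater(expert1, expert2, model = "ICC(2,1)"))
  if (!is.null(auto)) {
    if (length(auto) != n)
      stop("auto scores must match the number of outcomes")
    meanExp <- (expert1 + expert2) / 2
    rep$ibmd <- ibmd(meanExp, pmax(auto, 0))
    rep$pearson <- pearsonCorrelation(meanExp, auto)
  }
  rep
}
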