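#' Suite of standard binary-classification metrics
#'
#' Evaluates 24 established binary-classification metrics on a confusion
#' table, the comparison pool from which the F1 baseline was chosen.  The
#' exact historical list is not canonical, so this suite is a declared
#' superset of the common choices; entries whose denominator vanishes are
#' reported as `NA` with an explanatory note, never silently as 0.
#'
#' @param counts A [ClassificationCounts-class].
#' @return A `data.frame` with columns `metric`, `value` and `note`
#'   (empty string when defined).  Rows: accuracy, balanced_accuracy,
#'   precision, recall, specificity, npv, f1, jaccard, threat_score, mcc,
#'   cohen_kappa, informedness, markedness, fowlkes_mallows, g_mean,
#'   prevalence, fpr, fnr, fdr, for, lr_plus, lr_minus, dor,
#'   prevalence_threshold.
#' @examples
#' ms <- metricSuite(ClassificationCounts(1000, 780, 20, 200))
#' ms[ms$metric == "jaccard", ]
#' @export
metricSuite <- function(counts) {
  validObject(counts)
  TP <- counts@TP; TN <- counts@TN; FP <- counts@FP; FN <- counts@FN
  n <- TP + TN + FP + FN

  out <- list()
  add <- function(name, num, den, value = NULL, note = "") {
    if (is.null(value)) {
      if (den == 0) {
        value <- NA_real_
        if (note == "") note <- "zero denominator"
      } else value <- num / den
    }
    out[[length(out) + 1L]] <<- data.frame(
      metric = name, value = value, note = note,
      stringsAsFactors = FALSE)
  }

  if (n == 0) stop("all counts are zero")

  tpr <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  tnr <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  fpr <- if (TN + FP > 0) FP / (TN + FP) else NA_real_
  fnr <- if (TP + FN > 0) FN / (TP + FN) else NA_real_
  ppv <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  npv <- if (TN + FN > 0) TN / (TN + FN) else NA_real_

  add("accuracy", TP + TN, n)
  if (is.na(tpr) || is.na(tnr))
    add("balanced_accuracy", 0, 0, NA_real_, "TPR or TNR undefined")
  else add("balanced_accuracy", tpr + tnr, 2, (tpr + tnr) / 2)
  add("precision", TP, TP + FP)
  add("recall", TP, TP + FN)
  add("specificity", TN, TN + FP)
  add("npv", TN, TN + FN)
  add("f1", 2 * TP, 2 * TP + FP + FN)
  add("jaccard", TP, TP + FP + FN)
  add("threat_score", TP, TP + FP + FN)

  mccDen <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  if (mccDen == 0) add("mcc", 0, 0, NA_real_, "a marginal total is zero")
  else add("mcc", TP * TN - FP * FN, mccDen)

  ## Cohen's kappa of the 2x2 table: observed vs chance agreement
  pe <- ((TP + FP) * (TP + FN) + (TN + FN) * (TN + FP)) / n^2
  po <- (TP + TN) / n
  if (pe == 1) add("cohen_kappa", 0, 0, NA_real_,
                   "degenerate marginals (chance agreement = 1)")
  else add("cohen_kappa", po - pe, 1 - pe)

  if (is.na(tpr) || is.na(tnr)) {
    add("informedness", 0, 0, NA_real_, "TPR or TNR undefined")
    add("g_mean", 0, 0, NA_real_, "TPR or TNR undefined")
  } else {
    add("informedness", 1, 1, tpr + tnr - 1)
    add("g_mean", 1, 1, sqrt(tpr * tnr))
  }
  if (is.na(ppv) || is.na(npv))
    add("markedness", 0, 0, NA_real_, "PPV or NPV undefined")
  else add("markedness", 1, 1, ppv + npv - 1)
  if (is.na(ppv) || is.na(tpr))
    add("fowlkes_mallows", 0, 0, NA_real_, "PPV or TPR undefined")
  else add("fowlkes_mallows", 1, 1, sqrt(ppv * tpr))

  add("prevalence", TP + FN, n)
  add("fpr", FP, TN + FP)
  add("fnr", FN, TP + FN)
  add("fdr", FP, TP + FP)
  add("for", FN, TN + FN)

  if (is.na(fpr) || is.na(tpr)) {
    add("lr_plus", 0, 0, NA_real_, "TPR or FPR undefined")
    add("prevalence_threshold", 0, 0, NA_real_, "TPR or FPR undefined")
  } else if (fpr == 0) {
    add("lr_plus", 0, 0, NA_real_, "FPR = 0 (likelihood ratio infinite)")
    if (tpr == 0)
      add("prevalence_threshold", 0, 0, NA_real_, "TPR = FPR = 0")
    else add("prevalence_threshold", 1, 1, 0)
  } else {
    add("lr_plus", tpr, fpr)
    if (tpr == fpr)
      add("prevalence_threshold", 0, 0, NA_real_, "TPR = FPR")
    else add("prevalence_threshold", 1, 1,
             (sqrt(tpr * fpr) - fpr) / (tpr - fpr))
  }
  if (is.na(fnr) || is.na(tnr))
    add("lr_minus", 0, 0, NA_real_, "FNR or TNR undefined")
  else if (tnr == 0)
    add("lr_minus", 0, 0, NA_real_, "TNR = 0")
  else add("lr_minus", fnr, tnr)

  if (FP == 0 || FN == 0 || is.na(tnr))
    add("dor", 0, 0, NA_real_, "FP or FN is zero (odds ratio infinite)")
  else add("dor", TP * TN, FP * FN)

  do.call(rbind, out)
}
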