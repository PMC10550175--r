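## Cohort-level suitability and transfer analyses.

GROUP_LEVELS <- c("stereo_aligned", "mono_aligned",
                  "stereo_misaligned", "mono_misaligned")

groupRendering <- function(group)
  ifelse(grepl("^stereo", as.character(group)), "stereo", "mono")

groupAlignment <- function(group)
  ifelse(grepl("misaligned$", as.character(group)), "misaligned", "aligned")

#' Suitability-for-assessment and learning-transfer correlations
#'
#' Runs the two cohort correlation analyses per stratum (all
#' participants, by 3D rendering mode, by hand-tool alignment, and by
#' condition group):
#'
#' * **suitability**: Pearson correlation of the pre-test expert error
#'   `e0` with initial in-simulator performance (mean of the day-1
#'   trials 1-3 by default, or trial 1 only) — does pre-existing
#'   real-world skill show up in the simulator?
#' * **transfer**: Pearson correlation of the real learning gain
#'   `e1 - e0` with the simulator gain `t6 - t1` — do in-simulator
#'   improvements track real-world improvements?
#'
#' @param cohort `data.frame` with columns `group` (one of
#'   `stereo_aligned`, `mono_aligned`, `stereo_misaligned`,
#'   `mono_misaligned`), `e0`, `e1` and `t1` ... `t6`; see
#'   [generateCohort()].
#' @param day1 `"mean13"` (mean of trials 1-3, default) or `"trial1"`
#'   as the measure of initial simulator performance.
#' @param removeOutliers Drop participants whose learning gain falls
#'   outside the Tukey fences ([iqrOutlierFilter()]) before any analysis
#'   (default `TRUE`, mirroring the usual pre-processing).
#' @return `data.frame` with columns `stratum`, `level`, `analysis`
#'   (`"suitability"`/`"transfer"`), `n`, `r`, `p`.  Strata with fewer
#'   than 3 usable participants or zero variance are reported with `NA`
#'   and a `note`.  The removed learning gains are attached as attribute
#'   `"removedGains"`.
#' @export
transferAnalyses <- function(cohort, day1 = c("mean13", "trial1"),
                             removeOutliers = TRUE) {
  day1 <- match.arg(day1)
  need <- c("group", "e0", "e1", paste0("t", 1:6))
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns ", paste(need, collapse = ", "))

  gain <- learningGain(cohort$e0, cohort$e1)
  removed <- numeric(0)
  if (removeOutliers && length(gain) >= 4L) {
    filt <- iqrOutlierFilter(gain)
    keep <- gain >= filt$fences["lower"] & gain <= filt$fences["upper"]
    removed <- filt$removed
    cohort <- cohort[keep, , drop = FALSE]
    gain <- gain[keep]
  }
  simStart <- if (day1 == "mean13")
    rowMeans(cohort[, c("t1", "t2", "t3")]) else cohort$t1
  simGain <- cohort$t6 - cohort$t1

  strata <- list(
    list(stratum = "all", level = "all", idx = seq_len(nrow(cohort))))
  rend <- groupRendering(cohort$group)
  alg <- groupAlignment(cohort$group)
  for (lv in c("stereo", "mono"))
    strata[[length(strata) + 1L]] <-
      list(stratum = "rendering", level = lv, idx = which(rend == lv))
  for (lv in c("aligned", "misaligned"))
    strata[[length(strata) + 1L]] <-
      list(stratum = "alignment", level = lv, idx = which(alg == lv))
  for (lv in intersect(GROUP_LEVELS, unique(as.character(cohort$group))))
    strata[[length(strata) + 1L]] <-
      list(stratum = "group", level = lv,
           idx = which(as.character(cohort$group) == lv))

  rows <- list()
  addRow <- function(st, analysis, x, y) {
    n <- length(st$idx)
    note <- ""
    r <- p <- NA_real_
    if (n < 3L) {
      note <- "stratum too small (n < 3)"
    } else {
      pc <- pearsonCorrelation(x[st$idx], y[st$idx])
      if (isUndefined(pc$r)) note <- undefinedReason(pc$r)
      else { r <- pc$r; p <- pc$p }
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      stratum = st$stratum, level = st$level, analysis = analysis,
      n = n, r = r, p = p, note = note, stringsAsFactors = FALSE)
  }
  for (st in strata) {
    addRow(st, "suitability", cohort$e0, simStart)
    addRow(st, "transfer", gain, simGain)
  }
  out <- do.call(rbind, rows)
  attr(out, "removedGains") <- removed
  out
}
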