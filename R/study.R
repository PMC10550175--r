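## Pre/post learning-gain analytics, calibration math and gaze utilities.

#' Inverse learning gain
#'
#' `eDelta = e1 - e0`: the change in mean expert error from pre-test to
#' post-test.  Negative values indicate improvement ("inverse" because
#' the underlying scores are errors).
#'
#' @param e0 Pre-test mean expert error.
#' @param e1 Post-test mean expert error.
#' @return `e1 - e0`.
#' @examples
#' learningGain(3, 2)   # -1, improvement
#' @export
learningGain <- function(e0, e1) {
  assertFinite(e0, "e0"); assertFinite(e1, "e1")
  e1 - e0
}

#' Interquartile-range outlier filter
#'
#' Removes values outside the Tukey fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles computed by linear
#' interpolation of the order statistics (the default quantile
#' definition, type 7).
#'
#' @param values Numeric vector, `n >= 4`.
#' @return List with `kept`, `removed`, and the numeric `fences`
#'   (`lower`, `upper`).
#' @examples
#' iqrOutlierFilter(c(1, 2, 3, 100))$removed  # 100
#' @export
iqrOutlierFilter <- function(values) {
  assertFinite(values, "values")
  if (length(values) < 4L) stop("need at least 4 values for IQR analysis")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  out <- values < fences["lower"] | values > fences["upper"]
  list(kept = values[!out], removed = values[out], fences = fences)
}

#' Paired one-tailed t-test
#'
#' Classical paired t-test on the differences `post - pre` with a
#' one-tailed p-value in the requested direction (`"less"`: the
#' hypothesis that post values are lower).  Degenerate inputs return
#' explicit markers instead of NaN: all differences zero gives `t = 0`,
#' `p = 0.5`; a nonzero constant difference has zero variance and yields
#' [undefinedValue()] markers.
#'
#' @param pre,post Equal-length paired samples, `n >= 3`.
#' @param direction Alternative hypothesis for `post` relative to `pre`:
#'   `"less"` (default) or `"greater"`.
#' @return List with `t`, `df`, `p`, `meanDiff` and `n`.
#' @examples
#' pairedTOneTailed(c(3, 4, 5, 6), c(2, 4, 3, 6))
#' @export
pairedTOneTailed <- function(pre, post, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (length(pre) != length(post)) stop("pre and post must be paired")
  n <- length(pre)
  if (n < 3L) stop("need n >= 3 pairs")
  assertFinite(pre, "pre"); assertFinite(post, "post")
  d <- post - pre
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 0.5, meanDiff = 0, n = n))
    u <- undefinedValue("zero variance of differences with nonzero mean")
    return(list(t = u, df = n - 1, p = u, meanDiff = mean(d), n = n))
  }
  tt <- stats::t.test(post, pre, paired = TRUE, alternative = direction)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDiff = unname(tt$estimate), n = n)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom
#' (fractional df), two-sided by default.
#'
#' @param a,b Numeric samples, each `n >= 2`.
#' @param alternative Passed to [stats::t.test()].
#' @return List with `t`, `df`, `p`.
#' @export
welchT <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  assertFinite(a, "a"); assertFinite(b, "b")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    u <- undefinedValue("zero variance in both samples")
    return(list(t = u, df = u, p = u))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Mean eye-tooth distance over a trial
#'
#' Mean Euclidean distance between the cyclops-eye position (midpoint of
#' the two eyes) and the gaze hit point on the tooth, over the samples
#' where the gaze ray actually hit the tooth; non-hit samples are
#' excluded.
#'
#' @param gaze A `data.frame` with columns `ex, ey, ez` (eye position,
#'   cm), `hx, hy, hz` (tooth hit position, cm) and logical `hit`.
#' @return Mean distance in cm, or an [undefinedValue()] marker if no
#'   sample hit the tooth.
#' @export
meanEyeToothDistance <- function(gaze) {
  need <- c("ex", "ey", "ez", "hx", "hy", "hz", "hit")
  if (!all(need %in% names(gaze)))
    stop("gaze needs columns ", paste(need, collapse = ", "))
  g <- gaze[as.logical(gaze$hit), , drop = FALSE]
  if (nrow(g) == 0L)
    return(undefinedValue("no gaze sample hit the tooth"))
  mean(sqrt((g$ex - g$hx)^2 + (g$ey - g$hy)^2 + (g$ez - g$hz)^2))
}

#' Fraction of the display covered by a screen region
#'
#' `100 * region area / display area`, in percent; e.g. the tooth region
#' of roughly 119 x 119 pixels on a 2880 x 1600 head-mounted display
#' covers about 0.31% of the screen.
#'
#' @param regionPx Integer pair, region width and height in pixels.
#' @param displayPx Integer pair, display width and height in pixels.
#' @return Coverage in percent.
#' @examples
#' screenCoverageFraction(c(119, 119), c(2880, 1600))
#' @export
screenCoverageFraction <- function(regionPx, displayPx) {
  assertFinite(regionPx, "regionPx"); assertFinite(displayPx, "displayPx")
  if (length(regionPx) != 2L || length(displayPx) != 2L)
    stop("regionPx and displayPx must each be a pair (width, height)")
  if (any(displayPx <= 0)) stop("display area must be positive")
  if (any(regionPx < 0)) stop("region dimensions must be non-negative")
  100 * prod(regionPx) / prod(displayPx)
}

#' Componentwise angle difference wrapped to [-180, 180]
#'
#' Subtracts `b` from `a` and wraps each component into `[-180, 180]`
#' degrees.  Boundary convention: a raw difference of exactly +180 maps
#' to +180 and exactly -180 maps to -180.
#'
#' @param a,b Angle triples in degrees.
#' @return Numeric triple in `[-180, 180]`.
#' @examples
#' angleDelta(c(350, 0, 0), c(10, 0, 0))   # -20, 0, 0
#' @export
angleDelta <- function(a, b) {
  assertFinite(a, "a"); assertFinite(b, "b")
  d <- a - b
  w <- d %% 360
  w[w > 180] <- w[w > 180] - 360
  w[d == -180] <- -180
  w
}

#' Hand-tool calibration offset
#'
#' Computes the virtual-camera offset that co-locates the physical haptic
#' handles with the rendered virtual tools.  The target VR-controller
#' pose is the mirror haptic-device origin plus a hand-measured offset,
#' `pCT = pM + deltaP`, `thetaCT = thetaM + deltaTheta`; the camera
#' correction is the difference to the actually tracked controller,
#' `pVR = pCT - pC` and `thetaVR = angleDelta(thetaCT, thetaC)`.
#'
#' @param mirror [Pose-class] of the mirror haptic-device origin.
#' @param deltaP Measured translation offset (cm) from mirror origin to
#'   the VR-controller dock.
#' @param deltaTheta Measured rotation offset (degrees).
#' @param controller [Pose-class] of the tracked physical VR controller.
#' @return List with `target` (the controller target [Pose-class]) and
#'   `offset` (the camera-correction [Pose-class]).
#' @examples
#' cal <- calibrationOffset(Pose(), c(22, 26, -7), c(0, 0, 90),
#'                          Pose(c(22, 26, -7), c(0, 0, 90)))
#' cal$offset   # zero position and angle offset
#' @export
calibrationOffset <- function(mirror, deltaP, deltaTheta, controller) {
  stopifnot(is(mirror, "Pose"), is(controller, "Pose"))
  assertFinite(deltaP, "deltaP"); assertFinite(deltaTheta, "deltaTheta")
  pCT <- mirror@position + deltaP
  thetaCT <- mirror@rotation + deltaTheta
  list(
    target = Pose(pCT, thetaCT),
    offset = Pose(pCT - controller@position,
                  angleDelta(thetaCT, controller@rotation)))
}
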