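## Parameterized drilled-outcome simulation.

#' Simulate a drilled outcome from a drill plan
#'
#' Carves the phantom along the plan's path: the carved region is the
#' union of capsules of radius `toolRadius + overdrillExtent` around the
#' path, with per-voxel Gaussian boundary jitter of amplitude
#' `roughness` (cm, seeded), minus a retained sub-region of the ideal
#' cavity — the deepest `underdrillFraction` of the cavity's voxels, the
#' part a hesitant student fails to reach.  The result is always a
#' subset of the initial occupancy.
#'
#' With `overdrillExtent = 0`, `underdrillFraction = 0`, `roughness = 0`
#' and the phantom's own ideal path/tool radius, the carve reproduces
#' the ideal cavity exactly and the outcome equals the ideal outcome.
#'
#' @param phantom A [ToothPhantom-class].
#' @param plan A [DrillPlan-class].
#' @return A [VoxelGrid-class]: the actual outcome volume.
#' @examples
#' ph <- buildToothPhantom(shape = c(30, 45, 30), spacing = 0.0375,
#'                         nEnamel = 400, nDentin = 700, nPulp = 60)
#' out <- simulateOutcome(ph, idealPlan(ph))
#' identical(gridMask(out), gridMask(ph@idealOutcome))
#' @export
simulateOutcome <- function(phantom, plan) {
  stopifnot(is(phantom, "ToothPhantom"), is(plan, "DrillPlan"))
  validObject(plan)
  occ <- phantom@occupancy
  sh <- gridShape(occ)
  ax <- voxelAxes(occ)
  R <- plan@toolRadius + plan@overdrillExtent
  margin <- R + 3 * plan@roughness + max(occ@spacing)

  lo <- apply(plan@path, 2, min) - margin
  hi <- apply(plan@path, 2, max) + margin
  win <- lapply(1:3, function(a) which(ax[[a]] >= lo[a] & ax[[a]] <= hi[a]))
  carve <- array(FALSE, dim = sh)
  if (all(lengths(win) > 0L)) {
    nx <- length(win[[1]]); ny <- length(win[[2]]); nz <- length(win[[3]])
    x <- rep(ax[[1]][win[[1]]], times = ny * nz)
    y <- rep(rep(ax[[2]][win[[2]]], each = nx), times = nz)
    z <- rep(ax[[3]][win[[3]]], each = nx * ny)
    d <- sqrt(polylineDist2(x, y, z, plan@path))
    thr <- if (plan@roughness > 0) {
      withSeed(plan@seed, R + plan@roughness * rnorm(length(d)))
    } else R
    carve[win[[1]], win[[2]], win[[3]]] <- d <= thr
  }

  if (plan@underdrillFraction > 0) {
    cav <- which(phantom@idealCavity@mask)
    if (length(cav) > 0L) {
      ## deepest part of the cavity first (lowest y = furthest from the
      ## occlusal entry)
      yIdx <- ((cav - 1L) %/% sh[1]) %% sh[2]
      nRet <- round(plan@underdrillFraction * length(cav))
      if (nRet > 0L) {
        keep <- cav[order(yIdx)][seq_len(nRet)]
        carve[keep] <- FALSE
      }
    }
  }

  withMask(occ, occ@mask & !carve)
}

#' The plan that reproduces the ideal cavity
#'
#' Convenience constructor: a noise-free [DrillPlan-class] along the
#' phantom's ideal path at the phantom's tool radius.
#'
#' @param phantom A [ToothPhantom-class].
#' @param ... Overrides passed to [DrillPlan()].
#' @return A [DrillPlan-class].
#' @export
idealPlan <- function(phantom, ...) {
  DrillPlan(path = phantom@idealPath, toolRadius = phantom@toolRadius, ...)
}

#' Generate a series of synthetic drilled outcomes
#'
#' Samples `n` drill plans whose severity spans the score range seen in
#' student cohorts: a severity draw controls the over-drill extent and
#' the number of stray "wander" strokes through the tooth (perforation-
#' like errors), while under-drilling and boundary roughness are drawn
#' independently.  Each outcome is classified against the phantom's
#' ideal outcome and scored.  Sensitivity spans its wide empirical
#' window (0.2, 1) while precision stays high and narrow — the
#' asymmetry characteristic of real outcomes, where over-drilling
#' dominates.
#'
#' @param phantom A [ToothPhantom-class].
#' @param n Number of outcomes (>= 1).
#' @param seed Integer seed; the full series is reproducible.
#' @param target `"uniform"` spreads severity evenly over its range
#'   (best coverage for essential-outcome selection); `"normal"`
#'   concentrates severity around the middle, emulating a natural score
#'   distribution.
#' @param overdrillMax,underdrillMax,roughnessMax,wanderMax Upper limits
#'   of the sampled plan parameters (cm, fraction, cm, stroke count).
#' @param keepMasks Keep every outcome [VoxelGrid-class] in memory
#'   (large); plans are always kept and outcomes can be regenerated
#'   deterministically via [simulateOutcome()].
#' @return List with `manifest` (a `data.frame`: id, plan parameters,
#'   TP/TN/FP/FN, P, S, D, F1), `plans` (list of [DrillPlan-class]),
#'   `outcomes` (list of [VoxelGrid-class] or `NULL`), and a
#'   `scoreHistogram` (a precomputed [graphics::hist()] object of the
#'   Dentist scores).
#' @export
generateOutcomeSeries <- function(phantom, n, seed = 1L,
                                  target = c("uniform", "normal"),
                                  overdrillMax = 0.2, underdrillMax = 0.3,
                                  roughnessMax = 0.03, wanderMax = 2,
                                  keepMasks = FALSE) {
  stopifnot(is(phantom, "ToothPhantom"))
  target <- match.arg(target)
  assertCount(n, "n")
  if (n < 1L) stop("n must be >= 1")
  if (overdrillMax < 0 || underdrillMax < 0 || underdrillMax > 1 ||
      roughnessMax < 0 || wanderMax < 0) {
    warning("infeasible parameter ranges; clamping to valid values")
    overdrillMax <- max(overdrillMax, 0)
    underdrillMax <- min(max(underdrillMax, 0), 1)
    roughnessMax <- max(roughnessMax, 0)
    wanderMax <- max(wanderMax, 0)
  }

  occ <- phantom@occupancy
  ## sample wander strokes inside the occupied bounding box
  occIdx <- which(occ@mask)
  sh <- gridShape(occ)
  ii <- (occIdx - 1L) %% sh[1]
  jj <- ((occIdx - 1L) %/% sh[1]) %% sh[2]
  kk <- (occIdx - 1L) %/% (sh[1] * sh[2])
  bboxLo <- occ@origin + c(min(ii), min(jj), min(kk)) * occ@spacing
  bboxHi <- occ@origin + c(max(ii), max(jj), max(kk)) * occ@spacing

  params <- withSeed(seed, {
    u <- switch(target,
      uniform = runif(n),
      normal = pmin(pmax(rnorm(n, 0.5, 0.22), 0), 1))
    list(
      severity = u,
      overdrill = u * overdrillMax,
      underdrill = runif(n) * underdrillMax * (1 - u),
      roughness = runif(n) * roughnessMax,
      wander = lapply(seq_len(n), function(i) {
        m <- floor(u[i] * wanderMax + 0.5)
        if (m == 0L) return(NULL)
        cbind(runif(m, bboxLo[1], bboxHi[1]),
              runif(m, bboxLo[2], bboxHi[2]),
              runif(m, bboxLo[3], bboxHi[3]))
      }))
  })

  plans <- vector("list", n)
  outcomes <- if (keepMasks) vector("list", n) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    path <- phantom@idealPath
    if (!is.null(params$wander[[i]])) path <- rbind(path, params$wander[[i]])
    plan <- DrillPlan(path, toolRadius = phantom@toolRadius,
                      overdrillExtent = params$overdrill[i],
                      underdrillFraction = params$underdrill[i],
                      roughness = params$roughness[i],
                      seed = childSeed(seed, i))
    actual <- simulateOutcome(phantom, plan)
    cc <- classifyOutcome(occ, phantom@idealOutcome, actual)
    cs <- componentScores(cc, warn = FALSE)
    plans[[i]] <- plan
    if (keepMasks) outcomes[[i]] <- actual
    rows[[i]] <- data.frame(
      id = i, severity = params$severity[i],
      overdrillExtent = params$overdrill[i],
      underdrillFraction = params$underdrill[i],
      roughness = params$roughness[i],
      nWander = if (is.null(params$wander[[i]])) 0L
                else nrow(params$wander[[i]]),
      TP = cc@TP, TN = cc@TN, FP = cc@FP, FN = cc@FN,
      P = cs@P, S = cs@S,
      D = dentistScoreFromCounts(cc), F1 = f1Score(cc))
  }
  manifest <- do.call(rbind, rows)
  if (n >= 10L && (max(manifest$S) - min(manifest$S)) < 0.3)
    warning("achieved sensitivity coverage is narrow (span < 0.3); ",
            "consider widening the parameter ranges")
  list(manifest = manifest, plans = plans, outcomes = outcomes,
       scoreHistogram = graphics::hist(manifest$D, plot = FALSE))
}
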