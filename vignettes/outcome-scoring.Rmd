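---
title: "Scoring virtual dental drilling outcomes with drillscore"
author: "drillscore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring virtual dental drilling outcomes with drillscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drillscore)
```

## The problem

In virtual-reality dental training, a student drills a root-canal access
opening into a simulated molar.  Clinically, the outcome is judged by an
instructor against a rubric: each of the four cardinal tooth walls and
the pulp floor receives an integer error category 0–3 (0 = clean access
to all canal orifices, 3 = unidentified canals and/or perforation), for
a total error of 0–15, lower better.  A simulator, however, knows the
full 3D geometry of the drilled tooth, so the outcome can be scored
automatically — provided a metric exists that tracks expert judgment.
drillscore implements such a metric, the machinery to compute it from
voxel volumes, the statistics used to validate it against expert raters,
and a synthetic data generator so the whole pipeline runs without any
proprietary study data.

## Voxel classification

All volumes are `VoxelGrid` objects: 3D logical occupancy masks (`TRUE`
= material present, i.e. *undrilled*) with physical spacing and origin
in cm, by default discretized at 90 × 135 × 90 voxels over the tooth
bounding box (0.0125 cm/voxel; voxel-centre convention, 1-based
indices).  Scoring needs three volumes: the *initial* tooth, the
expert-approved *ideal* outcome, and the student's *actual* outcome.
`classifyOutcome()` compares actual and ideal voxel by voxel, restricted
to the initial tooth (air was never drillable, so it carries no
information about drilling skill):

* **TP** — correctly undrilled (kept material that should be kept),
* **TN** — correctly drilled,
* **FP** — incorrectly undrilled: *under-drilling*,
* **FN** — incorrectly drilled: *over-drilling*.

The counts always sum to the initial tooth's voxel count, and drilling
can only remove material, so ideal ⊆ initial and actual ⊆ initial are
enforced preconditions.

## The Dentist metric

Precision and sensitivity of this classification specialize cleanly:
$P = TP/(TP+FP)$ is degraded only by under-drilling, and
$S = TP/(TP+FN)$ only by over-drilling.  Empirically the two occupy very
different ranges — outcomes concentrate in $P \in (0.96, 0.995]$ but
$S \in (0.2, 1)$ — so both are linearly rescaled onto a comparable range
using the anchors 0.95 and 0.2:

$$\tilde P = \frac{P - 0.95}{1 - 0.95}, \qquad
  \tilde S = \frac{S - 0.2}{1 - 0.2}.$$

The **Dentist score** is a weighted mean of the rescaled components,
flipped into a distance and scaled onto the 0–15 rubric:

$$D = \left(1 - \frac{1.5\,\tilde S + \tilde P}{2.5}\right) \times 15
    = \frac{15\,(32\,FP\,TP + 3\,FN\,TP + 35\,FN\,FP)}
           {4\,(TP+FN)(TP+FP)}.$$

The right-hand closed form is an unconditional algebraic identity of the
left-hand definition; the package implements both (`dentistScore()` and
`dentistScoreFromCounts()`) and tests their agreement to $10^{-9}$
relative tolerance on random count triples.  $D = 0$ at a perfect
outcome and $D = 15$ at the rescale anchors ($S = 0.2$, $P = 0.95$).

```{r}
cc <- ClassificationCounts(TP = 1000, TN = 780, FP = 20, FN = 200)
componentScores(cc, warn = FALSE)
dentistScoreFromCounts(cc)
f1Score(cc)
```

**No clamping.**  Inputs outside the empirical windows produce rescaled
values outside $[0,1]$ and Dentist scores outside $[0,15]$; the package
warns but does not clamp, because clamping would destroy the identity
between the two formulations.  Degenerate counts ($TP+FP = 0$ or
$TP+FN = 0$) are an explicit error rather than a sentinel: a real
outcome always retains some material.

`f1Score()` is the baseline the Dentist score improves upon, and
`metricSuite()` evaluates 24 standard binary-classification metrics
(accuracy through diagnostic odds ratio) on the same table — the
comparison pool from which F1 was originally chosen.  The exact
historical list of 24 is not canonical; the suite is a declared superset
of the common choices, and any metric with a vanishing denominator is
reported as `NA` with a reason, never silently as 0.

## Essential-outcome selection

Expert validation cannot rate hundreds of outcomes, so
`selectEssentialOutcomes()` reduces a scored series to *k* (typically
20) representatives covering the observed score range: the range is cut
into *k* equal-width bins, each non-empty bin contributes the sample
nearest its centre (ties → lowest index), and empty bins are back-filled
with the nearest unused sample.  The tie-breaking rules are this
package's choice; only "uniform coverage" is inherited from the
validation protocol.

## Agreement statistics

`cohensKappa()` (linear weights by default — appropriate for the ordinal
0–15 totals; unweighted available), `iccTwoRater()` (two-way
random-effects ICC(2,1) absolute agreement by default, ICC(2,k)
selectable) and `pearsonCorrelation()` quantify inter-expert reliability
and expert-vs-automated correlation.  `ibmd()` implements the
information-based measure of disagreement,
$\mathrm{mean}_i \left[\log(|x_i - y_i| + 1) / \log(\max(x_i, y_i) + 1)\right]$
(natural logs, with $0/0$ defined as 0), which is 0 iff the raters agree
everywhere.  The ICC variant and kappa weighting are deliberately
explicit parameters because validation reports rarely state them.
`agreementReport()` bundles all of these for a rated outcome set.

Statistics that are mathematically undefined for an input (one observed
category, zero between-subject variance, zero variance in a
correlation) return an `undefinedValue()` marker — an `NA` carrying a
reason string — rather than `NaN` or a silent 0.

## Volume machinery

`occupancyFromSpheres()` voxelizes a labelled sphere set under three
kernels: `"metaball"` (summed compact polynomial falloff
$g(d) = (1-(d/2r)^2)^2/(9/16)$, threshold 1 at the nominal boundary),
`"max"` (pointwise maximum — the union of balls at threshold 1) and
`"hard"` (boolean spheres).  The implicit-surface function used in
production simulators is generally unspecified, so rather than guess,
the package offers the summed-field mode for blending and the exact
boolean mode, which the synthesis module uses where exactness matters.

`extractSurfaceMesh()` extracts the 0.5 iso-surface as a closed,
consistently outward-oriented triangle mesh via serial marching
tetrahedra (six tetrahedra per cell around the main diagonal, linear
edge interpolation, watertight by shared-edge vertex dedup).  Marching
tetrahedra was chosen over table-based marching cubes because its case
analysis is derivable from first principles and therefore fully
verifiable in the test suite; the two are semantically interchangeable
here.  One numerical caveat is inherent to *binary* fields: midpoint
iso-surfaces overestimate area (about +27% on a voxelized sphere,
whatever the triangulation scheme), so for quantitative area/volume
measurements `smooth = TRUE` first anti-aliases the mask with a 3-voxel
box filter; the smoothed sphere mesh reproduces the analytic area to
well under 1%, and its enclosed volume converges to the analytic value
as spacing shrinks.  The raw binary mode (default) preserves
single-voxel features that smoothing would erase.  Meshes are written
with `writeMeshPLY()` (binary little-endian) and `writeMeshOBJ()`;
volumes round-trip through NRRD, NIfTI and a raw + JSON-sidecar dialect
(`readVolume()`/`writeVolume()`).

## The synthetic tooth phantom

`buildToothPhantom()` generates a procedural molar: a superellipsoid
crown with an enamel shell, a tapered root, and a pulp chamber with four
canals, each tissue filled with randomly placed labelled spheres and
voxelized in boolean-spheres mode.  Sphere counts default to
5000/8500/500 (enamel/dentin/pulp) — the production-scale composition of
100k/170k/10k scaled down 20× for desk-scale runtimes while preserving
the tissue ratios; counts are configurable back up.  The *ideal cavity*
is a capsule swept along a reference drill path descending through the
crown and visiting all four canal orifices; the ideal outcome is
occupancy minus cavity.  Four deterministic dentin spheres at the
orifices guarantee material there regardless of the random fill.

The phantom is deliberately *not* anatomically faithful — no real tooth
geometry enters the package.  Its purpose is score-distribution
fidelity: outcomes drilled into it must populate the same component-
score windows as real student outcomes.

`simulateOutcome()` carves a `DrillPlan`: capsules of radius
`toolRadius + overdrillExtent` along a path, Gaussian boundary jitter of
SD `roughness` (per-voxel, seeded), minus the deepest
`underdrillFraction` of the ideal cavity (a hesitant student fails to
reach depth first).  Running the phantom's own `idealPlan()` with zero
over/under-drill reproduces the ideal outcome *exactly*, because the
cavity itself is defined by the same swept capsule — this gives the
pipeline a bit-exact zero-error anchor.

`generateOutcomeSeries()` samples plans whose severity drives the
over-drill extent and the number of stray "wander" strokes (perforation
errors), with under-drilling and roughness drawn independently.  The
default ranges (`overdrillMax = 0.2` cm, `underdrillMax = 0.3`,
`wanderMax = 2`, `roughnessMax = 0.03` cm) were calibrated once so that
achieved scores land in the empirical windows: measured on a default
phantom, $S$ spans ≈ [0.26, 0.99], $P$ ≈ [0.961, 0.999], F1 spans more
than half the unit interval.  Both a `"uniform"` severity target (best
range coverage, the regime essential-outcome selection assumes) and a
`"normal"` target (natural score distribution) are exposed, since the
validation protocol wants both at different stages.

## The synthetic cohort

`generateCohort()` draws four-arm study cohorts (stereo/mono rendering ×
aligned/misaligned hand-tool calibration): reported pre/post expert
errors, six simulator trials, and a mean eye-tooth distance per
participant.  Defaults are calibrated to published group-level moments:
pre-test error 2.77 ± 1.19, pooled inverse learning gain −0.375 with
realized SD ≈ 1.87, the four group gains recentred as zero-sum offsets,
per-group trial trajectories, and suitability/transfer couplings whose
signs reproduce the reported correlation pattern (strongest positive
skill transfer in the stereo+aligned arm, negative in mono+misaligned).

Two reporting artefacts of real rubric data are modelled: scores are
floored at 0 and reported on the half-integer grid (the mean of two
integer expert totals).  Both shift the mean of a normal draw, so the
generator solves for the *latent* gain mean that makes the reported
pooled gain hit the configured target exactly — a 1D root-solve over a
quadrature of the truncated pre-test distribution, cached per
configuration.  Because truncation also compresses spread, the latent
gain SD default (2.10) was set once so the realized pooled-gain SD
matches the target 1.87 (the naive latent value 1.84 realizes only
1.69).  Under the zero-effect configuration (`nullCohortConfig()`) the
pooled paired one-tailed t-test holds its nominal 5% size to within the
Monte-Carlo band — the residual truncation skewness costs a few tenths
of a percentage point, measured, not assumed.

What the generator does *not* emulate: per-surface rating structure
(only totals), learning curves within a day beyond linear trends, and
any anatomical variation between trials.  Passing tests on synthetic
cohorts therefore validate the *analysis machinery and its
calibration*, not claims about real students.

## Study analytics

`learningGain()` ($e_\Delta = e_1 - e_0$; negative = improvement),
`iqrOutlierFilter()` (Tukey fences at 1.5 IQR, type-7 linear-
interpolation quartiles — the quartile convention is stated because
reports rarely do), `pairedTOneTailed()` and `welchT()` (thin wrappers
over `stats::t.test()` with explicit degenerate-input markers; Welch is
the default two-sample form because fractional df appear throughout the
reported comparisons), and `transferAnalyses()`, which computes per
stratum (all / rendering / alignment / group) the two correlations that
matter for simulator validity:

* **suitability for assessment** — pre-test error vs initial simulator
  performance (mean of trials 1–3 by default; trial 1 selectable, since
  "initial performance" is used in both senses),
* **learning transfer** — real gain vs simulator gain (trial 6 − trial 1).

Outlier removal before these analyses is a flag (`removeOutliers`,
default `TRUE`, matching the usual n = 37-of-40 pre-processing).  The
`analyze` CLI report additionally runs a standard one-way ANOVA of the
learning gains across the four groups; with four groups this has 3
numerator degrees of freedom — study write-ups sometimes print
`F(1, ...)` here, which is internally inconsistent notation that this
package does not imitate.
`meanEyeToothDistance()` averages cyclops-eye-to-tooth distances over
gaze samples that actually hit the tooth, and
`screenCoverageFraction()` is the pixel-coverage arithmetic (119² px of
a 2880 × 1600 display ≈ 0.31%).  `calibrationOffset()` and
`angleDelta()` implement the hand-tool calibration math: target pose =
mirror pose + measured offset, camera correction = target − tracked
controller, with angles wrapped componentwise into [−180°, 180°]
(boundary convention: a raw difference of exactly ±180° keeps its
sign).

## Numerical and design notes

* **Determinism.**  Every stochastic function takes a seed and restores
  the caller's RNG state; derived child seeds stay below $2^{31}$.
* **Voxel convention.**  0-based world arithmetic with 1-based R
  indices: voxel $[i,j,k]$ sits at `origin + (c(i,j,k)-1)*spacing`.
  Stated once, used everywhere.
* **Mask polarity.**  `TRUE` means material present ("undrilled").
* **Grid geometry checks** use an absolute tolerance of $10^{-9}$ cm;
  masks must match exactly.
* **Degenerate inputs** (all-false/all-true masks, zero variances,
  single observed categories, empty rating lists) are either explicit
  errors or `undefinedValue()` markers; nothing silently returns 0.
* **Problem sizes.**  The test suite exercises small phantoms
  (30 × 45 × 30) for unit-level properties and the full default
  90 × 135 × 90 phantom for the sweep, coverage and end-to-end checks
  (240 outcomes); statistical calibration uses 10,000 replicate
  cohorts.  These sizes are the package's chosen validation conditions
  and run on a single CPU in a few minutes.

## Known limitations

* The phantom is procedural; results on it say nothing about any
  specific tooth's anatomy, and the ideal cavity is geometric, not
  expert-approved.
* Reported reliability figures from human studies (inter-expert kappa
  or ICC, expert-vs-automated correlation on real outcomes) cannot be
  reproduced here because per-expert raw ratings are not published;
  the package computes those statistics but makes no claims about
  their values on real data.
* NIfTI stores spacing/origin as 32-bit floats; use NRRD or the raw
  dialect where bit-exact geometry round-trips matter.
* The Dentist score is a global metric; it does not localize which
  wall an error sits on (the per-surface rubric structure is available
  only through `ExpertRating`).
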