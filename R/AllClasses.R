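#' @import methods
NULL

## Default discretization of the tooth bounding box: 90 x 135 x 90 voxels
## at 0.0125 cm/voxel, i.e. a 1.125 x 1.6875 x 1.125 cm volume with the
## long axis (y) along the tooth height.
DEFAULT_SHAPE   <- c(90L, 135L, 90L)
DEFAULT_SPACING <- c(0.0125, 0.0125, 0.0125)

#' VoxelGrid: a 3D boolean occupancy volume
#'
#' The universal representation of tooth material in this package: a 3D
#' logical array (`TRUE` = material present, i.e. undrilled) together with
#' the physical voxel spacing (cm) and the world position (cm) of the
#' centre of voxel `[1, 1, 1]`.  Voxel `[i, j, k]` is centred at
#' `origin + (c(i, j, k) - 1) * spacing` (voxel-centre convention).
#'
#' @slot mask 3D logical array; `TRUE` where material is present.
#' @slot spacing Numeric length 3, cm per voxel along each axis (> 0).
#' @slot origin Numeric length 3, world coordinates (cm) of the centre of
#'   the first voxel.
#' @seealso [occupancyFromSpheres()], [classifyOutcome()], [readVolume()]
#' @export
setClass("VoxelGrid",
  slots = c(mask = "array", spacing = "numeric", origin = "numeric"))

setValidity("VoxelGrid", function(object) {
  m <- object@mask
  if (!is.logical(m) || length(dim(m)) != 3L)
    return("mask must be a 3D logical array")
  if (any(dim(m) < 1L))
    return("all mask dimensions must be >= 1")
  if (length(object@spacing) != 3L || anyNA(object@spacing) ||
      any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("spacing must be 3 positive finite numbers (cm)")
  if (length(object@origin) != 3L || anyNA(object@origin) ||
      any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers (cm)")
  if (anyNA(m))
    return("mask must not contain NA")
  TRUE
})

#' Construct a VoxelGrid
#'
#' @param mask 3D logical array (`TRUE` = material present).
#' @param spacing Voxel spacing in cm, length 1 or 3.
#' @param origin World position (cm) of the centre of voxel `[1,1,1]`.
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- VoxelGrid(array(TRUE, c(4, 4, 4)), spacing = 0.1)
#' gridShape(g)
#' voxelCount(g)
#' @export
VoxelGrid <- function(mask, spacing = DEFAULT_SPACING, origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VoxelGrid", mask = mask, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

## An all-FALSE grid of a given shape.
emptyGrid <- function(shape = DEFAULT_SHAPE, spacing = DEFAULT_SPACING,
                      origin = c(0, 0, 0)) {
  VoxelGrid(array(FALSE, dim = as.integer(shape)), spacing, origin)
}

#' SphereSet: labelled spheres defining a metaball field
#'
#' A set of spheres (centre, radius, tissue label) used both as the
#' implicit-surface primitive for tooth geometry and as the input to
#' [occupancyFromSpheres()].
#'
#' @slot centers Numeric matrix, n x 3, sphere centres in cm.
#' @slot radii Numeric length n, positive radii in cm.
#' @slot labels Character length n; for tooth phantoms one of
#'   `"enamel"`, `"dentin"`, `"pulp"`.
#' @export
setClass("SphereSet",
  slots = c(centers = "matrix", radii = "numeric", labels = "character"))

setValidity("SphereSet", function(object) {
  n <- nrow(object@centers)
  if (ncol(object@centers) != 3L) return("centers must have 3 columns")
  if (length(object@radii) != n || length(object@labels) != n)
    return("centers, radii and labels must have equal lengths")
  if (n > 0L) {
    if (anyNA(object@centers) || any(!is.finite(object@centers)))
      return("sphere centers must be finite")
    if (anyNA(object@radii) || any(!is.finite(object@radii)) ||
        any(object@radii <= 0))
      return("sphere radii must be positive and finite")
  }
  TRUE
})

#' Construct a SphereSet
#'
#' @param centers n x 3 numeric matrix of centres (cm); an empty set is
#'   allowed (`nrow = 0`).
#' @param radii Positive radii (cm), recycled to n if length 1.
#' @param labels Tissue labels, recycled to n if length 1.
#' @return A [SphereSet-class] object.
#' @examples
#' s <- SphereSet(rbind(c(0, 0, 0)), radii = 0.5, labels = "dentin")
#' length(s)
#' @export
SphereSet <- function(centers, radii, labels = "dentin") {
  centers <- as.matrix(centers)
  if (nrow(centers) > 0L) {
    if (length(radii) == 1L) radii <- rep(radii, nrow(centers))
    if (length(labels) == 1L) labels <- rep(labels, nrow(centers))
  }
  storage.mode(centers) <- "double"
  new("SphereSet", centers = centers, radii = as.numeric(radii),
      labels = as.character(labels))
}

#' @describeIn SphereSet Number of spheres in the set.
#' @param x A `SphereSet`.
#' @export
setMethod("length", "SphereSet", function(x) nrow(x@centers))

#' ClassificationCounts: voxel-wise confusion counts
#'
#' Tallies from comparing an actual drilling outcome against the ideal
#' outcome over the voxels of the initial tooth.  The class polarity
#' follows the drilling convention: a *positive* is an undrilled voxel
#' (material present), so `TP` are correctly undrilled, `TN` correctly
#' drilled, `FP` incorrectly undrilled (under-drilling) and `FN`
#' incorrectly drilled (over-drilling).
#'
#' @slot TP,TN,FP,FN Non-negative integer voxel counts; their sum equals
#'   the voxel count of the initial tooth mask.
#' @seealso [classifyOutcome()], [componentScores()], [dentistScoreFromCounts()]
#' @export
setClass("ClassificationCounts",
  slots = c(TP = "numeric", TN = "numeric", FP = "numeric", FN = "numeric"))

setValidity("ClassificationCounts", function(object) {
  v <- c(object@TP, object@TN, object@FP, object@FN)
  if (length(v) != 4L || anyNA(v) || any(v < 0) || any(v != round(v)))
    return("TP, TN, FP, FN must be single non-negative integers")
  TRUE
})

#' Construct ClassificationCounts
#'
#' @param TP,TN,FP,FN Non-negative integer voxel tallies.
#' @return A [ClassificationCounts-class] object.
#' @examples
#' counts(ClassificationCounts(TP = 1000, TN = 780, FP = 20, FN = 200))
#' @export
ClassificationCounts <- function(TP, TN = 0, FP = 0, FN = 0) {
  new("ClassificationCounts", TP = as.numeric(TP), TN = as.numeric(TN),
      FP = as.numeric(FP), FN = as.numeric(FN))
}

#' ComponentScores: precision/sensitivity and their rescalings
#'
#' Precision `P = TP / (TP + FP)` penalizes under-drilling, sensitivity
#' `S = TP / (TP + FN)` penalizes over-drilling.  Both are linearly
#' rescaled onto roughly the unit interval using the empirical anchors
#' `P = 0.95` and `S = 0.2`:
#' `Ptilde = (P - 0.95) / 0.05`, `Stilde = (S - 0.2) / 0.8`.
#' Rescaled values are deliberately *not* clamped, so inputs outside the
#' empirical windows yield values outside `[0, 1]` (and Dentist scores
#' outside `[0, 15]`); clamping would break the algebraic identity between
#' the two Dentist formulations.
#'
#' @slot P,S Precision and sensitivity in `[0, 1]`.
#' @slot Ptilde,Stilde Rescaled precision and sensitivity (unclamped).
#' @export
setClass("ComponentScores",
  slots = c(P = "numeric", S = "numeric",
            Ptilde = "numeric", Stilde = "numeric"))

#' ExpertRating: one rater's rubric scores for one outcome
#'
#' The clinical rubric rates each of the four cardinal tooth walls and the
#' pulp floor with an integer error category 0-3 (0 = access to all
#' orifices without excess cavity, 3 = unidentified canals and/or
#' perforation).  The total error is the sum, 0-15, lower is better.
#'
#' @slot surfaceErrors Integer length 5, each in `{0, 1, 2, 3}`, ordered
#'   mesial, distal, buccal, lingual wall, then pulp floor.
#' @slot raterId Single string identifying the rater.
#' @export
setClass("ExpertRating",
  slots = c(surfaceErrors = "integer", raterId = "character"))

setValidity("ExpertRating", function(object) {
  e <- object@surfaceErrors
  if (length(e) != 5L) return("surfaceErrors must have length 5")
  if (anyNA(e) || any(e < 0L) || any(e > 3L))
    return("each surface error must be an integer in {0, 1, 2, 3}")
  if (length(object@raterId) != 1L) return("raterId must be a single string")
  TRUE
})

#' Construct an ExpertRating
#'
#' @param surfaceErrors Five integers in `{0,1,2,3}` (four walls + floor).
#' @param raterId Rater label.
#' @return An [ExpertRating-class] object.
#' @examples
#' expertTotalError(ExpertRating(c(1, 0, 2, 0, 3), "expert1"))
#' @export
ExpertRating <- function(surfaceErrors, raterId = "rater") {
  se <- surfaceErrors
  if (is.numeric(se) && all(se == round(se), na.rm = TRUE))
    se <- as.integer(round(se))
  new("ExpertRating", surfaceErrors = se, raterId = as.character(raterId))
}

#' DrillPlan: a parameterized synthetic drilling action
#'
#' Describes one simulated student drilling: a tool path swept as a
#' capsule (cylinder with spherical caps), systematic over-drilling
#' (extra carve radius), under-drilling (a fraction of the ideal cavity
#' left uncarved, deepest part first) and boundary roughness, all
#' deterministic for a fixed seed.
#'
#' @slot path Numeric matrix, m x 3, ordered waypoints in world cm.
#' @slot toolRadius Positive tool radius in cm.
#' @slot overdrillExtent Extra carve radius in cm (>= 0) beyond the tool.
#' @slot underdrillFraction Fraction in `[0, 1]` of the ideal cavity left
#'   uncarved.
#' @slot roughness Standard deviation (cm) of the boundary jitter.
#' @slot seed Integer seed for the jitter noise.
#' @export
setClass("DrillPlan",
  slots = c(path = "matrix", toolRadius = "numeric",
            overdrillExtent = "numeric", underdrillFraction = "numeric",
            roughness = "numeric", seed = "integer"))

setValidity("DrillPlan", function(object) {
  if (ncol(object@path) != 3L || nrow(object@path) < 1L)
    return("path must be an m x 3 matrix with m >= 1")
  if (anyNA(object@path) || any(!is.finite(object@path)))
    return("path waypoints must be finite")
  if (object@toolRadius <= 0) return("toolRadius must be > 0")
  if (object@overdrillExtent < 0) return("overdrillExtent must be >= 0")
  if (object@underdrillFraction < 0 || object@underdrillFraction > 1)
    return("underdrillFraction must be in [0, 1]")
  if (object@roughness < 0) return("roughness must be >= 0")
  TRUE
})

#' Construct a DrillPlan
#'
#' @param path m x 3 matrix of waypoints (cm).
#' @param toolRadius Tool radius in cm.
#' @param overdrillExtent Extra carve radius (cm), default 0.
#' @param underdrillFraction Fraction of the ideal cavity left uncarved.
#' @param roughness Boundary jitter SD in cm.
#' @param seed Integer seed for jitter reproducibility.
#' @return A [DrillPlan-class] object.
#' @export
DrillPlan <- function(path, toolRadius = 0.16, overdrillExtent = 0,
                      underdrillFraction = 0, roughness = 0, seed = 1L) {
  path <- as.matrix(path)
  storage.mode(path) <- "double"
  new("DrillPlan", path = path, toolRadius = as.numeric(toolRadius),
      overdrillExtent = as.numeric(overdrillExtent),
      underdrillFraction = as.numeric(underdrillFraction),
      roughness = as.numeric(roughness), seed = as.integer(seed))
}

#' ToothPhantom: a procedural molar with an ideal access cavity
#'
#' A synthetic stand-in for a scanned tooth: sphere-set geometry for
#' enamel shell, dentin body and pulp chamber/canals, the voxel occupancy
#' they induce, an expert-style ideal access cavity (a swept-capsule
#' region reaching all four canal orifices) and the resulting ideal
#' outcome.  See [buildToothPhantom()].
#'
#' @slot spheres [SphereSet-class] with tissue labels.
#' @slot occupancy [VoxelGrid-class]; the initial (undrilled) tooth.
#' @slot idealCavity [VoxelGrid-class]; voxels an ideal access opening
#'   removes (a subset of `occupancy`).
#' @slot idealOutcome [VoxelGrid-class]; `occupancy` minus `idealCavity`.
#' @slot orificeCenters 4 x 3 matrix, canal orifice positions (cm).
#' @slot idealPath Waypoints (cm) of the drill path that carves exactly
#'   the ideal cavity at `toolRadius`.
#' @slot toolRadius Tool radius (cm) used for the ideal cavity.
#' @slot config List of the generation parameters (including the seed).
#' @export
setClass("ToothPhantom",
  slots = c(spheres = "SphereSet", occupancy = "VoxelGrid",
            idealCavity = "VoxelGrid", idealOutcome = "VoxelGrid",
            orificeCenters = "matrix", idealPath = "matrix",
            toolRadius = "numeric", config = "list"))

#' TriangleMesh: an extracted iso-surface
#'
#' @slot vertices n x 3 numeric matrix of vertex positions (world cm).
#' @slot faces m x 3 integer matrix of 1-based vertex indices, counter-
#'   clockwise when seen from outside the material.
#' @seealso [extractSurfaceMesh()], [meshArea()], [meshVolume()]
#' @export
setClass("TriangleMesh",
  slots = c(vertices = "matrix", faces = "matrix"))

#' @describeIn TriangleMesh `TRUE` if the mesh has no faces (extraction
#'   from an all-false or all-true mask).
#' @param mesh A `TriangleMesh`.
#' @export
isEmptyMesh <- function(mesh) nrow(mesh@faces) == 0L

#' Pose: a position plus Euler rotation
#'
#' Used by the hand-tool calibration math: a world position in cm and an
#' Euler-angle rotation in degrees.
#'
#' @slot position Numeric length 3, cm.
#' @slot rotation Numeric length 3, degrees.
#' @export
setClass("Pose", slots = c(position = "numeric", rotation = "numeric"))

setValidity("Pose", function(object) {
  if (length(object@position) != 3L || any(!is.finite(object@position)))
    return("position must be 3 finite numbers")
  if (length(object@rotation) != 3L || any(!is.finite(object@rotation)))
    return("rotation must be 3 finite numbers")
  TRUE
})

#' Construct a Pose
#' @param position World position, cm (length 3).
#' @param rotation Euler angles, degrees (length 3).
#' @return A [Pose-class] object.
#' @export
Pose <- function(position = c(0, 0, 0), rotation = c(0, 0, 0)) {
  new("Pose", position = as.numeric(position),
      rotation = as.numeric(rotation))
}
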