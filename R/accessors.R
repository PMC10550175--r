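## Accessors and show methods for the central classes.

#' @rdname VoxelGrid
#' @param grid A [VoxelGrid-class].
#' @return `gridShape()`: integer length 3; `gridSpacing()`, `gridOrigin()`:
#'   numeric length 3; `gridMask()`: the logical array; `voxelVolume()`:
#'   volume of one voxel in cm^3; `voxelCount()`: number of `TRUE` voxels.
#' @export
gridShape <- function(grid) dim(grid@mask)

#' @rdname VoxelGrid
#' @export
gridSpacing <- function(grid) grid@spacing

#' @rdname VoxelGrid
#' @export
gridOrigin <- function(grid) grid@origin

#' @rdname VoxelGrid
#' @export
gridMask <- function(grid) grid@mask

#' @rdname VoxelGrid
#' @export
voxelVolume <- function(grid) prod(grid@spacing)

#' @rdname VoxelGrid
#' @export
voxelCount <- function(grid) sum(grid@mask)

## World coordinates of voxel centres along each axis.
voxelAxes <- function(grid) {
  sh <- gridShape(grid)
  lapply(1:3, function(a)
    grid@origin[a] + (seq_len(sh[a]) - 1) * grid@spacing[a])
}

## TRUE if two grids share shape, spacing and origin (geometry, not mask).
sameGeometry <- function(a, b, tol = 1e-9) {
  identical(gridShape(a), gridShape(b)) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol)
}

## A copy of `grid` with a new mask (geometry preserved).
withMask <- function(grid, mask) {
  VoxelGrid(mask, spacing = grid@spacing, origin = grid@origin)
}

setMethod("show", "VoxelGrid", function(object) {
  sh <- gridShape(object)
  cat(sprintf(
    "VoxelGrid %d x %d x %d, spacing (%g, %g, %g) cm, %d occupied (%.1f%%)\n",
    sh[1], sh[2], sh[3], object@spacing[1], object@spacing[2],
    object@spacing[3], sum(object@mask), 100 * mean(object@mask)))
})

setMethod("show", "SphereSet", function(object) {
  cat(sprintf("SphereSet of %d spheres", length(object)))
  if (length(object) > 0) {
    tab <- table(object@labels)
    cat(": ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        sep = "")
  }
  cat("\n")
})

#' @rdname ClassificationCounts
#' @param x A [ClassificationCounts-class].
#' @return `counts()`: named numeric vector `c(TP, TN, FP, FN)`;
#'   `totalVoxels()`: their sum (the size of the initial tooth mask).
#' @export
counts <- function(x) c(TP = x@TP, TN = x@TN, FP = x@FP, FN = x@FN)

#' @rdname ClassificationCounts
#' @export
totalVoxels <- function(x) x@TP + x@TN + x@FP + x@FN

setMethod("show", "ClassificationCounts", function(object) {
  cat(sprintf("ClassificationCounts: TP=%d TN=%d FP=%d FN=%d (total %d)\n",
              object@TP, object@TN, object@FP, object@FN,
              totalVoxels(object)))
})

setMethod("show", "ComponentScores", function(object) {
  cat(sprintf(
    "ComponentScores: P=%.5f S=%.5f  rescaled Ptilde=%.5f Stilde=%.5f\n",
    object@P, object@S, object@Ptilde, object@Stilde))
})

setMethod("show", "ExpertRating", function(object) {
  cat(sprintf("ExpertRating [%s]: walls+floor (%s), total %d/15\n",
              object@raterId,
              paste(object@surfaceErrors, collapse = ","),
              sum(object@surfaceErrors)))
})

setMethod("show", "DrillPlan", function(object) {
  cat(sprintf(
    paste0("DrillPlan: %d waypoints, tool r=%.3f cm, overdrill=%.3f cm, ",
           "underdrill=%.2f, roughness=%.3f, seed=%d\n"),
    nrow(object@path), object@toolRadius, object@overdrillExtent,
    object@underdrillFraction, object@roughness, object@seed))
})

setMethod("show", "ToothPhantom", function(object) {
  sh <- gridShape(object@occupancy)
  cat(sprintf(
    paste0("ToothPhantom: grid %d x %d x %d, %d spheres, ",
           "%d tooth voxels, %d ideal-cavity voxels\n"),
    sh[1], sh[2], sh[3], length(object@spheres),
    voxelCount(object@occupancy), voxelCount(object@idealCavity)))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "Pose", function(object) {
  cat(sprintf("Pose: position (%g, %g, %g) cm, rotation (%g, %g, %g) deg\n",
              object@position[1], object@position[2], object@position[3],
              object@rotation[1], object@rotation[2], object@rotation[3]))
})
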