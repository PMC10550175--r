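#' Classify an actual drilling outcome against the ideal outcome
#'
#' Compares the actual outcome volume with the ideal outcome volume, voxel
#' by voxel, restricted to the voxels of the initial (undrilled) tooth;
#' voxels that were never tooth material are ignored, so every count is
#' drilling-related.  The polarity is "positive = undrilled":
#'
#' * `TP` — correctly undrilled (present in actual and in ideal);
#' * `TN` — correctly drilled (absent from both);
#' * `FP` — incorrectly undrilled (present in actual, absent from ideal;
#'   under-drilling);
#' * `FN` — incorrectly drilled (absent from actual, present in ideal;
#'   over-drilling).
#'
#' `TP + TN + FP + FN` always equals the voxel count of the initial mask.
#'
#' @param initial,ideal,actual [VoxelGrid-class] objects sharing shape,
#'   spacing and origin.  Drilling only removes material, so `ideal` and
#'   `actual` must be subsets of `initial`.
#' @return A [ClassificationCounts-class].
#' @examples
#' m <- array(FALSE, c(5, 5, 1)); m[1:5, 1:2, 1] <- TRUE  # 10 tooth voxels
#' init <- VoxelGrid(m, spacing = 0.1)
#' ideal <- init; ideal@mask[1:4, 1, 1] <- FALSE          # remove 4
#' act <- init; act@mask[1:3, 1, 1] <- FALSE              # 3 of those...
#' act@mask[5, 2, 1] <- FALSE                             # ...plus 1 wrong
#' counts(classifyOutcome(init, ideal, act))              # TP=5 TN=3 FP=1 FN=1
#' @export
classifyOutcome <- function(initial, ideal, actual) {
  for (g in list(initial, ideal, actual)) validObject(g)
  if (!sameGeometry(initial, ideal) || !sameGeometry(initial, actual))
    stop("initial, ideal and actual grids must share shape, spacing and origin")
  mi <- initial@mask; mg <- ideal@mask; ma <- actual@mask
  bad <- sum(mg & !mi)
  if (bad > 0)
    stop("ideal outcome is not a subset of the initial tooth (",
         bad, " voxels present in ideal but not in initial)")
  bad <- sum(ma & !mi)
  if (bad > 0)
    stop("actual outcome is not a subset of the initial tooth (",
         bad, " voxels present in actual but not in initial)")
  ClassificationCounts(
    TP = sum(mi & ma & mg),
    TN = sum(mi & !ma & !mg),
    FP = sum(mi & ma & !mg),
    FN = sum(mi & !ma & mg))
}
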