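## Procedural molar phantom.
##
## The phantom is not anatomically faithful to any real tooth; it is a
## score-distribution stand-in: a crown (superellipsoid) with an enamel
## shell, a tapered root, a pulp chamber with four canals, and an
## expert-style ideal access cavity carved as a swept capsule that
## reaches all four canal orifices.  All tissue bodies are filled with
## labelled spheres so the occupancy is genuinely produced by
## occupancyFromSpheres(); the geometry scales with the grid extent, so
## smaller grids give the same tooth at lower resolution.

## Implicit tissue regions, vectorized over world coordinates (cm).
## E = physical extent of the grid; all proportions are relative to E.
toothRegions <- function(E) {
  cx <- E[1] / 2; cz <- E[3] / 2
  crownC <- c(cx, 0.682 * E[2], cz)
  crownA <- c(0.373 * E[1], 0.237 * E[2], 0.373 * E[3])
  shellT <- c(0.071 * E[1], 0.047 * E[2], 0.071 * E[3])
  rootY <- c(0.071, 0.563) * E[2]
  rootR <- 0.302 * E[1]
  pulpC <- c(cx, 0.581 * E[2], cz)
  pulpA <- c(0.151 * E[1], 0.077 * E[2], 0.151 * E[3])
  canTopY <- 0.563 * E[2]; canBotY <- 0.148 * E[2]
  canTopOff <- 0.0756 * E[1]; canBotOff <- 0.0356 * E[1]
  canR <- 0.022 * E[1]

  super4 <- function(x, y, z, c0, a) {
    ((x - c0[1]) / a[1])^4 + ((y - c0[2]) / a[2])^4 + ((z - c0[3]) / a[3])^4
  }
  crown <- function(x, y, z) super4(x, y, z, crownC, crownA) <= 1
  crownCore <- function(x, y, z)
    super4(x, y, z, crownC, crownA - shellT) <= 1
  root <- function(x, y, z) {
    frac <- (y - rootY[1]) / (rootY[2] - rootY[1])
    ok <- y >= rootY[1] & y <= rootY[2]
    rr <- rootR * (0.35 + 0.65 * pmin(pmax(frac, 0), 1))
    ok & ((x - cx)^2 + (z - cz)^2 <= rr^2)
  }
  chamber <- function(x, y, z) {
    ((x - pulpC[1]) / pulpA[1])^2 + ((y - pulpC[2]) / pulpA[2])^2 +
      ((z - pulpC[3]) / pulpA[3])^2 <= 1
  }
  signs <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  canalTop <- cbind(cx + signs[, 1] * canTopOff, canTopY,
                    cz + signs[, 2] * canTopOff)
  canalBot <- cbind(cx + signs[, 1] * canBotOff, canBotY,
                    cz + signs[, 2] * canBotOff)
  canals <- function(x, y, z) {
    inAny <- rep(FALSE, length(x))
    for (i in 1:4) {
      d2 <- pointSegmentDist2(x, y, z, canalTop[i, ], canalBot[i, ])
      inAny <- inAny | d2 <= canR^2
    }
    inAny
  }
  tooth <- function(x, y, z) crown(x, y, z) | root(x, y, z)
  pulp <- function(x, y, z) chamber(x, y, z) | canals(x, y, z)
  enamel <- function(x, y, z) crown(x, y, z) & !crownCore(x, y, z)
  dentin <- function(x, y, z)
    tooth(x, y, z) & !enamel(x, y, z) & !pulp(x, y, z)

  orifices <- cbind(cx + signs[, 1] * canTopOff, 0.5215 * E[2],
                    cz + signs[, 2] * canTopOff)
  idealPath <- rbind(
    c(cx, 0.948 * E[2], cz),
    c(cx, 0.545 * E[2], cz),
    orifices[c(1, 2, 4, 3), ])          # ring order around the floor
  list(tooth = tooth, enamel = enamel, dentin = dentin, pulp = pulp,
       orifices = orifices, idealPath = idealPath,
       toolRadius = 0.142 * E[1])
}

## Squared distance from points to a segment a-b, vectorized over points.
pointSegmentDist2 <- function(x, y, z, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return((x - a[1])^2 + (y - a[2])^2 + (z - a[3])^2)
  }
  t <- ((x - a[1]) * ab[1] + (y - a[2]) * ab[2] + (z - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  (x - (a[1] + t * ab[1]))^2 + (y - (a[2] + t * ab[2]))^2 +
    (z - (a[3] + t * ab[3]))^2
}

## Squared distance from points to a polyline (min over segments).
polylineDist2 <- function(x, y, z, path) {
  d2 <- rep(Inf, length(x))
  for (s in seq_len(nrow(path) - 1L)) {
    d2 <- pmin(d2, pointSegmentDist2(x, y, z, path[s, ], path[s + 1L, ]))
  }
  d2
}

## Mask of voxels within `radius` of the polyline, intersected with `clip`.
capsuleMask <- function(grid, path, radius, clip = NULL) {
  ax <- voxelAxes(grid)
  sh <- gridShape(grid)
  x <- rep(ax[[1]], times = sh[2] * sh[3])
  y <- rep(rep(ax[[2]], each = sh[1]), times = sh[3])
  z <- rep(ax[[3]], each = sh[1] * sh[2])
  m <- array(polylineDist2(x, y, z, path) <= radius^2, dim = sh)
  if (!is.null(clip)) m <- m & clip
  m
}

#' Build a procedural molar phantom
#'
#' Generates a synthetic molar-like tooth: enamel shell, dentin body and
#' pulp chamber/canals are filled with randomly placed labelled spheres
#' (counts scaled down from the production-scale 100k/170k/10k
#' composition; configurable), voxelized with [occupancyFromSpheres()]
#' in boolean-spheres mode, and carved with an ideal access cavity — a
#' capsule swept along a reference drill path that descends through the
#' crown and visits all four canal orifices.  The ideal outcome is the
#' occupancy minus this cavity.  Fully reproducible per seed.
#'
#' @param shape Grid dimensions (default 90 x 135 x 90).
#' @param spacing Voxel spacing in cm (default 0.0125); the physical
#'   tooth scales with `shape * spacing`.
#' @param nEnamel,nDentin,nPulp Sphere counts per tissue.
#' @param coverFactor Sphere radius multiplier relative to the
#'   even-coverage radius `(V/n)^(1/3)`; larger values close pores at
#'   the cost of a bulgier surface.
#' @param seed Integer seed.
#' @return A [ToothPhantom-class].
#' @examples
#' ph <- buildToothPhantom(shape = c(30, 45, 30), spacing = 0.0375,
#'                         nEnamel = 400, nDentin = 700, nPulp = 60)
#' ph
#' @export
buildToothPhantom <- function(shape = DEFAULT_SHAPE,
                              spacing = DEFAULT_SPACING,
                              nEnamel = 5000, nDentin = 8500, nPulp = 500,
                              coverFactor = 1.25, seed = 1L) {
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(shape) != 3L || any(shape < 20L))
    stop("degenerate grid: each dimension must be >= 20 voxels")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (nEnamel < 50 || nDentin < 50 || nPulp < 10)
    stop("sphere counts too small to cover the tissue bodies")

  E <- shape * spacing
  reg <- toothRegions(E)
  grid0 <- emptyGrid(shape, spacing)
  ax <- voxelAxes(grid0)
  x <- rep(ax[[1]], times = shape[2] * shape[3])
  y <- rep(rep(ax[[2]], each = shape[1]), times = shape[3])
  z <- rep(ax[[3]], each = shape[1] * shape[2])
  vv <- voxelVolume(grid0)

  sampleTissue <- function(regionFn, n, label) {
    inReg <- which(regionFn(x, y, z))
    if (length(inReg) == 0L) stop("tissue region '", label, "' is empty")
    V <- length(inReg) * vv
    r <- coverFactor * (V / n)^(1 / 3)
    pick <- sample(inReg, n, replace = n > length(inReg))
    jit <- matrix(runif(3L * n, -0.5, 0.5), ncol = 3L) *
      rep(spacing, each = n)
    ctr <- cbind(x[pick], y[pick], z[pick]) + jit
    list(centers = ctr, radii = rep(r, n), labels = rep(label, n))
  }

  built <- withSeed(seed, {
    en <- sampleTissue(reg$enamel, nEnamel, "enamel")
    de <- sampleTissue(reg$dentin, nDentin, "dentin")
    pu <- sampleTissue(reg$pulp, nPulp, "pulp")
    ## deterministic dentin spheres guarantee material at every orifice
    anchorR <- max(3 * max(spacing), 0.02 * E[1])
    an <- list(centers = reg$orifices, radii = rep(anchorR, 4L),
               labels = rep("dentin", 4L))
    SphereSet(rbind(en$centers, de$centers, pu$centers, an$centers),
              c(en$radii, de$radii, pu$radii, an$radii),
              c(en$labels, de$labels, pu$labels, an$labels))
  })

  occupancy <- occupancyFromSpheres(built, shape, spacing, kernel = "hard")
  cavity <- withMask(grid0,
    capsuleMask(occupancy, reg$idealPath, reg$toolRadius,
                clip = occupancy@mask))
  idealOutcome <- withMask(grid0, occupancy@mask & !cavity@mask)

  new("ToothPhantom", spheres = built, occupancy = occupancy,
      idealCavity = cavity, idealOutcome = idealOutcome,
      orificeCenters = reg$orifices, idealPath = reg$idealPath,
      toolRadius = reg$toolRadius,
      config = list(shape = shape, spacing = spacing, nEnamel = nEnamel,
                    nDentin = nDentin, nPulp = nPulp,
                    coverFactor = coverFactor, seed = seed))
}
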