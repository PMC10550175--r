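## Shared fixtures, generated in code.  Phantoms are cached per session.

tinyPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- buildToothPhantom(shape = c(30, 45, 30), spacing = 0.0375,
                                  nEnamel = 400, nDentin = 700, nPulp = 60,
                                  seed = 202)
    cache
  }
})

defaultPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildToothPhantom(seed = 7)
    cache
  }
})

## A random (initial, ideal, actual) grid triple satisfying the subset
## preconditions of classifyOutcome().
randomMaskTriple <- function(seed, shape = c(8, 8, 8)) {
  set.seed(seed)
  init <- array(runif(prod(shape)) > 0.3, dim = shape)
  ideal <- init & (array(runif(prod(shape)), dim = shape) > 0.4)
  act <- init & (array(runif(prod(shape)), dim = shape) > 0.4)
  list(initial = VoxelGrid(init, spacing = 0.1),
       ideal = VoxelGrid(ideal, spacing = 0.1),
       actual = VoxelGrid(act, spacing = 0.1))
}

## A centred sphere voxelized on a cubic grid.
sphereGrid <- function(radius = 0.5, spacing = 0.02,
                       kernel = "hard") {
  n <- ceiling(2.6 * radius / spacing)
  ctr <- rep(n * spacing / 2, 3)
  occupancyFromSpheres(SphereSet(rbind(ctr), radius),
                       shape = rep(n, 3), spacing = spacing,
                       kernel = kernel)
}

## Random rubric-total vectors for two raters over n outcomes.
randomRaterPair <- function(seed, n = 6) {
  set.seed(seed)
  a <- sample(0:15, n, replace = TRUE)
  b <- pmin(pmax(a + sample(-2:2, n, replace = TRUE), 0), 15)
  list(a = a, b = b)
}
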