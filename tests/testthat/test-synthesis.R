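test_that("phantom construction is deterministic and well-formed", {
  ph <- tinyPhantom()
  ph2 <- buildToothPhantom(shape = c(30, 45, 30), spacing = 0.0375,
                           nEnamel = 400, nDentin = 700, nPulp = 60,
                           seed = 202)
  expect_identical(gridMask(ph@occupancy), gridMask(ph2@occupancy))
  expect_identical(gridMask(ph@idealCavity), gridMask(ph2@idealCavity))

  expect_gt(voxelCount(ph@idealCavity), 0)
  ## cavity and ideal outcome are subsets of the occupancy
  expect_false(any(gridMask(ph@idealCavity) & !gridMask(ph@occupancy)))
  expect_false(any(gridMask(ph@idealOutcome) & !gridMask(ph@occupancy)))
  ## every orifice centre voxel lies inside the ideal cavity
  sh <- gridShape(ph@occupancy)
  sp <- gridSpacing(ph@occupancy)
  for (i in 1:4) {
    idx <- pmin(pmax(round((ph@orificeCenters[i, ] -
                            gridOrigin(ph@occupancy)) / sp) + 1, 1), sh)
    expect_true(ph@idealCavity@mask[idx[1], idx[2], idx[3]])
  }
  expect_error(buildToothPhantom(shape = c(5, 5, 5)), "degenerate")
})

test_that("pulp spheres sit strictly inside the dentin body", {
  ph <- tinyPhantom()
  E <- gridShape(ph@occupancy) * gridSpacing(ph@occupancy)
  reg <- drillscore:::toothRegions(E)
  pulpIdx <- which(ph@spheres@labels == "pulp")
  expect_gt(length(pulpIdx), 0)
  ctr <- ph@spheres@centers[pulpIdx, , drop = FALSE]
  ## all pulp spheres are interior: inside the tooth body, never in the
  ## enamel shell; the bulk sit in the pulp region itself (sub-voxel
  ## placement jitter can nudge a canal-wall centre into dentin)
  expect_true(all(reg$tooth(ctr[, 1], ctr[, 2], ctr[, 3])))
  expect_false(any(reg$enamel(ctr[, 1], ctr[, 2], ctr[, 3])))
  expect_gt(mean(reg$pulp(ctr[, 1], ctr[, 2], ctr[, 3])), 0.9)
})

test_that("the ideal plan reproduces the ideal outcome exactly", {
  ph <- tinyPhantom()
  out <- simulateOutcome(ph, idealPlan(ph))
  expect_identical(gridMask(out), gridMask(ph@idealOutcome))
  cc <- classifyOutcome(ph@occupancy, ph@idealOutcome, out)
  expect_equal(dentistScoreFromCounts(cc), 0)
  expect_equal(f1Score(cc), 1)
})

test_that("full under-drilling leaves the tooth untouched", {
  ph <- tinyPhantom()
  out <- simulateOutcome(ph, idealPlan(ph, underdrillFraction = 1))
  expect_identical(gridMask(out), gridMask(ph@occupancy))
  cc <- classifyOutcome(ph@occupancy, ph@idealOutcome, out)
  expect_equal(cc@FN, 0)
  expect_equal(cc@TN, 0)
})

test_that("over- and under-drilling sweeps increase FN/FP and D monotonically", {
  ph <- tinyPhantom()
  fn <- c(); dOver <- c()
  for (ext in c(0, 0.05, 0.1, 0.15)) {
    cc <- classifyOutcome(ph@occupancy, ph@idealOutcome,
                          simulateOutcome(ph, idealPlan(ph,
                            overdrillExtent = ext)))
    fn <- c(fn, cc@FN); dOver <- c(dOver, dentistScoreFromCounts(cc))
  }
  expect_true(all(diff(fn) > 0))
  expect_true(all(diff(dOver) > 0))

  fp <- c(); dUnder <- c()
  for (uf in c(0, 0.25, 0.5, 0.75)) {
    cc <- classifyOutcome(ph@occupancy, ph@idealOutcome,
                          simulateOutcome(ph, idealPlan(ph,
                            underdrillFraction = uf)))
    fp <- c(fp, cc@FP); dUnder <- c(dUnder, dentistScoreFromCounts(cc))
  }
  expect_true(all(diff(fp) > 0))
  expect_true(all(diff(dUnder) > 0))
})

test_that("roughness jitter is reproducible per plan seed", {
  ph <- tinyPhantom()
  p1 <- idealPlan(ph, roughness = 0.02, seed = 9L)
  a <- simulateOutcome(ph, p1)
  b <- simulateOutcome(ph, p1)
  expect_identical(gridMask(a), gridMask(b))
  p2 <- idealPlan(ph, roughness = 0.02, seed = 10L)
  expect_false(identical(gridMask(simulateOutcome(ph, p2)), gridMask(a)))
})

test_that("outcome series: determinism, validity and coverage", {
  ph <- tinyPhantom()
  s1 <- generateOutcomeSeries(ph, 12, seed = 5, keepMasks = TRUE)
  s2 <- generateOutcomeSeries(ph, 12, seed = 5)
  expect_equal(s1$manifest, s2$manifest)
  ## every actual mask is a subset of the initial occupancy
  for (out in s1$outcomes)
    expect_false(any(gridMask(out) & !gridMask(ph@occupancy)))
  ## single outcome works
  s3 <- generateOutcomeSeries(ph, 1, seed = 2)
  expect_equal(nrow(s3$manifest), 1)
  expect_s3_class(s1$scoreHistogram, "histogram")
})

test_that("series scores cover a wide range and feed essential selection", {
  ph <- tinyPhantom()
  ser <- generateOutcomeSeries(ph, 40, seed = 17)
  m <- ser$manifest
  expect_gt(max(m$F1) - min(m$F1), 0.4)
  expect_gt(max(m$S) - min(m$S), 0.4)
  expect_true(all(m$P > 0.9))
  sel <- selectEssentialOutcomes(m$F1, 10)
  expect_length(unique(sel), 10)
  binW <- (max(m$F1) - min(m$F1)) / 10
  expect_lte(min(m$F1[sel]), min(m$F1) + binW)
  expect_gte(max(m$F1[sel]), max(m$F1) - binW)
})

test_that("a virtual expert's per-surface ratings track the Dentist score", {
  ph <- tinyPhantom()
  ser <- generateOutcomeSeries(ph, 14, seed = 23, keepMasks = TRUE)
  sh <- gridShape(ph@occupancy)
  sp <- gridSpacing(ph@occupancy)
  org <- gridOrigin(ph@occupancy)
  cx <- org[1] + (sh[1] - 1) * sp[1] / 2
  cz <- org[3] + (sh[3] - 1) * sp[3] / 2
  floorY <- min(ph@orificeCenters[, 2])
  ax <- lapply(1:3, function(a) org[a] + (seq_len(sh[a]) - 1) * sp[a])
  X <- array(rep(ax[[1]], times = sh[2] * sh[3]), dim = sh)
  Y <- array(rep(rep(ax[[2]], each = sh[1]), times = sh[3]), dim = sh)
  Z <- array(rep(ax[[3]], each = sh[1] * sh[2]), dim = sh)
  nInit <- voxelCount(ph@occupancy)
  breaks <- nInit * c(0.002, 0.01, 0.04)
  virtualExpert <- function(actual) {
    err <- (gridMask(actual) != gridMask(ph@idealOutcome)) &
      gridMask(ph@occupancy)
    zones <- list(err & Y > floorY & X < cx, err & Y > floorY & X >= cx,
                  err & Y > floorY & Z < cz, err & Y > floorY & Z >= cz,
                  err & Y <= floorY)
    sum(vapply(zones, function(zn) findInterval(sum(zn), breaks),
               numeric(1)))
  }
  vTotals <- vapply(ser$outcomes, virtualExpert, numeric(1))
  r <- pearsonCorrelation(ser$manifest$D, vTotals)$r
  expect_gt(r, 0)
})

test_that("cohort generation is deterministic and calibrated", {
  c1 <- generateCohort(10, seed = 4)
  c2 <- generateCohort(10, seed = 4)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 40)
  expect_identical(levels(c1$group),
                   c("stereo_aligned", "mono_aligned",
                     "stereo_misaligned", "mono_misaligned"))
  expect_true(all(c1$e0 >= 0 & c1$e1 >= 0))
  expect_true(all(c1$e0 %% 0.5 == 0))       # half-integer rubric grid

  ## zero-effect config: pooled gain centred at 0
  g <- vapply(1:300, function(i) {
    co <- generateCohort(10, config = nullCohortConfig(), seed = 7000 + i)
    mean(co$e1 - co$e0)
  }, numeric(1))
  expect_lt(abs(mean(g)), 3 * sd(g) / sqrt(length(g)))
})

test_that("suitability and transfer sign pattern emerges across replicates", {
  g1 <- g4 <- tran <- numeric(60)
  for (i in 1:60) {
    co <- generateCohort(10, seed = 5000 + i)
    ta <- transferAnalyses(co)
    g1[i] <- ta$r[ta$level == "stereo_aligned" & ta$analysis == "suitability"]
    g4[i] <- ta$r[ta$level == "mono_misaligned" & ta$analysis == "suitability"]
    tran[i] <- ta$r[ta$level == "all" & ta$analysis == "transfer"]
  }
  expect_gt(mean(g1 > 0, na.rm = TRUE), 0.5)
  expect_gt(mean(g4 < 0, na.rm = TRUE), 0.5)
  expect_gt(mean(tran > 0, na.rm = TRUE), 0.5)
})
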