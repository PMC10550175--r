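test_that("learning gain arithmetic and antisymmetry", {
  expect_equal(learningGain(3, 2), -1)
  expect_equal(learningGain(4.5, 4.5), 0)
  expect_equal(learningGain(2.5, 6.5), 4)
  for (seed in 1:5) {
    set.seed(seed)
    e0 <- runif(1, 0, 15); e1 <- runif(1, 0, 15)
    expect_equal(learningGain(e0, e1), -learningGain(e1, e0))
  }
})

test_that("IQR outlier filter matches brute-force Tukey fences", {
  v <- c(1, 2, 3, 100)
  res <- iqrOutlierFilter(v)
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  lo <- q[1] - 1.5 * (q[2] - q[1]); hi <- q[2] + 1.5 * (q[2] - q[1])
  expect_identical(res$removed, v[v < lo | v > hi])
  expect_identical(res$removed, 100)
  expect_length(iqrOutlierFilter(rep(3, 6))$removed, 0)
  sym <- c(-2, -1, 0, 1, 2)
  expect_identical(iqrOutlierFilter(sym)$kept, sym)
  expect_error(iqrOutlierFilter(c(1, 2, 3)), "at least 4")
})

test_that("paired one-tailed t-test: examples and formula oracle", {
  pre <- c(3, 4, 5, 6)
  res <- pairedTOneTailed(pre, pre)
  expect_equal(res$t, 0); expect_equal(res$p, 0.5)

  res <- pairedTOneTailed(c(3, 4, 5), c(2, 3, 4))
  expect_true(isUndefined(res$t))

  post <- c(2, 4, 3, 6)
  res <- pairedTOneTailed(pre, post, "less")
  d <- post - pre
  tOracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, tOracle, tolerance = 1e-9)
  expect_equal(res$df, 3)
  expect_equal(res$p, pt(tOracle, 3), tolerance = 1e-9)
  ## direction flip
  resG <- pairedTOneTailed(pre, post, "greater")
  expect_equal(resG$p, 1 - pt(tOracle, 3), tolerance = 1e-9)
})

test_that("Welch t-test: formula oracle and pooled-df limit", {
  expect_equal(welchT(c(1, 2, 3), c(1, 2, 3))$t, 0)
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  res <- welchT(a, b)
  va <- var(a) / 3; vb <- var(b) / 5
  tOracle <- (mean(a) - mean(b)) / sqrt(va + vb)
  dfOracle <- (va + vb)^2 / (va^2 / 2 + vb^2 / 4)
  expect_equal(res$t, tOracle, tolerance = 1e-9)
  expect_equal(res$df, dfOracle, tolerance = 1e-9)
  ## equal variances, equal n: Welch df equals the pooled df
  set.seed(8)
  x <- rnorm(20); y <- rnorm(20)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(x) + 1   # same variance as x
  expect_equal(welchT(x, y)$df, 38, tolerance = 1e-9)
  expect_true(isUndefined(welchT(c(1, 1), c(2, 2))$t))
})

test_that("mean eye-tooth distance honours the hit filter", {
  g <- data.frame(ex = 0, ey = 0, ez = 0, hx = 20, hy = 0, hz = 0,
                  hit = TRUE)
  expect_equal(meanEyeToothDistance(g), 20)
  g <- data.frame(ex = c(0, 0, 0), ey = 0, ez = 0,
                  hx = c(10, 30, 500), hy = 0, hz = 0,
                  hit = c(TRUE, TRUE, FALSE))
  expect_equal(meanEyeToothDistance(g), 20)
  g$hit <- FALSE
  expect_true(isUndefined(meanEyeToothDistance(g)))
})

test_that("screen coverage arithmetic", {
  expect_equal(round(screenCoverageFraction(c(119, 119),
                                            c(2880, 1600)), 2), 0.31)
  expect_equal(screenCoverageFraction(c(2880, 1600), c(2880, 1600)), 100)
  expect_equal(screenCoverageFraction(c(1, 1), c(10, 10)), 1)
  expect_error(screenCoverageFraction(c(1, 1), c(0, 10)), "positive")
})

test_that("angle delta wraps into [-180, 180] with the stated boundary", {
  expect_equal(angleDelta(c(10, 20, 30), c(10, 20, 30)), c(0, 0, 0))
  expect_equal(angleDelta(c(350, 0, 0), c(10, 0, 0)), c(-20, 0, 0))
  expect_equal(angleDelta(c(-170, 0, 0), c(170, 0, 0)), c(20, 0, 0))
  expect_equal(angleDelta(180, 0), 180)
  expect_equal(angleDelta(-180, 0), -180)
  for (seed in 1:10) {
    set.seed(seed)
    a <- runif(3, -720, 720); b <- runif(3, -720, 720)
    d <- angleDelta(a, b)
    expect_true(all(d >= -180 & d <= 180))
    ## antisymmetry away from the boundary
    if (all(abs(abs(d) - 180) > 1e-9))
      expect_equal(angleDelta(b, a), -d)
  }
})

test_that("hand-tool calibration offsets", {
  ## controller already at target: zero offsets
  cal <- calibrationOffset(Pose(), c(22, 26, -7), c(0, 0, 90),
                           Pose(c(22, 26, -7), c(0, 0, 90)))
  expect_equal(cal$offset@position, c(0, 0, 0))
  expect_equal(cal$offset@rotation, c(0, 0, 0))
  expect_equal(cal$target@position, c(22, 26, -7))
  ## angle normalization across the wrap
  cal <- calibrationOffset(Pose(rotation = c(350, 0, 0)), c(0, 0, 0),
                           c(0, 0, 0), Pose(rotation = c(10, 0, 0)))
  expect_equal(cal$offset@rotation[1], -20)
})

test_that("transfer analyses recover constructed perfect correlations", {
  set.seed(5)
  n <- 20
  grp <- rep(c("stereo_aligned", "mono_aligned", "stereo_misaligned",
               "mono_misaligned"), each = 5)
  e0 <- runif(n, 1, 6)
  gain <- rnorm(n, 0, 1)
  co <- data.frame(group = grp, e0 = e0, e1 = e0 + gain)
  ## trial scores an affine function of e0; simulator gain equals real gain
  for (j in 1:6) co[[paste0("t", j)]] <- 0.5 * e0 + 1
  co$t6 <- co$t1 + gain
  res <- transferAnalyses(co, removeOutliers = FALSE)
  suit <- res[res$analysis == "suitability", ]
  expect_true(all(abs(suit$r[suit$stratum != "group" |
                             suit$n >= 3] - 1) < 1e-9))
  tran <- res[res$analysis == "transfer", ]
  expect_true(all(abs(tran$r - 1) < 1e-9))
  ## outlier handling: an absurd gain is removed before analysis
  co2 <- co; co2$e1[1] <- co2$e0[1] + 50
  res2 <- transferAnalyses(co2, removeOutliers = TRUE)
  expect_equal(attr(res2, "removedGains"), 50)
  expect_equal(res2$n[res2$stratum == "all"][1], n - 1)
})

test_that("day-1 measure options differ when trials differ", {
  co <- generateCohort(5, seed = 31)
  r1 <- transferAnalyses(co, day1 = "mean13")
  r2 <- transferAnalyses(co, day1 = "trial1")
  s1 <- r1$r[r1$stratum == "all" & r1$analysis == "suitability"]
  s2 <- r2$r[r2$stratum == "all" & r2$analysis == "suitability"]
  expect_false(isTRUE(all.equal(s1, s2)))
})
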