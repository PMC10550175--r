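test_that("component scores and rescaling match direct evaluation", {
  cs <- componentScores(ClassificationCounts(TP = 1000, FP = 20, FN = 200),
                        warn = FALSE)
  expect_equal(cs@P, 1000 / 1020, tolerance = 1e-12)
  expect_equal(cs@S, 1000 / 1200, tolerance = 1e-12)
  expect_equal(cs@Ptilde, (1000 / 1020 - 0.95) / 0.05, tolerance = 1e-12)
  expect_equal(cs@Stilde, (1000 / 1200 - 0.2) / 0.8, tolerance = 1e-12)

  perfect <- componentScores(ClassificationCounts(TP = 10))
  expect_equal(c(perfect@P, perfect@S, perfect@Ptilde, perfect@Stilde),
               c(1, 1, 1, 1))

  anchor <- componentScores(ClassificationCounts(TP = 20, FN = 80))
  expect_equal(anchor@S, 0.2)
  expect_equal(anchor@Stilde, 0)

  expect_error(componentScores(ClassificationCounts(TP = 0, FN = 5)),
               "precision undefined")
  expect_error(componentScores(ClassificationCounts(TP = 0, FP = 5)),
               "sensitivity undefined")
  expect_warning(componentScores(ClassificationCounts(TP = 10, FN = 90)),
                 "empirical window")
})

test_that("Dentist score hits its anchors exactly", {
  ## perfect outcome
  expect_equal(dentistScore(componentScores(ClassificationCounts(TP = 5))), 0)
  ## lower anchors S = 0.2, P = 0.95
  low <- componentScores(ClassificationCounts(TP = 19, FP = 1, FN = 76),
                         warn = FALSE)
  expect_equal(low@S, 0.2); expect_equal(low@P, 0.95)
  expect_equal(dentistScore(low), 15)
  expect_equal(dentistScoreFromCounts(
    ClassificationCounts(TP = 19, FP = 1, FN = 76)), 15)
})

test_that("Dentist closed form matches hand arithmetic and simplifications", {
  cc <- ClassificationCounts(TP = 1000, FP = 20, FN = 200)
  hand <- 15 * (32 * 20 * 1000 + 3 * 200 * 1000 + 35 * 200 * 20) /
    (4 * 1200 * 1020)
  expect_equal(dentistScoreFromCounts(cc), hand, tolerance = 1e-12)
  expect_equal(hand, 4.227941, tolerance = 1e-6)
  expect_equal(dentistScoreFromCounts(ClassificationCounts(TP = 7)), 0)
  ## FP = 0, FN = 4 TP simplifies to 9
  expect_equal(dentistScoreFromCounts(
    ClassificationCounts(TP = 50, FN = 200)), 9, tolerance = 1e-12)
})

test_that("the two Dentist formulations agree on random count triples", {
  set.seed(42)
  for (i in 1:500) {
    cc <- ClassificationCounts(TP = sample(1:10000, 1),
                               FP = sample(0:5000, 1),
                               FN = sample(0:5000, 1))
    d5 <- dentistScore(componentScores(cc, warn = FALSE))
    d6 <- dentistScoreFromCounts(cc)
    expect_lt(abs(d5 - d6), 1e-9 * (1 + abs(d6)))
  }
})

test_that("F1 baseline matches hand arithmetic", {
  expect_equal(f1Score(ClassificationCounts(TP = 10)), 1)
  expect_equal(f1Score(ClassificationCounts(TP = 1000, FP = 20, FN = 200)),
               2000 / 2220, tolerance = 1e-12)
  expect_equal(f1Score(ClassificationCounts(TP = 0, FP = 1, FN = 1)), 0)
  expect_error(f1Score(ClassificationCounts(TP = 0)), "undefined")
})

test_that("orientation: D is a distance, F1 a similarity", {
  ## progressively more over-drilling
  ccs <- lapply(c(0, 50, 150, 400), function(fn)
    ClassificationCounts(TP = 1000 - fn, FN = fn, FP = 5, TN = 100))
  D <- vapply(ccs, dentistScoreFromCounts, numeric(1))
  F1 <- vapply(ccs, f1Score, numeric(1))
  S <- vapply(ccs, function(cc) cc@TP / (cc@TP + cc@FN), numeric(1))
  expect_identical(order(D), rev(order(S)))
  expect_true(all(diff(D) > 0))
  expect_true(all(diff(F1) < 0))
})

test_that("metric suite covers 24 metrics with correct values and markers", {
  ms <- metricSuite(ClassificationCounts(TP = 1000, TN = 780, FP = 20,
                                         FN = 200))
  expect_gte(nrow(ms), 24)
  expect_equal(ms$value[ms$metric == "jaccard"], 1000 / 1220,
               tolerance = 1e-12)
  expect_equal(ms$value[ms$metric == "threat_score"],
               ms$value[ms$metric == "jaccard"])
  perfect <- metricSuite(ClassificationCounts(TP = 50, TN = 50))
  val <- function(m, x) x$value[x$metric == m]
  expect_equal(val("accuracy", perfect), 1)
  expect_equal(val("jaccard", perfect), 1)
  expect_equal(val("mcc", perfect), 1)
  ## TN = 0 with FP > 0: specificity defined and zero
  z <- metricSuite(ClassificationCounts(TP = 10, TN = 0, FP = 5, FN = 2))
  expect_equal(val("specificity", z), 0)
  ## undefined entries carry a reason, never a silent 0
  u <- metricSuite(ClassificationCounts(TP = 10, TN = 5, FP = 0, FN = 0))
  dor <- u[u$metric == "dor", ]
  expect_true(is.na(dor$value))
  expect_match(dor$note, ".")
  lrp <- u[u$metric == "lr_plus", ]
  expect_true(is.na(lrp$value))
})

test_that("essential-outcome selection matches a brute-force bin search", {
  scores <- seq(0, 1, length.out = 240)
  k <- 20
  sel <- selectEssentialOutcomes(scores, k)
  expect_length(unique(sel), k)
  width <- 1 / k
  centers <- (seq_len(k) - 0.5) * width
  ## brute-force oracle: nearest sample to each bin centre
  oracle <- vapply(centers, function(cen) which.min(abs(scores - cen)),
                   integer(1))
  expect_identical(sort(sel), sort(oracle))
  expect_true(all(abs(scores[sel] - centers) <= width / 2 + 1e-12))
})

test_that("essential-outcome selection edge cases", {
  s <- c(5, 1, 3, 2, 4)
  expect_setequal(selectEssentialOutcomes(s, 5), 1:5)      # k = n
  expect_identical(selectEssentialOutcomes(rep(2, 4), 1), 1L)
  expect_error(selectEssentialOutcomes(s, 6), "exceeds the number")
  expect_error(selectEssentialOutcomes(c(1, 1, 2), 3), "distinct")
  ## empty-bin back-fill keeps indices distinct and spans the range
  gap <- c(0, 0.01, 0.02, 0.98, 1)
  sel <- selectEssentialOutcomes(gap, 4)
  expect_length(unique(sel), 4)
  expect_lte(min(gap[sel]), 0.02)
  expect_equal(max(gap[sel]), 1)
})
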