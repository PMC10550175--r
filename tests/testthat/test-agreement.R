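test_that("rubric totals and means", {
  expect_equal(expertTotalError(ExpertRating(c(0, 0, 0, 0, 0))), 0)
  expect_equal(expertTotalError(ExpertRating(c(3, 3, 3, 3, 3))), 15)
  expect_equal(expertTotalError(ExpertRating(c(1, 0, 2, 0, 3))), 6)
  expect_error(ExpertRating(c(1, 0, 4, 0, 3)), "0, 1, 2, 3")
  expect_error(ExpertRating(c(1, 0, 2, 0)), "length 5")

  r6 <- ExpertRating(c(1, 1, 2, 1, 1), "A")   # total 6
  r7 <- ExpertRating(c(2, 1, 2, 1, 1), "B")   # total 7
  expect_equal(meanExpertError(list(r6, r7)), 6.5)
  expect_equal(meanExpertError(list(r7, r6)), 6.5)   # rater-order invariant
  expect_equal(meanExpertError(list(ExpertRating(c(1, 1, 1, 1, 0)))), 4)
  expect_error(meanExpertError(list()), "at least one")
})

test_that("Cohen's kappa matches hand contingency tables", {
  expect_equal(cohensKappa(c(0, 2, 5, 9), c(0, 2, 5, 9)), 1)
  expect_equal(cohensKappa(c(0, 0, 1, 1), c(1, 1, 0, 0),
                           weighting = "none"), -1)
  ## p_o = 0.75, p_e = 0.5 -> kappa = 0.5
  expect_equal(cohensKappa(c(0, 1, 0, 1), c(0, 1, 1, 1),
                           weighting = "none"), 0.5)
  expect_true(isUndefined(cohensKappa(c(2, 2, 2), c(2, 2, 2))))
})

test_that("kappa against an independent contingency-table computation", {
  for (seed in 1:25) {
    rp <- randomRaterPair(seed, n = 6)
    ## oracle: explicit double loop over the observed category set
    cats <- sort(unique(c(rp$a, rp$b)))
    K <- length(cats)
    if (K < 2) next
    O <- matrix(0, K, K)
    for (i in seq_along(rp$a)) {
      O[match(rp$a[i], cats), match(rp$b[i], cats)] <-
        O[match(rp$a[i], cats), match(rp$b[i], cats)] + 1
    }
    O <- O / length(rp$a)
    for (wt in c("none", "linear")) {
      W <- matrix(0, K, K)
      for (i in 1:K) for (j in 1:K) {
        W[i, j] <- if (wt == "none") as.numeric(i != j) else
          abs(cats[i] - cats[j]) / (max(cats) - min(cats))
      }
      E <- rowSums(O) %o% colSums(O)
      expected <- 1 - sum(W * O) / sum(W * E)
      expect_equal(cohensKappa(rp$a, rp$b, weighting = wt), expected,
                   tolerance = 1e-9)
    }
  }
})

test_that("kappa never exceeds 1 and equals 1 only at perfect agreement", {
  for (seed in 1:20) {
    rp <- randomRaterPair(seed, n = 8)
    k <- cohensKappa(rp$a, rp$b)
    if (isUndefined(k)) next
    expect_lte(k, 1 + 1e-12)
    if (abs(k - 1) < 1e-12) expect_identical(rp$a, rp$b)
  }
})

test_that("ICC matches a mean-squares ANOVA oracle", {
  for (seed in 1:20) {
    rp <- randomRaterPair(seed, n = 6)
    if (var(c(rp$a, rp$b)) == 0) next
    ## oracle: mean squares from lm() on the long-format two-way layout
    d <- data.frame(score = c(rp$a, rp$b),
                    subj = factor(rep(1:6, 2)),
                    rater = factor(rep(1:2, each = 6)))
    an <- anova(lm(score ~ subj + rater, data = d))
    MSR <- an["subj", "Mean Sq"]; MSC <- an["rater", "Mean Sq"]
    MSE <- an["Residuals", "Mean Sq"]
    icc21 <- (MSR - MSE) / (MSR + MSE + 2 * (MSC - MSE) / 6)
    icc2k <- (MSR - MSE) / (MSR + (MSC - MSE) / 6)
    got21 <- iccTwoRater(rp$a, rp$b, "ICC(2,1)")
    got2k <- iccTwoRater(rp$a, rp$b, "ICC(2,k)")
    if (isUndefined(got21)) next
    expect_equal(got21, icc21, tolerance = 1e-9)
    expect_equal(got2k, icc2k, tolerance = 1e-9)
  }
})

test_that("ICC edge behaviour", {
  a <- c(1, 3, 5, 7, 2)
  expect_equal(iccTwoRater(a, a), 1)
  ## constant shift: consistency preserved, absolute agreement penalized
  shifted <- iccTwoRater(a, a + 2, "ICC(2,1)")
  expect_lt(shifted, 1)
  expect_gt(shifted, 0)
  expect_true(isUndefined(iccTwoRater(c(3, 3, 3), c(3, 3, 3))))
})

test_that("IBMD matches the reference formula and its conventions", {
  expect_equal(ibmd(c(2, 5, 9), c(2, 5, 9)), 0)
  expect_equal(ibmd(2, 4), log(3) / log(5), tolerance = 1e-12)
  expect_equal(ibmd(2, 4), 0.6826, tolerance = 1e-4)
  expect_equal(ibmd(0, 0), 0)
  expect_error(ibmd(c(-1, 2), c(0, 2)), "non-negative")
  ## symmetry on random non-negative vectors
  for (seed in 1:10) {
    set.seed(seed)
    x <- runif(8, 0, 15); y <- runif(8, 0, 15)
    expect_equal(ibmd(x, y), ibmd(y, x), tolerance = 1e-12)
  }
})

test_that("Pearson correlation and degenerate marker", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  expect_equal(pearsonCorrelation(x, c(1, 3, 2, 4))$r, 0.8,
               tolerance = 1e-12)
  expect_true(isUndefined(pearsonCorrelation(x, rep(2, 4))$r))
})

test_that("agreement report bundles the validation statistics", {
  e1 <- c(2, 5, 9, 12, 3, 7); e2 <- c(3, 5, 8, 12, 4, 7)
  rep <- agreementReport(e1, e2, auto = (e1 + e2) / 2 + 0.3)
  expect_equal(rep$n, 6)
  expect_gt(rep$kappa, 0)
  expect_gt(rep$icc, 0.9)
  expect_gt(rep$ibmd, 0)
  expect_gt(rep$pearson$r, 0.99)
})
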