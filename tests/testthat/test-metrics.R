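test_that("confusion counts are exact and reject malformed input", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  cc2 <- confusion(c("sepsis", "no_sepsis"), c(1, 0))
  expect_equal(cc2$tp + cc2$tn, 2L)
  expect_equal(cc2$fp + cc2$fn, 0L)
  expect_error(confusion(integer(0), integer(0)), "empty")
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
  expect_error(confusion(c("abstain", "sepsis"), c(1, 1)), "abstain")
})

test_that("rate metrics match hand counts and Wald half-widths", {
  cc <- confusion(c(rep(1, 9), 0), rep(1, 10))
  rm <- rate_metrics(cc)
  expect_equal(rm$sensitivity$value, 0.9)
  expect_false(rm$specificity$defined) # no true-negative denominator
  expect_equal(rm$npv$value, 0) # one negative call, and it was wrong

  # p = 0.5 over denominator 100: half-width = z * sqrt(0.25/100)
  cc2 <- confusion(c(rep(1, 50), rep(0, 50)), rep(1, 100))
  hw <- (rm2 <- rate_metrics(cc2, alpha = 0.05))$sensitivity
  expect_equal(hw$value, 0.5)
  expected_hw <- qnorm(0.975) * sqrt(0.5 * 0.5 / 100)
  expect_equal(expected_hw, 0.0979982, tolerance = 1e-5)
  expect_equal(hw$ci_high - hw$value, expected_hw, tolerance = 1e-12)
  expect_equal(hw$value - hw$ci_low, expected_hw, tolerance = 1e-12)
  expect_identical(hw$ci_method, "wald")
})

test_that("AUC equals the Mann-Whitney statistic on hand-checkable cases", {
  expect_equal(auc_estimate(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$value, 0.75)
  expect_equal(auc_estimate(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$value, 1.0)
  expect_false(auc_estimate(c(0.1, 0.9), c(1, 1))$defined)
  # ties count half
  expect_equal(auc_estimate(c(0.5, 0.5), c(1, 0))$value, 0.5)
})

test_that("AUC and A-PPV match exhaustive brute force for small n", {
  set.seed(42)
  scores <- sort(runif(8)) # distinct
  for (bits in 1:(2^8 - 2)) {
    y <- as.integer(intToBits(bits)[1:8])
    if (sum(y) == 0 || sum(y) == 8) next
    expect_equal(auc_estimate(scores, y)$value, brute_auc(scores, y))
    expect_equal(average_ppv_estimate(scores, y)$value, brute_ap(scores, y))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  s <- runif(300)
  y <- rbinom(300, 1, plogis(4 * s - 2))
  expect_equal(auc_estimate(s, y)$value,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("average PPV matches hand enumerations", {
  expect_equal(average_ppv_estimate(c(0.9, 0.8, 0.7), c(1, 0, 1))$value,
               (1 + 2 / 3) / 2)
  expect_equal(average_ppv_estimate(c(0.9, 0.8, 0.7, 0.6, 0.5),
                                    c(0, 0, 0, 0, 1))$value, 0.2)
  expect_equal(average_ppv_estimate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$value, 1)
  expect_false(average_ppv_estimate(c(0.2, 0.4), c(0, 0))$defined)
})

test_that("rank metrics are invariant to strictly monotone score transforms", {
  set.seed(3)
  s <- runif(100); y <- rbinom(100, 1, 0.4)
  for (f in list(function(x) x^3, function(x) plogis(5 * x),
                 function(x) exp(x))) {
    expect_equal(auc_estimate(f(s), y)$value, auc_estimate(s, y)$value)
    expect_equal(average_ppv_estimate(f(s), y)$value,
                 average_ppv_estimate(s, y)$value)
  }
})

test_that("Brier score and its Hoeffding interval match closed forms", {
  expect_equal(brier_estimate(c(1, 0, 1), c(1, 0, 1))$value, 0)
  expect_equal(brier_estimate(rep(0.5, 10), rbinom(10, 1, 0.5))$value, 0.25)
  b <- brier_estimate(runif(200), rbinom(200, 1, 0.5), alpha = 0.05)
  expected_hw <- sqrt(log(2 / 0.05) / (2 * 200))
  expect_equal(expected_hw, 0.09603, tolerance = 1e-4)
  expect_equal(b$ci_high - b$value, expected_hw, tolerance = 1e-12)
  expect_identical(b$ci_method, "hoeffding")
})

test_that("standardized net benefit matches the decision-curve formula", {
  # perfect classifier: sNB = 1 at any prevalence
  cc <- confusion(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
                  c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(snb_estimate(cc)$value, 1)
  # flags nobody: sNB = 0
  cc0 <- confusion(rep(0, 10), c(1, 1, rep(0, 8)))
  expect_equal(snb_estimate(cc0)$value, 0)
  # sens 0.8, spec 0.9, prevalence 0.2, t = 0.5: (0.16 - 0.08) / 0.2 = 0.4
  cc2 <- structure(list(tp = 16L, fn = 4L, tn = 72L, fp = 8L),
                   class = "confusion_counts")
  expect_equal(snb_estimate(cc2, 0.5)$value, 0.4, tolerance = 1e-12)
  # no positives: undefined
  expect_false(snb_estimate(confusion(c(1, 0), c(0, 0)))$defined)
})

test_that("intervals contain their estimate and respect range clipping", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    s <- runif(n); y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    for (est in list(auc_estimate(s, y), average_ppv_estimate(s, y),
                     brier_estimate(s, y),
                     rate_metrics(confusion(as.integer(s > 0.5), y))$sensitivity)) {
      if (!est$defined) next
      expect_lte(est$ci_low, est$value)
      expect_gte(est$ci_high, est$value)
      expect_gte(est$ci_low, 0)
      expect_lte(est$ci_high, 1)
    }
    snb <- snb_estimate(confusion(as.integer(s > 0.5), y))
    expect_lte(snb$ci_low, snb$value)
    expect_lte(snb$value, snb$ci_high)
    expect_lte(snb$ci_high, 1)
  }
})

test_that("undefined metrics are reported as undefined, never as zero", {
  est <- rate_metrics(confusion(c(0, 0), c(0, 0)))$ppv
  expect_false(est$defined)
  expect_true(is.na(est$value))
  expect_match(format(est), "—")
})
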