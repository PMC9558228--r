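test_that("categorical policy picks the right test and agrees with stats::", {
  # balanced table: Pearson, statistic exactly 0
  res <- compare_categorical(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$method, "pearson")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  expect_error(compare_categorical(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)),
               "margin")
  expect_error(compare_categorical(matrix(c(1.5, 2, 3, 4), 2)), "integer")

  # oracle agreement across random tables in all three policy regimes
  set.seed(99)
  for (i in 1:40) {
    tb <- matrix(rpois(4, sample(c(2, 8, 25), 1)) + 1L, 2)
    res <- compare_categorical(tb)
    if (res$method == "pearson") {
      o <- suppressWarnings(chisq.test(tb, correct = FALSE))
      expect_equal(res$statistic, unname(o$statistic))
      expect_equal(res$p, o$p.value)
    } else if (res$method == "yates") {
      o <- suppressWarnings(chisq.test(tb, correct = TRUE))
      expect_equal(res$statistic, unname(o$statistic))
    } else {
      expect_equal(res$p, fisher.test(tb)$p.value, tolerance = 1e-10)
    }
  }
})

test_that("mean comparisons match oracles for every variant", {
  # identical groups: t exactly 0
  expect_equal(compare_means(c(1, 2, 3), c(1, 2, 3))$statistic, 0)

  # summary-statistic pooled t reproduces the published MoCA comparison
  res <- compare_means(list(n = 24, mean = 20.3, sd = 3.9),
                       list(n = 33, mean = 18.0, sd = 4.3))
  expect_equal(res$statistic, 2.087, tolerance = 0.05 / 2.087)
  expect_equal(res$df, 55)

  # raw-data t variants against stats::t.test
  set.seed(12)
  a <- rnorm(20, 1); b <- rnorm(25)
  expect_equal(compare_means(a, b, "pooled")$statistic,
               unname(t.test(a, b, var.equal = TRUE)$statistic))
  expect_equal(compare_means(a, b, "welch")$p, t.test(a, b)$p.value)

  # Mann-Whitney: U frozen from exhaustive pair counting, p vs wilcox.test
  x <- c(3.1, 4.5, 2.2, 5.0, 3.3); y <- c(2.9, 3.3, 1.8, 2.0, 4.1)
  mw <- compare_means(x, y, "mann_whitney")
  expect_equal(mw$U, 18.5)  # sum over pairs of (x > y) + 0.5 (x == y)
  expect_equal(mw$p,
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  expect_error(compare_means(list(n = 5, mean = 1, sd = 1), y, "mann_whitney"),
               "raw")
})

test_that("binary-predictor logistic fits equal the cross-product oracle", {
  set.seed(7)
  for (i in 1:100) {
    tb <- matrix(rpois(4, 12) + 1L, 2)  # no zero cells
    a <- tb[1, 1]; b <- tb[1, 2]; c_ <- tb[2, 1]; d <- tb[2, 2]
    outcome <- rep(c(1, 1, 0, 0), c(a, b, c_, d))
    exposure <- rep(c(1, 0, 1, 0), c(a, b, c_, d))
    fit <- univariate_logistic(outcome, exposure)
    or_oracle <- (a * d) / (b * c_)
    se_oracle <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    expect_equal(fit$terms$odds_ratio, or_oracle, tolerance = 1e-6)
    expect_equal(fit$terms$ci_low,
                 exp(log(or_oracle) - qnorm(0.975) * se_oracle),
                 tolerance = 1e-6)
    expect_equal(fit$terms$ci_high,
                 exp(log(or_oracle) + qnorm(0.975) * se_oracle),
                 tolerance = 1e-6)
  }
})

test_that("logistic edge behaviour: independence, per-SD scaling, separation", {
  outcome <- rep(c(0, 1), each = 20)
  balanced <- rep(c(0, 1), 20)  # identical distribution in both classes
  expect_equal(univariate_logistic(outcome, balanced)$terms$odds_ratio, 1,
               tolerance = 1e-8)

  set.seed(31)
  x <- rnorm(80); y <- rbinom(80, 1, plogis(x))
  f1 <- univariate_logistic(y, x)
  f2 <- univariate_logistic(y, x, per_sd = TRUE)
  expect_equal(f2$terms$coefficient, f1$terms$coefficient * sd(x))
  expect_equal(f2$scaling, "per SD of predictor")

  sep <- c(rep(0, 20), rep(1, 20))
  expect_warning(fs <- univariate_logistic(sep, sep), "separation")
  expect_true(fs$separation)
  expect_error(univariate_logistic(rep(1, 10), rnorm(10)), "single class")
})

test_that("backward-LR selection removes noise and keeps signal", {
  set.seed(13)
  x <- rnorm(300); y <- rbinom(300, 1, plogis(1.2 * x))
  # single strong candidate: retained, empty trace
  fit <- multivariate_logistic_backward_lr(y, data.frame(x = x))
  expect_equal(fit$retained, "x")
  expect_equal(nrow(fit$selection_trace), 0)
  expect_error(multivariate_logistic_backward_lr(y, data.frame()), "empty")

  # signal + pure noise: noise removed first in >= 95% of replicates
  first_removed <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(500)
    z <- rnorm(500)
    y <- rbinom(500, 1, plogis(0.9 * x))
    fit <- multivariate_logistic_backward_lr(y, data.frame(x = x, z = z))
    if (nrow(fit$selection_trace) == 0) NA_character_
    else fit$selection_trace$removed[1]
  }, character(1))
  expect_gte(mean(first_removed == "z", na.rm = TRUE), 0.95)
})

test_that("AUC equals the pair-counting and Mann-Whitney identities", {
  # enumerated example: 3 of 4 positive-negative pairs concordant
  res <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(res$auc, 0.75)

  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(rnorm(5), rep(1, 5)), "single class")

  set.seed(41)
  for (i in 1:20) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    pos <- sample(1:8, n1, replace = TRUE)  # ties guaranteed
    neg <- sample(1:8, n0, replace = TRUE)
    scores <- c(pos, neg); labels <- rep(c(1, 0), c(n1, n0))
    auc <- roc_auc(scores, labels)$auc
    u <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
    expect_equal(auc, u / (n1 * n0))
    # invariance under a strictly increasing transform
    expect_equal(roc_auc(exp(scores / 3), labels)$auc, auc)
  }
})

test_that("DeLong intervals cover the binormal truth at nominal rate", {
  true_auc <- pnorm(1 / sqrt(2))  # unit-variance normals, unit shift
  covered <- vapply(1:500, function(s) {
    set.seed(s)
    scores <- c(rnorm(60, 1), rnorm(60, 0))
    labels <- rep(c(1, 0), each = 60)
    ci <- roc_auc(scores, labels, ci_method = "delong")
    ci$ci_low <= true_auc && true_auc <= ci$ci_high
  }, logical(1))
  band <- qbinom(c(0.005, 0.995), 500, 0.95) / 500
  expect_gte(mean(covered), band[1])
  expect_lte(mean(covered), band[2])
})

test_that("combined-model ROC behaves under nesting and monotone links", {
  set.seed(55)
  x <- rnorm(100); y <- rbinom(100, 1, plogis(1.5 * x))
  single <- roc_auc(x, y)
  comb1 <- combined_model_auc(y, data.frame(x = x))
  # one variable: logistic link is monotone, AUC identical
  expect_equal(comb1$auc, single$auc)
  # hanley_mcneil variant returns a wider-or-narrower but valid interval
  hm <- roc_auc(x, y, ci_method = "hanley_mcneil")
  expect_true(hm$ci_low <= hm$auc && hm$auc <= hm$ci_high)
})

test_that("AUC power matches the published design and its monotonicities", {
  # published design: 33 vs 24, 0.5 vs 0.715, two-sided 0.05 -> ~83%
  p <- auc_power(33, 24, 0.5, 0.715, 0.05)
  expect_lt(abs(p - 0.83), 0.02)

  # vanishing effect: power collapses toward the alpha side
  expect_lt(auc_power(33, 24, 0.5, 0.5005, 0.05), 0.10)
  # doubling both n strictly increases power
  expect_gt(auc_power(66, 48, 0.5, 0.715, 0.05), p)
  # larger effect strictly increases power
  expect_gt(auc_power(33, 24, 0.5, 0.80, 0.05), p)
  expect_error(auc_power(33, 24, 0.7, 0.6), "auc_null < auc_alt")
})
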