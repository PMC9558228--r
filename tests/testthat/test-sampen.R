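test_that("degenerate and periodic series give zero entropy", {
  # constant series with absolute tolerance: perfect regularity
  res <- sample_entropy(rep(5, 200), m = 2, r_absolute = 0.2)
  expect_equal(res$value, 0)
  expect_equal(res$a_count, res$b_count)

  # strictly alternating: every m-match extends to an (m+1)-match
  res2 <- sample_entropy(rep(c(0, 1), 100), m = 2, r_absolute = 0.3)
  expect_equal(res2$value, 0)

  # constant series with coefficient-based r: degenerate tolerance
  expect_error(sample_entropy(rep(5, 200), m = 2, r_coefficient = 0.1),
               "constant")
  expect_error(resolve_tolerance(rep(1, 50), 0.2), "constant")
})

test_that("resolve_tolerance is coefficient times the sample SD", {
  x <- rnorm(50)
  x <- (x - mean(x)) / sd(x)  # exact unit SD
  expect_equal(resolve_tolerance(x, 0.1), 0.1)
  y <- rep(c(0, 2), 25)       # closed-form SD
  expect_equal(resolve_tolerance(y, 0.25), 0.25 * sd(y))
  expect_error(resolve_tolerance(x, -1), "positive")
})

test_that("the 12-point fixture matches the frozen brute-force oracle", {
  u <- c(1, 3, 2, 4, 2, 1, 3, 5, 2, 3, 1, 4)
  res <- suppressWarnings(sample_entropy(u, m = 2, r_absolute = 1.0))
  # frozen from the explicit double-loop enumeration (d <= r)
  expect_equal(res$a_count, 7)
  expect_equal(res$b_count, 14)
  expect_equal(res$value, log(2))

  # strict d < r on the same integer-valued fixture: no (m+1)-matches left
  res_lt <- suppressWarnings(
    sample_entropy(u, m = 2, r_absolute = 1.0, strict_lt = TRUE))
  expect_equal(res_lt$b_count, 1)
  expect_equal(res_lt$a_count, 0)
  expect_false(res_lt$defined)
  expect_true(is.na(res_lt$value))
})

test_that("production counts equal the naive oracle exactly on random series", {
  # loop and vectorized oracles agree with each other and the C++ core
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(60:120, 1)
    x <- rnorm(n)
    r <- 0.25 * sd(x)
    o1 <- sampen_oracle_loop(x, 2, r)
    o2 <- sampen_oracle_vec(x, 2, r)
    expect_identical(o1[c("a_count", "b_count")], o2[c("a_count", "b_count")])
    res <- suppressWarnings(sample_entropy(x, m = 2, r_absolute = r))
    expect_identical(res$a_count, as.numeric(o1$a_count))
    expect_identical(res$b_count, as.numeric(o1$b_count))
    expect_equal(res$value, o1$value)
  }
  # larger N and other m against the vectorized oracle
  for (seed in 7:16) {
    set.seed(seed)
    n <- sample(100:500, 1)
    m <- sample(1:3, 1)
    x <- cumsum(rnorm(n))
    r <- 0.2 * sd(x)
    o <- sampen_oracle_vec(x, m, r)
    res <- suppressWarnings(sample_entropy(x, m = m, r_absolute = r))
    expect_identical(res$a_count, as.numeric(o$a_count))
    expect_identical(res$b_count, as.numeric(o$b_count))
  }
})

test_that("white-noise entropy sits in the Monte-Carlo oracle band", {
  # oracle band across 20 seeds: mean 2.1872, sd 0.0135 (N = 3000,
  # m = 2, r = 0.2 SD); the mean of 10 fresh seeds must land within
  # ~3.5 combined standard errors of that mean.
  vals <- vapply(1:10, function(s) {
    set.seed(9000 + s)
    sample_entropy(rnorm(3000), m = 2, r_coefficient = 0.2)$value
  }, numeric(1))
  expect_gt(mean(vals), 2.1872 - 0.016)
  expect_lt(mean(vals), 2.1872 + 0.016)
})

test_that("entropy respects reversal symmetry and affine equivariance", {
  for (seed in 1:8) {
    set.seed(seed)
    x <- cumsum(rnorm(150))
    r <- 0.2 * sd(x)
    a <- suppressWarnings(sample_entropy(x, m = 2, r_absolute = r))
    b <- suppressWarnings(sample_entropy(rev(x), m = 2, r_absolute = r))
    # (m+1)-templates over 1..N-m are ALL (m+1)-windows, so a_count is
    # exactly reversal-invariant; b_count drops one boundary m-window
    # (the last, which reversal maps to the first), so it can shift by at
    # most the pairs that window participates in.
    expect_equal(a$a_count, b$a_count)
    expect_lte(abs(a$b_count - b$b_count), length(x) - 2 - 1)

    alpha <- runif(1, 0.5, 3); beta <- runif(1, -10, 10)
    cc <- suppressWarnings(
      sample_entropy(alpha * x + beta, m = 2, r_absolute = alpha * r))
    expect_equal(a$a_count, cc$a_count)
    expect_equal(a$b_count, cc$b_count)
    expect_equal(a$value, cc$value)

    expect_lte(a$a_count, a$b_count)
    if (a$defined) expect_gte(a$value, 0)
  }
})

test_that("entropy_profile labels the study grid and propagates errors", {
  set.seed(3)
  x <- rnorm(300)
  prof <- entropy_profile(x)
  expect_equal(prof$label, c("SampEn01", "SampEn015", "SampEn02", "SampEn025"))
  expect_equal(prof$r_absolute, c(0.10, 0.15, 0.20, 0.25) * sd(x))
  # for i.i.d. noise the profile is non-increasing in r
  expect_true(all(diff(prof$value) <= 0))
  # values agree with single calls
  expect_equal(prof$value[1],
               sample_entropy(x, m = 2, r_coefficient = 0.1)$value)

  expect_equal(nrow(entropy_profile(x, coefficients = numeric(0))), 0)
  expect_warning(sample_entropy(rnorm(50), m = 2, r_absolute = 1), "100 points")
})

test_that("a_count = 0 yields a flagged undefined result, not an error", {
  # widely spaced values with tiny tolerance: no extended matches
  set.seed(11)
  x <- seq(0, 100, length.out = 120) + rnorm(120, 0, 0.01)
  res <- suppressWarnings(sample_entropy(x, m = 2, r_absolute = 1e-6))
  expect_false(res$defined)
  expect_true(is.na(res$value))
})
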