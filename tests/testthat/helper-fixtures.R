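# Shared fixtures and independent oracles, built in code at test time.

# A small but valid series: 60-sample baseline plus an intraop segment.
make_test_series <- function(intraop, baseline_level = 73.4,
                             subject_id = "T001", side = "left") {
  rso2_series(c(rep(baseline_level, 60), intraop),
              baseline_window = 1:60,
              intraop_window = 61:(60 + length(intraop)),
              subject_id = subject_id, side = side)
}

# Independent brute-force SampEn oracle: explicit double loop over all
# template pairs, Chebyshev distance, d <= r matching. Deliberately naive
# and kept free of any package internals.
sampen_oracle_loop <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  a <- 0; b <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        b <- b + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) a <- a + 1
      }
    }
  }
  list(a_count = as.numeric(a), b_count = as.numeric(b),
       value = if (a > 0 && b > 0) -log(a / b) else NA_real_)
}

# Vectorized variant of the same enumeration (fast enough for N = 500),
# cross-checked against the loop oracle in the test suite.
sampen_oracle_vec <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  dm <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    xs <- x[(1:nt) + k]
    dm <- pmax(dm, abs(outer(xs, xs, "-")))
  }
  xe <- x[(1:nt) + m]
  dm1 <- pmax(dm, abs(outer(xe, xe, "-")))
  up <- upper.tri(dm)
  a <- as.numeric(sum(dm1[up] <= r))
  b <- as.numeric(sum(dm[up] <= r))
  list(a_count = a, b_count = b,
       value = if (a > 0 && b > 0) -log(a / b) else NA_real_)
}

# Irregularity weights calibrated once per test run and shared across
# test files (calibration is the expensive step).
calibrated_weights <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- c(
        non_poci = as.numeric(calibrate_irregularity(
          0.262, seed = substream_seed(424242L, 900001))),
        poci = as.numeric(calibrate_irregularity(
          0.372, seed = substream_seed(424242L, 900002))))
    }
    cache
  }
})
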