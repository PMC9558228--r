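#' Generate a surrogate series under the linear-stochastic null
#'
#' Phase-randomized surrogates preserve the discrete Fourier amplitudes of
#' the input exactly and randomize the phases (with conjugate symmetry, so
#' the result is real). Amplitude-adjusted (AAFT) surrogates additionally
#' rank-remap the phase-randomized series back onto the original value
#' distribution, so the surrogate has exactly the original amplitude
#' distribution and approximately its power spectrum — the null of a
#' Gaussian linear process observed through a static monotone measurement
#' function.
#'
#' @param values numeric series, at least 100 points.
#' @param method `"amplitude_adjusted"` (AAFT, default) or
#'   `"phase_randomized"`.
#' @param seed optional integer; fixes the surrogate exactly.
#' @return numeric surrogate series of the same length.
#' @export
make_surrogate <- function(values,
                           method = c("amplitude_adjusted", "phase_randomized"),
                           seed = NULL) {
  method <- match.arg(method)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 100L) stop("need at least 100 points", call. = FALSE)
  if (sd(values) == 0) stop("constant series has no surrogates", call. = FALSE)
  with_seed(seed, {
    if (method == "phase_randomized") {
      phase_randomize(values)
    } else {
      # AAFT: gaussianize by rank, phase-randomize, map ranks back
      rk <- rank(values, ties.method = "first")
      gauss <- sort(rnorm(n))[rk]
      shuffled <- phase_randomize(gauss)
      sort(values)[rank(shuffled, ties.method = "first")]
    }
  })
}

phase_randomize <- function(x) {
  n <- length(x)
  X <- fft(x)
  half <- floor((n - 1) / 2)
  if (half >= 1) {
    ph <- runif(half, 0, 2 * pi)
    idx <- 2:(half + 1)
    X[idx] <- Mod(X[idx]) * exp(1i * ph)
    X[n + 2 - idx] <- Conj(X[idx])
  }
  if (n %% 2 == 0) {
    # Nyquist bin must stay real; a random sign keeps it unbiased
    X[n / 2 + 1] <- Mod(X[n / 2 + 1]) * sample(c(-1, 1), 1)
  }
  Re(fft(X, inverse = TRUE)) / n
}

#' Third-order time-reversal asymmetry statistic
#'
#' `mean(diff^3) / mean(diff^2)^(3/2)` of the lagged differences — zero in
#' expectation for any time-reversible process (every Gaussian linear
#' process is reversible), generically nonzero for nonlinear dynamics.
#'
#' @param values numeric series.
#' @param lag positive integer lag of the differences.
#' @return the (dimensionless) asymmetry statistic.
#' @export
time_asymmetry_statistic <- function(values, lag = 1L) {
  values <- as.numeric(values)
  lag <- as.integer(lag)
  if (lag < 1L || length(values) <= lag)
    stop("need N > lag >= 1", call. = FALSE)
  d <- values[(lag + 1L):length(values)] - values[1:(length(values) - lag)]
  m2 <- mean(d^2)
  if (m2 == 0) stop("constant series: asymmetry undefined", call. = FALSE)
  mean(d^3) / m2^1.5
}

#' Surrogate-data test for nonlinear dynamics
#'
#' Rank test of an observed discriminating statistic against its
#' distribution over `n_surrogates` surrogates drawn under the linear
#' stochastic null. With the default settings (99 AAFT surrogates, lag-1
#' time-asymmetry statistic, two-sided alpha 0.05) the attained p-value is
#' `2 * min(rank, K + 2 - rank) / (K + 1)` where `rank` is the midrank of
#' the observed statistic among all `K + 1` values; the null is rejected
#' when this p is at most `alpha`. The series is linearly detrended first
#' by default, since surrogate methods assume stationarity.
#'
#' @param values numeric series (or an [rso2_series()]; its intraoperative
#'   segment is used).
#' @param n_surrogates number of surrogates K; must satisfy
#'   `2 / (K + 1) <= alpha` so the test can reject at all.
#' @param method surrogate construction, see [make_surrogate()].
#' @param statistic discriminating statistic, a function of a numeric
#'   vector; defaults to [time_asymmetry_statistic()] at `lag`.
#' @param alpha nominal two-sided level.
#' @param lag lag for the default statistic.
#' @param detrend remove a least-squares linear trend before testing.
#' @param seed optional integer for exact reproducibility.
#' @return an object of class `surrogate_test` with `observed_statistic`,
#'   `surrogate_statistics`, `n_surrogates`, `significance_level`, `p`,
#'   and `reject_null` (TRUE = evidence of nonlinear dynamics).
#' @export
surrogate_test <- function(values, n_surrogates = 99L,
                           method = c("amplitude_adjusted", "phase_randomized"),
                           statistic = NULL, alpha = 0.05, lag = 1L,
                           detrend = TRUE, seed = NULL) {
  method <- match.arg(method)
  if (inherits(values, "rso2_series")) values <- intraop_values(values)
  values <- as.numeric(values)
  K <- as.integer(n_surrogates)
  if (K < 1L) stop("need at least one surrogate", call. = FALSE)
  if (2 / (K + 1) > alpha)
    stop(sprintf(
      "K = %d surrogates cannot attain two-sided level %.3g (min p = %.3g); increase n_surrogates",
      K, alpha, 2 / (K + 1)), call. = FALSE)
  if (is.null(statistic)) statistic <- function(x) time_asymmetry_statistic(x, lag)
  if (isTRUE(detrend)) {
    tt <- seq_along(values)
    values <- values - fitted_line(tt, values)
  }
  obs <- statistic(values)
  surr <- with_seed(seed, {
    vapply(seq_len(K), function(i) statistic(make_surrogate(values, method)),
           numeric(1))
  })
  rk <- 1 + sum(surr < obs) + 0.5 * sum(surr == obs)
  p <- 2 * min(rk, K + 2 - rk) / (K + 1)
  p <- min(p, 1)
  structure(
    list(observed_statistic = obs, surrogate_statistics = surr,
         n_surrogates = K, significance_level = alpha, method = method,
         p = p, reject_null = p <= alpha),
    class = "surrogate_test")
}

fitted_line <- function(x, y) {
  xc <- x - mean(x)
  b <- sum(xc * y) / sum(xc^2)
  mean(y) + b * xc
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat(sprintf(
    "Surrogate-data rank test (%s, K=%d): statistic %.4g, p = %.3f -> %s\n",
    x$method, x$n_surrogates, x$observed_statistic, x$p,
    if (x$reject_null) "nonlinear dynamics" else "consistent with linear null"))
  invisible(x)
}
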