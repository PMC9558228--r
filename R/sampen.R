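#' Tolerance from a coefficient of the series standard deviation
#'
#' The similarity tolerance r is conventionally expressed as a multiple of
#' the standard deviation of the analyzed segment; the study grid is 0.10,
#' 0.15, 0.20 and 0.25 times the SD.
#'
#' @param values numeric series (the segment actually analyzed).
#' @param coefficient positive multiple of the sample SD (denominator
#'   `N - 1`).
#' @return absolute tolerance in signal units.
#' @export
resolve_tolerance <- function(values, coefficient) {
  if (!is.numeric(coefficient) || length(coefficient) != 1L || coefficient <= 0)
    stop("`coefficient` must be a single positive number", call. = FALSE)
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    stop("series is constant: tolerance r = coefficient * SD degenerates to 0; ",
         "supply an absolute tolerance instead", call. = FALSE)
  coefficient * s
}

#' Sample entropy SampEn(m, r, N)
#'
#' Estimates the negative logarithm of the conditional probability that two
#' length-m templates of the series that match within tolerance r (in the
#' Chebyshev metric, the maximum coordinate-wise absolute difference) still
#' match when extended by one point. Matching excludes self-comparison, and
#' both the m- and (m+1)-length counts run over template indices
#' `1..N-m`, so their ratio is a conditional probability. Larger values
#' indicate a more irregular, less predictable signal; a perfectly regular
#' series has SampEn 0.
#'
#' The match criterion is `d <= r` by default — the convention of the
#' reference toolkits — with `strict_lt = TRUE` switching to `d < r`.
#'
#' @param values numeric series (typically the intraoperative rSO2
#'   segment, or pass an [rso2_series()]).
#' @param m embedding (template) length; the conventional choice is 2.
#' @param r_coefficient tolerance as a multiple of the series SD
#'   (mutually exclusive with `r_absolute`).
#' @param r_absolute tolerance in signal units.
#' @param strict_lt use strict `d < r` matching instead of `d <= r`.
#' @return an object of class `sampen_result` with fields `a_count`
#'   ((m+1)-template match count), `b_count` (m-template match count), `n`,
#'   `m`, `r_absolute`, `r_coefficient`, `value` (`-log(a/b)`, `NA` when
#'   undefined) and `defined`.
#' @export
sample_entropy <- function(values, m = 2L, r_coefficient = NULL,
                           r_absolute = NULL, strict_lt = FALSE) {
  if (inherits(values, "rso2_series")) values <- intraop_values(values)
  values <- as.numeric(values)
  if (anyNA(values)) stop("series contains NA", call. = FALSE)
  m <- as.integer(m)
  if (m < 1L) stop("m must be a positive integer", call. = FALSE)
  n <- length(values)
  if (n < m + 2L) stop("series too short for embedding length m", call. = FALSE)
  if (n < 100L)
    warning("sample entropy is unreliable below 100 points (N = ", n, ")",
            call. = FALSE)
  if (is.null(r_absolute) == is.null(r_coefficient))
    stop("supply exactly one of `r_coefficient`, `r_absolute`", call. = FALSE)
  if (is.null(r_absolute)) r_absolute <- resolve_tolerance(values, r_coefficient)
  if (r_absolute <= 0) stop("tolerance r must be positive", call. = FALSE)

  cnt <- sampen_counts_cpp(values, m, r_absolute, isTRUE(strict_lt))
  a <- cnt$a_count
  b <- cnt$b_count
  defined <- a > 0 && b > 0
  structure(
    list(a_count = a, b_count = b, n = n, m = m,
         r_absolute = r_absolute,
         r_coefficient = if (is.null(r_coefficient)) NA_real_ else r_coefficient,
         value = if (defined) -log(a / b) else NA_real_,
         defined = defined),
    class = "sampen_result")
}

#' @export
print.sampen_result <- function(x, ...) {
  cat(sprintf("SampEn(m=%d, r=%.4g, N=%d) = %s  [A=%g, B=%g]\n",
              x$m, x$r_absolute, x$n,
              if (x$defined) sprintf("%.4f", x$value) else "undefined",
              x$a_count, x$b_count))
  invisible(x)
}

# "SampEn01", "SampEn015", ... from a tolerance coefficient
sampen_label <- function(coefficient) {
  paste0("SampEn", sub("^0\\.", "0", sprintf("%g", coefficient)))
}

#' Sample entropy over a grid of tolerance coefficients
#'
#' Convenience wrapper computing SampEn at fixed m for several tolerance
#' coefficients, labelled `SampEn01`, `SampEn015`, `SampEn02`, `SampEn025`
#' for the standard grid.
#'
#' @inheritParams sample_entropy
#' @param coefficients tolerance coefficients (multiples of the series SD).
#' @return a data frame with one row per coefficient: `label`, `m`,
#'   `r_coefficient`, `r_absolute`, `a_count`, `b_count`, `value`,
#'   `defined`.
#' @export
entropy_profile <- function(values, m = 2L,
                            coefficients = c(0.10, 0.15, 0.20, 0.25),
                            strict_lt = FALSE) {
  if (inherits(values, "rso2_series")) values <- intraop_values(values)
  if (length(coefficients) == 0L)
    return(data.frame(label = character(), m = integer(),
                      r_coefficient = numeric(), r_absolute = numeric(),
                      a_count = numeric(), b_count = numeric(),
                      value = numeric(), defined = logical()))
  rows <- lapply(coefficients, function(cf) {
    res <- sample_entropy(values, m = m, r_coefficient = cf,
                          strict_lt = strict_lt)
    data.frame(label = sampen_label(cf), m = res$m, r_coefficient = cf,
               r_absolute = res$r_absolute, a_count = res$a_count,
               b_count = res$b_count, value = res$value,
               defined = res$defined)
  })
  do.call(rbind, rows)
}
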