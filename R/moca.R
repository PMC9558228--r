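#' Education-adjusted MoCA score
#'
#' The Montreal Cognitive Assessment total (0-30) receives one extra point
#' for individuals with 12 years or less of formal education, capped at the
#' scale ceiling of 30.
#'
#' @param raw raw MoCA total, integer in \[0, 30\]. Vectorized.
#' @param education_years nonnegative years of formal education.
#' @return adjusted integer score in \[0, 30\].
#' @export
adjust_moca <- function(raw, education_years) {
  if (any(is.na(raw)) || any(raw < 0 | raw > 30))
    stop("raw MoCA scores must lie in [0, 30]", call. = FALSE)
  if (any(is.na(education_years)) || any(education_years < 0))
    stop("education_years must be nonnegative", call. = FALSE)
  pmin(raw + as.integer(education_years <= 12), 30L)
}

#' Classify postoperative cognitive improvement (POCI)
#'
#' POCI is a gain of at least three points in the education-adjusted MoCA
#' score between the preoperative assessment and postoperative day 3-4.
#' The adjustment is applied to both assessments (it cancels in the
#' difference except at the 30-point ceiling).
#'
#' @param moca_pre,moca_post raw pre- and postoperative MoCA totals.
#'   Vectorized.
#' @param education_years years of education (same subject for both
#'   assessments).
#' @return a data frame with `delta` (adjusted post minus adjusted pre) and
#'   logical `poci`.
#' @export
classify_poci <- function(moca_pre, moca_post, education_years) {
  n <- length(moca_pre)
  if (length(moca_post) != n || !(length(education_years) %in% c(1L, n)))
    stop("pre/post scores and education must align", call. = FALSE)
  pre_adj <- adjust_moca(moca_pre, education_years)
  post_adj <- adjust_moca(moca_post, education_years)
  delta <- as.integer(post_adj - pre_adj)
  data.frame(delta = delta, poci = delta >= 3L)
}
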