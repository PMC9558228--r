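#' Construct an rSO2 series object
#'
#' An `rso2_series` holds one subject's uniformly sampled regional cerebral
#' oxygen saturation (rSO2) trace together with the index windows that mark
#' the 2-minute pre-induction baseline and the operative period. All values
#' are percentages in \[0, 100\] on a fixed 2-second grid; the baseline
#' window must span exactly 60 samples (2 min at 2 s) and precede the
#' operative window, whose length must be at least 100 points — the floor
#' below which sample entropy estimates are unreliable.
#'
#' @param values numeric vector of saturation percentages for the whole
#'   monitoring period (baseline first, then intraoperative).
#' @param baseline_window integer vector of indices into `values` marking
#'   the pre-induction baseline (must have length 60).
#' @param intraop_window integer vector of indices marking the operative
#'   period (length >= 100, strictly after the baseline window).
#' @param subject_id opaque subject identifier.
#' @param side which forehead sensor the trace comes from; the affected
#'   side is the one analyzed.
#' @param sampling_interval sampling interval in seconds (fixed at 2).
#' @return an object of class `rso2_series`.
#' @export
rso2_series <- function(values, baseline_window, intraop_window,
                        subject_id = "subject", side = c("left", "right"),
                        sampling_interval = 2) {
  side <- match.arg(side)
  values <- as.numeric(values)
  if (anyNA(values))
    stop("rSO2 values must not contain NA after gap handling", call. = FALSE)
  if (any(values < 0 | values > 100))
    stop("rSO2 values must lie in [0, 100]", call. = FALSE)
  baseline_window <- as.integer(baseline_window)
  intraop_window <- as.integer(intraop_window)
  if (length(baseline_window) != 60L)
    stop("baseline window must span exactly 60 samples (2 min at 2 s), got ",
         length(baseline_window), call. = FALSE)
  if (length(intraop_window) < 100L)
    stop("intraoperative window has ", length(intraop_window),
         " points; at least 100 are required", call. = FALSE)
  if (max(baseline_window) >= min(intraop_window))
    stop("baseline window must precede the intraoperative window",
         call. = FALSE)
  rng <- c(baseline_window, intraop_window)
  if (any(rng < 1L) || any(rng > length(values)))
    stop("window indices out of range", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id),
         sampling_interval = sampling_interval,
         values = values,
         baseline_window = baseline_window,
         intraop_window = intraop_window,
         side = side),
    class = "rso2_series")
}

#' @export
print.rso2_series <- function(x, ...) {
  cat(sprintf(
    "<rso2_series> subject %s (%s side): %d samples at %gs,\n  baseline %d samples, intraop %d samples (%.1f min)\n",
    x$subject_id, x$side, length(x$values), x$sampling_interval,
    length(x$baseline_window), length(x$intraop_window),
    length(x$intraop_window) * x$sampling_interval / 60))
  invisible(x)
}

#' Extract the intraoperative segment of a series
#' @param series an [rso2_series()].
#' @return numeric vector of intraoperative saturation values.
#' @export
intraop_values <- function(series) {
  stopifnot(inherits(series, "rso2_series"))
  series$values[series$intraop_window]
}

# Fill short dropouts (<= max_gap_s seconds of consecutive missing samples)
# by previous-value carry-forward; longer dropouts invalidate the series.
fill_gaps <- function(values, sampling_interval, max_gap_s = 10) {
  miss <- is.na(values)
  if (!any(miss)) return(values)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    gap_s <- r$lengths[k] * sampling_interval
    if (gap_s > max_gap_s)
      stop(sprintf("signal dropout of %gs exceeds the %gs carry-forward limit",
                   gap_s, max_gap_s), call. = FALSE)
    if (starts[k] == 1L)
      stop("series starts with missing samples; cannot carry forward",
           call. = FALSE)
    values[starts[k]:ends[k]] <- values[starts[k] - 1L]
    warning(sprintf("filled a %gs dropout by carry-forward", gap_s),
            call. = FALSE)
  }
  values
}

#' Read an rSO2 series from a CSV file with its metadata sidecar
#'
#' The CSV has header `time_s,rso2_pct`, times in seconds from monitoring
#' start on a uniform 2-second grid. A sidecar JSON file (same stem,
#' extension `.meta.json`) carries `subject_id`, `side`, and the half-open
#' window bounds `baseline_start_s`/`baseline_end_s` and
#' `intraop_start_s`/`intraop_end_s` in seconds. Gaps of at most 10 s
#' (missing rows or missing values) are filled by previous-value
#' carry-forward with a warning; longer gaps are an error.
#'
#' @param path path to the series CSV.
#' @return an [rso2_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such series file: ", path, call. = FALSE)
  meta_path <- paste0(sub("\\.csv$", "", path), ".meta.json")
  if (!file.exists(meta_path))
    stop("missing metadata sidecar: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("subject_id", "side", "baseline_start_s", "baseline_end_s",
            "intraop_start_s", "intraop_end_s")
  if (!all(need %in% names(meta)))
    stop("metadata sidecar lacks keys: ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)

  dat <- read.csv(path, colClasses = c("numeric", "numeric"))
  if (!identical(names(dat), c("time_s", "rso2_pct")))
    stop("series CSV must have header `time_s,rso2_pct`", call. = FALSE)
  interval <- 2
  tt <- dat$time_s
  if (anyNA(tt) || is.unsorted(tt, strictly = TRUE))
    stop("time column must be strictly increasing", call. = FALSE)
  off <- tt %% interval
  if (any(abs(off - off[1]) > 1e-6))
    stop("time stamps do not lie on a uniform 2-second grid", call. = FALSE)

  # expand onto the full grid, then fill short dropouts
  grid <- seq(tt[1], tt[length(tt)], by = interval)
  vals <- rep(NA_real_, length(grid))
  vals[match(tt, grid)] <- dat$rso2_pct
  vals <- fill_gaps(vals, interval)
  if (any(vals < 0 | vals > 100))
    stop("saturation values outside [0, 100]", call. = FALSE)

  idx_of <- function(from_s, to_s) which(grid >= from_s & grid < to_s)
  rso2_series(vals,
              baseline_window = idx_of(meta$baseline_start_s, meta$baseline_end_s),
              intraop_window = idx_of(meta$intraop_start_s, meta$intraop_end_s),
              subject_id = meta$subject_id, side = meta$side,
              sampling_interval = interval)
}

#' Write an rSO2 series to CSV plus metadata sidecar
#'
#' Emits the same dialect [read_series()] consumes, with times 0-based and
#' values printed at full double precision so a round trip is bit-exact.
#'
#' @param series an [rso2_series()].
#' @param path destination CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "rso2_series"))
  iv <- series$sampling_interval
  tt <- (seq_along(series$values) - 1L) * iv
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,rso2_pct", con)
  writeLines(sprintf("%g,%.17g", tt, series$values), con)
  meta <- list(
    subject_id = series$subject_id,
    side = series$side,
    baseline_start_s = tt[series$baseline_window[1]],
    baseline_end_s = tt[series$baseline_window[60]] + iv,
    intraop_start_s = tt[series$intraop_window[1]],
    intraop_end_s = tt[series$intraop_window[length(series$intraop_window)]] + iv)
  jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pre-induction baseline saturation
#'
#' The baseline is the arithmetic mean of the 60 samples in the 2-minute
#' window recorded before induction of anesthesia.
#'
#' @param series an [rso2_series()].
#' @return baseline saturation in percent.
#' @export
compute_baseline <- function(series) {
  stopifnot(inherits(series, "rso2_series"))
  w <- series$baseline_window
  if (length(w) != 60L)
    stop("baseline window must contain exactly 60 samples", call. = FALSE)
  mean(series$values[w])
}

#' Summary statistics of an rSO2 trace
#'
#' @param series an [rso2_series()].
#' @return a one-row data frame: baseline, intraoperative mean, lowest and
#'   highest recorded value, number of intraoperative points and duration
#'   in minutes (`n_points / 30` at 2-second sampling).
#' @export
summarize_series <- function(series) {
  stopifnot(inherits(series, "rso2_series"))
  v <- intraop_values(series)
  data.frame(
    subject_id = series$subject_id,
    baseline = compute_baseline(series),
    mean = mean(v),
    lowest = min(v),
    highest = max(v),
    n_points = length(v),
    duration_min = length(v) * series$sampling_interval / 60)
}

#' Desaturation burden below a fraction of baseline
#'
#' Computes the time spent and the area accumulated strictly below
#' `fraction * baseline` during the operative period. Each 2-second sample
#' contributes its full dwell (rectangular integration, no interpolation of
#' threshold crossings); samples exactly at the threshold accrue no burden.
#' The thresholds used in practice are the baseline itself and 90% and 80%
#' of it.
#'
#' @param series an [rso2_series()].
#' @param baseline baseline saturation in percent; defaults to
#'   [compute_baseline()] of `series`.
#' @param fraction threshold as a fraction of baseline, in (0, 1]. Values
#'   other than 1.0, 0.9, 0.8 are allowed with a warning.
#' @return a one-row data frame: `threshold_fraction`, `threshold_value`
#'   (%), `duration_min` (minutes below threshold) and `area_min_pct`
#'   (min·% under the threshold).
#' @export
desaturation_metrics <- function(series, baseline = compute_baseline(series),
                                 fraction = 1.0) {
  stopifnot(inherits(series, "rso2_series"))
  if (baseline <= 0) stop("baseline must be positive", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  if (!any(abs(fraction - c(1.0, 0.9, 0.8)) < 1e-9))
    warning("nonstandard threshold fraction ", fraction, call. = FALSE)
  thr <- fraction * baseline
  v <- intraop_values(series)
  below <- v < thr
  dwell_min <- series$sampling_interval / 60
  data.frame(
    threshold_fraction = fraction,
    threshold_value = thr,
    duration_min = sum(below) * dwell_min,
    area_min_pct = sum((thr - v[below])) * dwell_min)
}
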