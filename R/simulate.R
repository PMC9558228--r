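#' Parameters of the synthetic rSO2 signal model
#'
#' The generator composes four ingredients on a 2-second grid: a slow
#' sinusoidal drift below the pre-induction baseline (surgical-course
#' trend), an asymmetric slow oscillation with fast desaturation and slow
#' recovery (vasomotion-like waves; physiological desaturation episodes
#' drop faster than they recover), and an AR(1) stochastic component with
#' negatively skewed (centred exponential) innovations. A single
#' irregularity weight `w` in \[0, 1\] mixes the oscillatory and stochastic
#' parts: `w = 0` gives a purely deterministic smooth trace (sample entropy
#' 0 when `noise_sd = 0`), `w = 1` a maximally irregular one, and expected
#' sample entropy increases monotonically in between. The skewed
#' innovations and asymmetric waveform make the process time-irreversible,
#' so surrogate-data tests classify generated traces as nonlinear — the
#' regime the real cohort sits in. A Gaussian linear mixture would be
#' time-reversible and could not reproduce that.
#'
#' @param baseline pre-induction baseline saturation, percent.
#' @param desat_offset mean intraoperative shift below baseline, percent
#'   (negative).
#' @param drift_amplitude,drift_period_min slow drift sine: amplitude (%)
#'   and period (minutes).
#' @param osc_amplitude,osc_period_min,fall_fraction asymmetric slow wave:
#'   amplitude (%), period (minutes) and the fraction of each cycle spent
#'   in the fast falling limb.
#' @param ar_coefficient AR(1) coefficient of the stochastic component.
#' @param noise_sd marginal SD (%) of the stochastic component.
#' @param irregularity_weight mixing weight `w` in \[0, 1\].
#' @return an object of class `signal_model_params`.
#' @export
signal_model_params <- function(baseline = 73.7, desat_offset = -3,
                                drift_amplitude = 2, drift_period_min = 45,
                                osc_amplitude = 2.5, osc_period_min = 3,
                                fall_fraction = 0.2,
                                ar_coefficient = 0.98, noise_sd = 2.5,
                                irregularity_weight = 0.2) {
  stopifnot(baseline > 0, baseline <= 100,
            drift_amplitude >= 0, drift_period_min > 0,
            osc_amplitude >= 0, osc_period_min > 0,
            fall_fraction > 0, fall_fraction < 1,
            ar_coefficient >= 0, ar_coefficient < 1, noise_sd >= 0,
            irregularity_weight >= 0, irregularity_weight <= 1)
  structure(as.list(environment()), class = "signal_model_params")
}

# Asymmetric sawtooth in [-1, 1]: falls 1 -> -1 over `fall` of the cycle,
# recovers -1 -> 1 over the rest. `u` is cycle phase in [0, 1).
asym_wave <- function(u, fall) {
  ifelse(u < fall, 1 - 2 * u / fall, -1 + 2 * (u - fall) / (1 - fall))
}

# AR(1) with centred-exponential (negatively skewed) innovations,
# standardized to unit marginal SD.
ar1_skewed <- function(n, phi) {
  e <- -(rexp(n) - 1)
  s <- as.numeric(stats::filter(e, phi, method = "recursive"))
  s * sqrt(1 - phi^2)
}

#' Generate one synthetic rSO2 series
#'
#' Draws a full monitoring trace: a 60-sample (2-minute) pre-induction
#' baseline window followed by an intraoperative segment of
#' `duration_min * 30` points, per the signal model of
#' [signal_model_params()]. Deterministic in `seed`.
#'
#' @param params a [signal_model_params()].
#' @param duration_min intraoperative duration in minutes (study range
#'   61-157).
#' @param seed integer seed; fixes the series exactly.
#' @param subject_id,side passed to [rso2_series()].
#' @return an [rso2_series()].
#' @export
generate_series <- function(params = signal_model_params(), duration_min = 98,
                            seed = NULL, subject_id = "sim", side = "left") {
  stopifnot(inherits(params, "signal_model_params"))
  if (duration_min * 30 < 100)
    stop("duration too short for a valid intraoperative window", call. = FALSE)
  n <- as.integer(round(duration_min * 30))
  w <- params$irregularity_weight
  with_seed(seed, {
    # pre-induction window: flat near baseline with gentle noise
    base_vals <- params$baseline +
      params$noise_sd * 0.15 * ar1_skewed(60, params$ar_coefficient)
    tm <- seq_len(n) / 30  # minutes
    drift <- params$drift_amplitude *
      sin(2 * pi * tm / params$drift_period_min + runif(1, 0, 2 * pi))
    u <- (tm / params$osc_period_min + runif(1)) %% 1
    periodic <- params$osc_amplitude * asym_wave(u, params$fall_fraction)
    noise <- params$noise_sd * ar1_skewed(n, params$ar_coefficient)
    x <- params$baseline + params$desat_offset + drift +
      (1 - w) * periodic + w * noise
    vals <- pmin(100, pmax(0, c(base_vals, x)))
    rso2_series(vals, baseline_window = 1:60,
                intraop_window = 61:(60 + n),
                subject_id = subject_id, side = side)
  })
}

#' Calibrate the irregularity weight to a target mean sample entropy
#'
#' Monotone bisection on the mixing weight `w` such that the mean
#' SampEn(2, 0.1 SD, N) over a set of seeded synthetic subjects — drawn
#' exactly as [generate_cohort()] draws them, including per-subject weight
#' jitter and random durations — hits the target. Common random numbers
#' across evaluations keep the estimated response monotone and smooth, so
#' bisection converges; the residual calibration error is the Monte Carlo
#' error of `n_series` subjects.
#'
#' @param target_sampen_mean target group mean of SampEn at `r_coef` SD.
#' @param params base [signal_model_params()] (its own weight is ignored).
#' @param m,r_coef entropy parameters.
#' @param tolerance stop when the evaluated mean is this close to target.
#' @param n_series subjects per evaluation.
#' @param duration_range intraoperative duration range, minutes.
#' @param jitter half-width of the uniform per-subject weight jitter.
#' @param seed seed of the common-random-number subject set.
#' @return calibrated weight `w`, with the achieved mean as attribute
#'   `"achieved"`.
#' @export
calibrate_irregularity <- function(target_sampen_mean,
                                   params = signal_model_params(),
                                   m = 2L, r_coef = 0.1, tolerance = 0.01,
                                   n_series = 60L,
                                   duration_range = c(61, 157),
                                   jitter = 0.1, seed = 20260101) {
  f <- function(w) {
    vals <- vapply(seq_len(n_series), function(i) {
      si <- substream_seed(seed, i)
      wi <- min(1, max(0, w + with_seed(si, runif(1, -jitter, jitter))))
      di <- with_seed(si + 1L, runif(1, duration_range[1], duration_range[2]))
      p <- params
      p$irregularity_weight <- wi
      ser <- generate_series(p, duration_min = round(di), seed = si + 2L)
      sample_entropy(ser, m = m, r_coefficient = r_coef)$value
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  lo <- 0; hi <- 1
  f_lo <- f(lo); f_hi <- f(hi)
  if (target_sampen_mean < f_lo - tolerance ||
      target_sampen_mean > f_hi + tolerance)
    stop(sprintf(
      "target %.3f outside achievable mean-SampEn range [%.3f, %.3f]",
      target_sampen_mean, f_lo, f_hi), call. = FALSE)
  if (target_sampen_mean <= f_lo)
    return(structure(0, achieved = f_lo))
  if (target_sampen_mean >= f_hi)
    return(structure(1, achieved = f_hi))
  w <- NA_real_; fw <- NA_real_
  for (it in 1:30) {
    w <- (lo + hi) / 2
    fw <- f(w)
    if (abs(fw - target_sampen_mean) <= tolerance) break
    if (fw < target_sampen_mean) lo <- w else hi <- w
  }
  structure(w, achieved = fw)
}

#' Specification of a synthetic study cohort
#'
#' Defaults reproduce the published cohort structure: 33 subjects with
#' postoperative cognitive improvement (POCI) and 24 without; group-wise
#' covariate prevalences, preoperative MoCA distributions, baseline rSO2
#' distributions, the 61-157 minute duration range at 2-second sampling,
#' and group mean sample-entropy targets of 0.372 (POCI) versus 0.262
#' (non-POCI) at tolerance 0.1 SD.
#'
#' @param n_poci,n_non_poci group sizes.
#' @param prevalence data frame with columns `covariate`, `non_poci`,
#'   `poci` of Bernoulli prevalences per group.
#' @param moca_pre,baseline_rso2,sampen_targets per-group `mean`/`sd`
#'   lists (`non_poci`, `poci`).
#' @param duration_range intraoperative duration range in minutes.
#' @param signal_params base [signal_model_params()] for the series mode.
#' @param weight_jitter per-subject uniform jitter on the irregularity
#'   weight.
#' @param seed root seed; every subject derives a private substream from
#'   it, so any subject is regenerable in isolation.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_poci = 33L, n_non_poci = 24L,
                        prevalence = default_prevalence(),
                        moca_pre = list(non_poci = c(mean = 20.3, sd = 3.9),
                                        poci = c(mean = 18.0, sd = 4.3)),
                        baseline_rso2 = list(non_poci = c(mean = 73.4, sd = 5.1),
                                             poci = c(mean = 74.0, sd = 4.2)),
                        sampen_targets = list(non_poci = c(mean = 0.262, sd = 0.121),
                                              poci = c(mean = 0.372, sd = 0.183)),
                        duration_range = c(61, 157),
                        signal_params = signal_model_params(),
                        weight_jitter = 0.1,
                        seed = 1L) {
  stopifnot(n_poci >= 2L, n_non_poci >= 2L,
            all(prevalence$non_poci >= 0 & prevalence$non_poci <= 1),
            all(prevalence$poci >= 0 & prevalence$poci <= 1),
            moca_pre$non_poci["sd"] > 0, moca_pre$poci["sd"] > 0,
            duration_range[1] >= 4, duration_range[1] <= duration_range[2])
  structure(as.list(environment()), class = "cohort_spec")
}

#' Group-wise covariate prevalences of the study cohort
#'
#' @return data frame of per-group Bernoulli prevalences (proportion with
#'   the characteristic) used as generator defaults.
#' @export
default_prevalence <- function() {
  data.frame(
    covariate = c("male", "education_gt12", "symptomatic", "hypertension",
                  "hyperlipidemia", "diabetes", "coronary_heart_disease",
                  "stroke_history", "tia_history", "smoke_history",
                  "alcohol_history", "antiplatelet", "anticoagulation",
                  "lipid_altering", "glucose_lowering",
                  "blood_pressure_lowering"),
    non_poci = c(23, 14, 23, 21, 17, 10, 6, 9, 11, 16, 18, 21, 0, 22, 10, 19) / 24,
    poci     = c(32, 23, 28, 21, 19, 13, 1, 10, 14, 24, 23, 26, 1, 26, 10, 14) / 33)
}

round_truncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  round(out)
}

#' Generate a synthetic study cohort
#'
#' Draws subject records — POCI group label, covariates, education,
#' pre/post MoCA — and either full rSO2 traces (`mode = "series"`, the
#' irregularity weight per group calibrated to the spec's sample-entropy
#' targets) or directly drawn SampEn01 features (`mode = "features"`,
#' truncated-normal at the group targets; used for large statistical
#' recovery experiments where feature-level normality is the point).
#' Postoperative MoCA deltas have small integer supports (3..6 for the
#' POCI group, -2..2 otherwise), so [classify_poci()] recovers the
#' generated labels exactly. Fully reproducible from the spec seed via
#' per-subject substreams.
#'
#' @param spec a [cohort_spec()].
#' @param mode `"series"` or `"features"`.
#' @param weights optional named vector `c(non_poci =, poci =)` of
#'   pre-calibrated irregularity weights; when omitted in series mode they
#'   are calibrated with [calibrate_irregularity()] (slow).
#' @return a list of class `synthetic_cohort`: `spec`, `manifest` (one row
#'   per subject), `series` (named list of [rso2_series()], series mode
#'   only) and `weights`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            mode = c("series", "features"),
                            weights = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  n <- spec$n_poci + spec$n_non_poci
  root <- spec$seed

  if (mode == "series" && is.null(weights)) {
    weights <- c(
      non_poci = as.numeric(calibrate_irregularity(
        spec$sampen_targets$non_poci[["mean"]], spec$signal_params,
        duration_range = spec$duration_range, jitter = spec$weight_jitter,
        seed = substream_seed(root, 900001))),
      poci = as.numeric(calibrate_irregularity(
        spec$sampen_targets$poci[["mean"]], spec$signal_params,
        duration_range = spec$duration_range, jitter = spec$weight_jitter,
        seed = substream_seed(root, 900002))))
  }

  # group labels in randomized order
  poci <- with_seed(root, sample(rep(c(1L, 0L), c(spec$n_poci, spec$n_non_poci))))
  ids <- sprintf("S%03d", seq_len(n))
  grp <- ifelse(poci == 1L, "poci", "non_poci")

  rows <- vector("list", n)
  series <- if (mode == "series") vector("list", n) else NULL
  for (i in seq_len(n)) {
    si <- substream_seed(root, i)
    g <- grp[i]
    rec <- with_seed(si, {
      cov <- stats::setNames(
        rbinom(nrow(spec$prevalence), 1L, spec$prevalence[[g]]),
        spec$prevalence$covariate)
      edu_gt12 <- cov[["education_gt12"]]
      edu_years <- if (edu_gt12 == 1L) 16L else 9L
      mp <- spec$moca_pre[[g]]
      pre <- round_truncnorm(1, mp[["mean"]], mp[["sd"]], 5, 26)
      dsup <- if (poci[i] == 1L) 3:min(6L, 29L - pre) else -2:2
      delta <- dsup[sample.int(length(dsup), 1L)]
      bl <- spec$baseline_rso2[[g]]
      baseline <- round(rnorm(1, bl[["mean"]], bl[["sd"]]), 1)
      baseline <- min(95, max(55, baseline))
      dur <- round(runif(1, spec$duration_range[1], spec$duration_range[2]))
      side <- sample(c("left", "right"), 1L)
      list(cov = cov, edu_gt12 = edu_gt12, edu_years = edu_years,
           pre = pre, post = pre + delta, baseline = baseline,
           dur = dur, side = side)
    })
    wi <- NA_real_
    sampen01 <- NA_real_
    if (mode == "series") {
      wi <- min(1, max(0, weights[[g]] +
                         with_seed(si + 7L, runif(1, -spec$weight_jitter,
                                                  spec$weight_jitter))))
      p <- spec$signal_params
      p$baseline <- rec$baseline
      p$irregularity_weight <- wi
      series[[i]] <- generate_series(p, duration_min = rec$dur,
                                     seed = si + 11L, subject_id = ids[i],
                                     side = rec$side)
    } else {
      st <- spec$sampen_targets[[g]]
      sampen01 <- with_seed(si + 7L, {
        repeat {
          x <- rnorm(1, st[["mean"]], st[["sd"]])
          if (x > 0) break
        }
        x
      })
    }
    rows[[i]] <- data.frame(
      subject_id = ids[i], poci_true = poci[i],
      as.list(rec$cov),
      education_years = rec$edu_years,
      moca_pre_raw = rec$pre, moca_post_raw = rec$post,
      baseline_rso2_target = rec$baseline, duration_min = rec$dur,
      side = rec$side, irregularity_weight = wi, sampen01 = sampen01)
  }
  manifest <- do.call(rbind, rows)
  if (mode == "series") names(series) <- ids
  structure(list(spec = spec, mode = mode, manifest = manifest,
                 series = series, weights = weights),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d POCI), mode '%s'\n",
              nrow(x$manifest), sum(x$manifest$poci_true), x$mode))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `cohort.csv` (the manifest) and, in series mode, one
#' `series/<id>.csv` plus metadata sidecar per subject, in the dialect of
#' [write_series()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$manifest, file.path(dir, "cohort.csv"), row.names = FALSE)
  if (!is.null(cohort$series)) {
    sdir <- file.path(dir, "series")
    dir.create(sdir, showWarnings = FALSE)
    for (id in names(cohort$series))
      write_series(cohort$series[[id]], file.path(sdir, paste0(id, ".csv")))
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `cohort.csv` and optionally
#'   `series/`.
#' @return a list with `manifest` and `series` (possibly `NULL`).
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "cohort.csv")
  if (!file.exists(mf)) stop("missing manifest: ", mf, call. = FALSE)
  manifest <- read.csv(mf)
  sdir <- file.path(dir, "series")
  series <- NULL
  if (dir.exists(sdir)) {
    files <- list.files(sdir, pattern = "\\.csv$", full.names = TRUE)
    series <- lapply(files, read_series)
    names(series) <- vapply(series, function(s) s$subject_id, character(1))
  }
  list(manifest = manifest, series = series)
}

#' Redraw a binary outcome from a logistic model on a feature
#'
#' Used for parameter-recovery experiments: given a numeric feature, draws
#' outcomes from `logit P(y = 1) = b0 + beta * x / sd(x)` with `b0` chosen
#' so the marginal prevalence is approximately `prevalence`.
#'
#' @param x numeric feature vector.
#' @param log_or_per_sd injected log odds ratio per SD of `x`.
#' @param prevalence target marginal outcome prevalence.
#' @param seed optional integer seed.
#' @return integer 0/1 outcome vector.
#' @export
inject_logistic_outcome <- function(x, log_or_per_sd, prevalence = 0.5,
                                    seed = NULL) {
  z <- as.numeric(x) / sd(x)
  b0 <- stats::uniroot(function(b) mean(plogis(b + log_or_per_sd * z)) - prevalence,
                       c(-20, 20))$root
  with_seed(seed, rbinom(length(z), 1L, plogis(b0 + log_or_per_sd * z)))
}
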