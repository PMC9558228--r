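#' Configuration for a full study run
#'
#' @param cohort_dir directory with `cohort.csv` + `series/` (as written
#'   by [write_cohort()]); `NULL` to simulate a cohort first.
#' @param spec [cohort_spec()] used when simulating.
#' @param out_dir where report CSVs and the run log are written; `NULL`
#'   for in-memory results only.
#' @param m,coefficients sample-entropy grid.
#' @param run_surrogate run the per-subject surrogate nonlinearity screen.
#' @param n_surrogates,surrogate_method,alpha surrogate-test settings.
#' @param ci_method ROC interval method, `"delong"` or `"hanley_mcneil"`.
#' @param t_variant `"pooled"` or `"welch"` for continuous comparisons.
#' @param p_enter univariate p threshold for entry into the multivariable
#'   model.
#' @param p_remove backward likelihood-ratio removal threshold.
#' @param weights pre-calibrated irregularity weights (skips calibration).
#' @param seed root seed for simulation and surrogate draws.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort_dir = NULL, spec = cohort_spec(),
                       out_dir = NULL, m = 2L,
                       coefficients = c(0.10, 0.15, 0.20, 0.25),
                       run_surrogate = TRUE, n_surrogates = 99L,
                       surrogate_method = "amplitude_adjusted", alpha = 0.05,
                       ci_method = "delong", t_variant = "pooled",
                       p_enter = 0.10, p_remove = 0.10,
                       weights = NULL, seed = 1L) {
  if (length(coefficients) == 0L)
    stop("entropy coefficient grid must be nonempty", call. = FALSE)
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir))
    stop("cohort directory does not exist: ", cohort_dir, call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

binary_covariates <- function(manifest) {
  known <- default_prevalence()$covariate
  cand <- c(known, "education_gt12")
  intersect(cand, names(manifest)[vapply(manifest, function(x)
    all(x %in% c(0L, 1L, NA)), logical(1))])
}

group_mean_sd <- function(x, poci) {
  c(non_mean = mean(x[poci == 0]), non_sd = sd(x[poci == 0]),
    poci_mean = mean(x[poci == 1]), poci_sd = sd(x[poci == 1]))
}

#' Extract per-subject signal features
#'
#' For each series: baseline, summary statistics, desaturation burden at
#' the three standard thresholds, the sample-entropy profile, and
#' optionally the surrogate nonlinearity screen.
#'
#' @param series named list of [rso2_series()].
#' @param config a [run_config()].
#' @return data frame, one row per subject.
#' @export
extract_features <- function(series, config = run_config()) {
  rows <- lapply(seq_along(series), function(i) {
    s <- series[[i]]
    sm <- summarize_series(s)
    bl <- sm$baseline
    des <- lapply(c(1.0, 0.9, 0.8), function(f)
      desaturation_metrics(s, baseline = bl, fraction = f))
    prof <- entropy_profile(s, m = config$m,
                            coefficients = config$coefficients)
    ent <- stats::setNames(as.list(prof$value), prof$label)
    out <- cbind(sm,
                 data.frame(dur_below_100 = des[[1]]$duration_min,
                            dur_below_90 = des[[2]]$duration_min,
                            dur_below_80 = des[[3]]$duration_min,
                            area_below_100 = des[[1]]$area_min_pct,
                            area_below_90 = des[[2]]$area_min_pct,
                            area_below_80 = des[[3]]$area_min_pct),
                 as.data.frame(ent))
    if (isTRUE(config$run_surrogate)) {
      st <- surrogate_test(s, n_surrogates = config$n_surrogates,
                           method = config$surrogate_method,
                           alpha = config$alpha,
                           seed = substream_seed(config$seed, 500000 + i))
      out$asymmetry_statistic <- st$observed_statistic
      out$surrogate_p <- st$p
      out$nonlinear <- st$reject_null
    }
    out
  })
  do.call(rbind, rows)
}

#' Run the full study pipeline
#'
#' Simulates (or loads) a cohort, extracts per-subject oximetry features,
#' labels postoperative cognitive improvement from the MoCA columns, and
#' produces the full report: a baseline-characteristics comparison table,
#' an oximetry/entropy comparison table, univariate and backward-LR
#' multivariable logistic tables, and ROC summaries for SampEn01 alone and
#' for SampEn01 combined with preoperative MoCA and blood-pressure-lowering
#' treatment. When `out_dir` is set, every table is written as CSV together
#' with a run log recording all settings and seeds; reruns with the same
#' seed are byte-identical.
#'
#' @param config a [run_config()].
#' @return a list of class `study_report` with elements `cohort`,
#'   `features`, `table1`, `table2`, `table3_univariate`,
#'   `table3_multivariate`, `roc`, `nonlinear_count`.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$cohort_dir)) {
    spec <- config$spec
    spec$seed <- config$seed
    cohort <- generate_cohort(spec, mode = "series", weights = config$weights)
    manifest <- cohort$manifest
    series <- cohort$series
  } else {
    cohort <- read_cohort(config$cohort_dir)
    manifest <- cohort$manifest
    series <- cohort$series
    if (is.null(series))
      stop("cohort directory has no series/ subdirectory: ",
           config$cohort_dir, call. = FALSE)
  }
  series <- series[manifest$subject_id]

  features <- extract_features(series, config)
  lab <- classify_poci(manifest$moca_pre_raw, manifest$moca_post_raw,
                       manifest$education_years)
  poci <- as.integer(lab$poci)
  dat <- cbind(manifest[c("subject_id", "moca_pre_raw", "moca_post_raw",
                          "education_years")],
               manifest[intersect(binary_covariates(manifest), names(manifest))],
               poci = poci,
               features[match(manifest$subject_id, features$subject_id),
                        -1, drop = FALSE])

  # -- baseline characteristics ---------------------------------------
  t1_rows <- lapply(binary_covariates(manifest), function(cv) {
    tb <- table(factor(dat[[cv]], levels = 0:1),
                factor(poci, levels = 0:1))
    res <- tryCatch(compare_categorical(unclass(matrix(tb, 2, 2))),
                    error = function(e)
                      list(method = "degenerate", statistic = NA_real_,
                           p = NA_real_))
    data.frame(characteristic = cv,
               non_poci_yes = tb[2, 1], poci_yes = tb[2, 2],
               method = res$method,
               statistic = ifelse(is.na(res$statistic), NA, res$statistic),
               p = res$p)
  })
  moca_cmp <- compare_means(dat$moca_pre_raw[poci == 0],
                            dat$moca_pre_raw[poci == 1],
                            variant = config$t_variant)
  gm <- group_mean_sd(dat$moca_pre_raw, poci)
  t1_rows <- c(t1_rows, list(data.frame(
    characteristic = "moca_pre", non_poci_yes = NA, poci_yes = NA,
    method = config$t_variant, statistic = moca_cmp$statistic,
    p = moca_cmp$p)))
  table1 <- do.call(rbind, t1_rows)

  # -- oximetry / entropy comparisons ---------------------------------
  cont_vars <- c("baseline", "mean", "lowest", "highest",
                 "dur_below_100", "dur_below_90", "dur_below_80",
                 "area_below_100", "area_below_90", "area_below_80",
                 grep("^SampEn", names(dat), value = TRUE))
  skew_vars <- grep("^(dur|area)_", cont_vars, value = TRUE)
  t2_rows <- lapply(cont_vars, function(v) {
    x0 <- dat[[v]][poci == 0]; x1 <- dat[[v]][poci == 1]
    variant <- if (v %in% skew_vars) "mann_whitney" else config$t_variant
    cmp <- tryCatch(compare_means(x0, x1, variant = variant),
                    error = function(e)  # e.g. a burden column of all zeros
                      list(statistic = NA_real_, p = NA_real_))
    data.frame(measure = v,
               non_poci_mean = mean(x0), non_poci_sd = sd(x0),
               poci_mean = mean(x1), poci_sd = sd(x1),
               variant = variant, statistic = cmp$statistic, p = cmp$p)
  })
  table2 <- do.call(rbind, t2_rows)

  # -- logistic modelling ---------------------------------------------
  cand_defs <- list(
    SampEn01_per_SD = list(x = dat$SampEn01, per_sd = TRUE),
    moca_pre = list(x = dat$moca_pre_raw, per_sd = FALSE))
  for (cv in binary_covariates(manifest))
    if (var(dat[[cv]]) > 0)  # constant covariates cannot enter the model
      cand_defs[[cv]] <- list(x = dat[[cv]], per_sd = FALSE)
  uni_rows <- lapply(names(cand_defs), function(nm) {
    d <- cand_defs[[nm]]
    fit <- univariate_logistic(poci, d$x, per_sd = d$per_sd, name = nm)
    cbind(fit$terms, separation = fit$separation)
  })
  table3_uni <- do.call(rbind, uni_rows)

  entered <- table3_uni$term[!is.na(table3_uni$p) &
                               table3_uni$p < config$p_enter &
                               !table3_uni$separation]
  table3_multi <- NULL
  multi_fit <- NULL
  if (length(entered) > 0) {
    cand <- data.frame(lapply(entered, function(nm) {
      d <- cand_defs[[nm]]
      if (d$per_sd) d$x / sd(d$x) else d$x
    }))
    names(cand) <- entered
    multi_fit <- multivariate_logistic_backward_lr(poci, cand,
                                                   p_remove = config$p_remove)
    table3_multi <- multi_fit$terms
  }

  # -- ROC --------------------------------------------------------------
  roc_single <- roc_auc(dat$SampEn01, poci, ci_method = config$ci_method)
  comb_vars <- data.frame(SampEn01 = dat$SampEn01,
                          moca_pre = dat$moca_pre_raw,
                          blood_pressure_lowering = dat$blood_pressure_lowering)
  roc_comb <- combined_model_auc(poci, comb_vars, ci_method = config$ci_method)
  roc_tab <- data.frame(
    model = c("SampEn01", "SampEn01 + moca_pre + blood_pressure_lowering"),
    auc = c(roc_single$auc, roc_comb$auc),
    ci_low = c(roc_single$ci_low, roc_comb$ci_low),
    ci_high = c(roc_single$ci_high, roc_comb$ci_high),
    ci_method = config$ci_method)

  nonlinear_count <- if (isTRUE(config$run_surrogate))
    sum(features$nonlinear) else NA_integer_

  report <- structure(
    list(cohort = cohort, features = features, data = dat,
         table1 = table1, table2 = table2,
         table3_univariate = table3_uni, table3_multivariate = table3_multi,
         multivariate_fit = multi_fit,
         roc = roc_tab, roc_single = roc_single, roc_combined = roc_comb,
         nonlinear_count = nonlinear_count, config = config),
    class = "study_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    if (!is.null(df)) write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(report$table1, "table1_baseline_characteristics.csv")
  wr(report$table2, "table2_oximetry_entropy.csv")
  wr(report$table3_univariate, "table3_univariate.csv")
  wr(report$table3_multivariate, "table3_multivariate.csv")
  wr(report$roc, "roc_summary.csv")
  wr(report$features, "features.csv")
  cfg <- report$config
  log_lines <- c(
    "rso2entropy run log",
    sprintf("seed: %d", cfg$seed),
    sprintf("entropy: m = %d, coefficients = %s", cfg$m,
            paste(cfg$coefficients, collapse = ", ")),
    sprintf("surrogate: %s, K = %d, alpha = %g, enabled = %s",
            cfg$surrogate_method, cfg$n_surrogates, cfg$alpha,
            cfg$run_surrogate),
    sprintf("statistics: ci_method = %s, t_variant = %s, p_enter = %g, p_remove = %g",
            cfg$ci_method, cfg$t_variant, cfg$p_enter, cfg$p_remove),
    sprintf("cohort: %s", if (is.null(cfg$cohort_dir)) "simulated"
            else cfg$cohort_dir),
    sprintf("nonlinear series: %s / %d",
            ifelse(is.na(report$nonlinear_count), "not screened",
                   report$nonlinear_count), nrow(report$features)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf("<study_report> %d subjects, %d POCI (%.1f%%)\n",
              n, sum(x$data$poci), 100 * mean(x$data$poci)))
  cat(sprintf("  SampEn01 AUC %.3f (%.3f-%.3f); combined AUC %.3f (%.3f-%.3f)\n",
              x$roc$auc[1], x$roc$ci_low[1], x$roc$ci_high[1],
              x$roc$auc[2], x$roc$ci_low[2], x$roc$ci_high[2]))
  if (!is.na(x$nonlinear_count))
    cat(sprintf("  nonlinear dynamics: %d / %d series\n",
                x$nonlinear_count, n))
  invisible(x)
}
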