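#' Compare a 2x2 contingency table between groups
#'
#' Applies the test policy that reproduces the published categorical
#' statistics of small surgical cohorts analysed with SPSS: Pearson's
#' chi-square when every expected cell count is at least 5, the Yates
#' continuity-corrected chi-square when the smallest expected count is in
#' \[1, 5), and Fisher's exact test (two-sided by the probability-mass
#' rule: the sum of hypergeometric probabilities of all tables no more
#' probable than the observed one) when it is below 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts (rows = levels of
#'   the characteristic, columns = groups).
#' @return an object of class `contingency_result`: `table`, `method`
#'   (`"pearson"`, `"yates"` or `"fisher"`), `statistic` (chi-square value,
#'   `NA` for Fisher), `p`, `min_expected`.
#' @export
compare_categorical <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L)) || any(tb < 0) || any(tb != round(tb)))
    stop("`table` must be a 2x2 matrix of nonnegative integer counts",
         call. = FALSE)
  rs <- rowSums(tb); cs <- colSums(tb); n <- sum(tb)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: a margin is zero", call. = FALSE)
  E <- outer(rs, cs) / n
  min_e <- min(E)
  if (min_e < 1) {
    method <- "fisher"
    statistic <- NA_real_
    p <- fisher_2x2_p(tb)
  } else if (min_e < 5) {
    method <- "yates"
    statistic <- sum(pmax(abs(tb - E) - 0.5, 0)^2 / E)
    p <- pchisq(statistic, df = 1, lower.tail = FALSE)
  } else {
    method <- "pearson"
    statistic <- sum((tb - E)^2 / E)
    p <- pchisq(statistic, df = 1, lower.tail = FALSE)
  }
  structure(list(table = tb, method = method, statistic = statistic,
                 p = p, min_expected = min_e),
            class = "contingency_result")
}

# Two-sided Fisher p for a 2x2 table: sum of hypergeometric probabilities
# of all tables (with the same margins) no more probable than the observed.
fisher_2x2_p <- function(tb) {
  m <- sum(tb[1, ]); nn <- sum(tb[2, ]); k <- sum(tb[, 1])
  lo <- max(0L, k - nn); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, nn, k)
  p_obs <- stats::dhyper(tb[1, 1], m, nn, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2 comparison [%s]: %s p = %.3f (min expected %.2f)\n",
              x$method,
              if (is.na(x$statistic)) "" else sprintf("chi2 = %.3f,", x$statistic),
              x$p, x$min_expected))
  invisible(x)
}

as_group_summary <- function(g) {
  if (is.list(g) && all(c("n", "mean", "sd") %in% names(g)))
    return(list(n = g$n, mean = g$mean, sd = g$sd, raw = NULL))
  g <- as.numeric(g)
  list(n = length(g), mean = mean(g), sd = sd(g), raw = g)
}

#' Compare a continuous measure between two groups
#'
#' Unpaired pooled-variance Student's t-test (default), Welch's t-test, or
#' the Mann-Whitney U-test with tie-corrected normal approximation. The t
#' variants accept either raw values or `list(n=, mean=, sd=)` summaries;
#' Mann-Whitney requires raw values.
#'
#' @param group_a,group_b numeric vectors, or `list(n=, mean=, sd=)`.
#' @param variant `"pooled"`, `"welch"` or `"mann_whitney"`.
#' @return an object of class `mean_comparison`: group summaries,
#'   `variant`, `statistic` (t or z), `df` (t variants), `p` (two-sided).
#' @export
compare_means <- function(group_a, group_b,
                          variant = c("pooled", "welch", "mann_whitney")) {
  variant <- match.arg(variant)
  a <- as_group_summary(group_a)
  b <- as_group_summary(group_b)
  if (a$n < 2 || b$n < 2) stop("need n >= 2 per group", call. = FALSE)
  if (variant == "mann_whitney") {
    if (is.null(a$raw) || is.null(b$raw))
      stop("Mann-Whitney requires raw values, not summaries", call. = FALSE)
    res <- mann_whitney_z(a$raw, b$raw)
    statistic <- res$z; df <- NA_real_; p <- res$p; U <- res$U
  } else {
    d <- a$mean - b$mean
    if (variant == "pooled") {
      sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
      se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
      df <- a$n + b$n - 2
    } else {
      va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
      se <- sqrt(va + vb)
      df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    }
    statistic <- d / se
    p <- 2 * stats::pt(-abs(statistic), df)
    U <- NA_real_
  }
  structure(list(group_a = a[c("n", "mean", "sd")],
                 group_b = b[c("n", "mean", "sd")],
                 variant = variant, statistic = statistic, df = df,
                 U = U, p = p),
            class = "mean_comparison")
}

# U = #(a > b) + 0.5 #(a = b) via midranks; z by tie-corrected normal
# approximation (no continuity correction).
mann_whitney_z <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) stop("all values tied: Mann-Whitney z undefined", call. = FALSE)
  z <- (U - n1 * n2 / 2) / sqrt(v)
  list(U = U, z = z, p = 2 * pnorm(-abs(z)))
}

#' @export
print.mean_comparison <- function(x, ...) {
  cat(sprintf("%s comparison: statistic = %.3f, p = %.3f\n",
              x$variant, x$statistic, x$p))
  invisible(x)
}

check_binary_outcome <- function(outcome) {
  outcome <- as.integer(outcome)
  if (anyNA(outcome) || !all(outcome %in% c(0L, 1L)))
    stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(outcome)) < 2L)
    stop("outcome has a single class", call. = FALSE)
  outcome
}

logistic_terms <- function(fit, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  sm <- summary(fit)$coefficients
  keep <- setdiff(rownames(sm), "(Intercept)")
  data.frame(
    term = keep,
    coefficient = sm[keep, 1],
    se = sm[keep, 2],
    odds_ratio = exp(sm[keep, 1]),
    ci_low = exp(sm[keep, 1] - z * sm[keep, 2]),
    ci_high = exp(sm[keep, 1] + z * sm[keep, 2]),
    p = sm[keep, 4],
    row.names = NULL)
}

separation_flag <- function(fit) {
  p <- fitted(fit)
  any(p < 1e-8 | p > 1 - 1e-8) || any(abs(coef(fit)) > 15, na.rm = TRUE)
}

#' Univariate logistic regression
#'
#' Maximum-likelihood logistic fit of a binary outcome on one predictor,
#' with Wald 95% confidence intervals on the odds ratio. With
#' `per_sd = TRUE` the predictor is standardized by its sample SD first, so
#' the odds ratio is per one SD of the predictor. Complete separation is
#' flagged, not silently reported.
#'
#' @param outcome binary 0/1 vector.
#' @param predictor numeric or binary vector.
#' @param per_sd standardize the predictor by its sample SD.
#' @param name term label used in the output.
#' @return an object of class `logistic_fit`: `terms` data frame
#'   (coefficient, odds_ratio, ci_low, ci_high, p), `scope =
#'   "univariate"`, `scaling`, `separation` flag and the underlying `fit`.
#' @export
univariate_logistic <- function(outcome, predictor, per_sd = FALSE,
                                name = "predictor") {
  outcome <- check_binary_outcome(outcome)
  x <- as.numeric(predictor)
  if (length(x) != length(outcome)) stop("length mismatch", call. = FALSE)
  scaling <- "natural units"
  if (isTRUE(per_sd)) {
    s <- sd(x)
    if (s == 0) stop("constant predictor cannot be standardized", call. = FALSE)
    x <- x / s
    scaling <- "per SD of predictor"
  }
  dat <- data.frame(.y = outcome, x = x)
  names(dat)[2] <- name
  fit <- suppressWarnings(glm(.y ~ ., family = binomial(), data = dat,
                              control = stats::glm.control(epsilon = 1e-12,
                                                           maxit = 100)))
  sep <- separation_flag(fit)
  if (sep) warning("possible complete separation; Wald intervals unreliable",
                   call. = FALSE)
  structure(list(terms = logistic_terms(fit), scope = "univariate",
                 scaling = scaling, separation = sep,
                 selection_trace = NULL, fit = fit),
            class = "logistic_fit")
}

#' Multivariable logistic regression with backward likelihood-ratio
#' selection
#'
#' Starts from the model containing every candidate (conventionally those
#' with univariate p < 0.1), then repeatedly removes the term whose
#' likelihood-ratio test against the reduced model has the largest p-value,
#' until every remaining term has LR p at or below `p_remove` (0.10, the
#' SPSS backward-LR default). Surviving terms are reported with Wald
#' intervals; the removal order and LR p-values are kept as a trace.
#'
#' @param outcome binary 0/1 vector.
#' @param candidates data frame of candidate predictors (numeric or 0/1).
#' @param p_remove removal threshold for the LR p-value.
#' @return an object of class `logistic_fit` with `scope =
#'   "multivariate"` and a `selection_trace` data frame (`step`, `removed`,
#'   `lr_p`).
#' @export
multivariate_logistic_backward_lr <- function(outcome, candidates,
                                              p_remove = 0.10) {
  outcome <- check_binary_outcome(outcome)
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1L) stop("empty candidate set", call. = FALSE)
  if (nrow(candidates) != length(outcome)) stop("length mismatch", call. = FALSE)
  dat <- cbind(data.frame(.y = outcome), candidates)
  current <- names(candidates)
  trace <- data.frame(step = integer(), removed = character(),
                      lr_p = numeric())
  step <- 0L
  repeat {
    fit <- suppressWarnings(glm(
      stats::reformulate(current, response = ".y"),
      family = binomial(), data = dat,
      control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
    if (length(current) == 0L) break
    lr_p <- vapply(current, function(tm) {
      reduced <- setdiff(current, tm)
      f0 <- suppressWarnings(glm(
        if (length(reduced)) stats::reformulate(reduced, response = ".y")
        else .y ~ 1,
        family = binomial(), data = dat,
        control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
      pchisq(stats::deviance(f0) - stats::deviance(fit), df = 1,
             lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(lr_p)
    if (lr_p[worst] <= p_remove) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     removed = current[worst],
                                     lr_p = unname(lr_p[worst])))
    current <- current[-worst]
    if (length(current) == 0L) {
      fit <- suppressWarnings(glm(.y ~ 1, family = binomial(), data = dat))
      break
    }
  }
  sep <- separation_flag(fit)
  if (sep) warning("possible complete separation in final model", call. = FALSE)
  structure(list(terms = logistic_terms(fit), scope = "multivariate",
                 scaling = "natural units", separation = sep,
                 selection_trace = trace, retained = current, fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic regression (%s, %s)%s\n", x$scope, x$scaling,
              if (isTRUE(x$separation)) " [separation flagged]" else ""))
  tf <- x$terms
  tf$or_ci <- sprintf("%.2f (%.2f, %.2f)", tf$odds_ratio, tf$ci_low, tf$ci_high)
  print(tf[, c("term", "or_ci", "p")], digits = digits, row.names = FALSE)
  if (!is.null(x$selection_trace) && nrow(x$selection_trace) > 0) {
    cat("Backward-LR removals:\n")
    print(x$selection_trace, row.names = FALSE)
  }
  invisible(x)
}

#' ROC area under the curve with confidence interval
#'
#' AUC by pair counting — the proportion of positive-negative score pairs
#' ranked concordantly, ties counting one half — with a standard error and
#' 95% interval by DeLong's placement-value method (default) or the
#' Hanley-McNeil formula. Higher scores are taken to indicate the positive
#' class.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 class labels (1 = positive).
#' @param ci_method `"delong"` or `"hanley_mcneil"`.
#' @param level confidence level.
#' @return an object of class `roc_result`: `auc`, `se`, `ci_low`,
#'   `ci_high`, `ci_method`, `n_positive`, `n_negative`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "hanley_mcneil"),
                    level = 0.95) {
  ci_method <- match.arg(ci_method)
  labels <- check_binary_outcome(labels)
  scores <- as.numeric(scores)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  n1 <- length(pos); n0 <- length(neg)

  # midrank formula: equals (concordant + 0.5 ties) / (n1 * n0)
  rk <- rank(c(pos, neg))
  auc <- (sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  if (ci_method == "delong") {
    # placement values of each positive among negatives and vice versa
    v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n0,
                  numeric(1))
    v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / n1,
                  numeric(1))
    se <- sqrt(var(v10) / n1 + var(v01) / n0)
  } else {
    se <- sqrt(hanley_mcneil_var(auc, n1, n0))
  }
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(auc = auc, se = se,
                 ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se),
                 ci_method = ci_method, n_positive = n1, n_negative = n0),
            class = "roc_result")
}

hanley_mcneil_var <- function(A, n1, n0) {
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  (A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n0 - 1) * (q2 - A^2)) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f, %s; n+ = %d, n- = %d)\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method,
              x$n_positive, x$n_negative))
  invisible(x)
}

#' ROC of a multivariable logistic model
#'
#' Fits a logistic model of the outcome on all supplied variables and
#' returns the ROC of its in-sample fitted probabilities — the standard way
#' to ask whether adding covariates to a single predictor improves
#' discrimination.
#'
#' @param outcome binary 0/1 vector.
#' @param variables data frame of predictor columns.
#' @inheritParams roc_auc
#' @return an object of class `roc_result`, with the fitted `glm` attached
#'   as attribute `"fit"`.
#' @export
combined_model_auc <- function(outcome, variables,
                               ci_method = c("delong", "hanley_mcneil")) {
  ci_method <- match.arg(ci_method)
  outcome <- check_binary_outcome(outcome)
  variables <- as.data.frame(variables)
  dat <- cbind(data.frame(.y = outcome), variables)
  fit <- suppressWarnings(glm(.y ~ ., family = binomial(), data = dat))
  res <- roc_auc(fitted(fit), outcome, ci_method = ci_method)
  attr(res, "fit") <- fit
  res
}

#' Power of a two-sided z-test on the AUC
#'
#' Power to detect `auc_alt` against a null AUC of `auc_null` with a
#' two-sided z-test, using the Hanley-McNeil variance
#' (`Q1 = A / (2 - A)`, `Q2 = 2 A^2 / (1 + A)`) evaluated under the null
#' and the alternative:
#' `power = Phi((auc_alt - auc_null - z_(1-alpha/2) * SE0) / SE1)`.
#'
#' @param n_positive,n_negative group sizes.
#' @param auc_null null-hypothesis AUC (at least 0.5).
#' @param auc_alt alternative AUC, in (`auc_null`, 1).
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
auc_power <- function(n_positive, n_negative, auc_null = 0.5, auc_alt,
                      alpha = 0.05) {
  if (n_positive < 2 || n_negative < 2) stop("need n >= 2 per group", call. = FALSE)
  if (!(auc_null >= 0.5 && auc_null < auc_alt && auc_alt < 1))
    stop("need 0.5 <= auc_null < auc_alt < 1", call. = FALSE)
  se0 <- sqrt(hanley_mcneil_var(auc_null, n_positive, n_negative))
  se1 <- sqrt(hanley_mcneil_var(auc_alt, n_positive, n_negative))
  pnorm((auc_alt - auc_null - qnorm(1 - alpha / 2) * se0) / se1)
}
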