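#' Nagelkerke pseudo-R-squared
#'
#' `R2 = (1 - exp((2/n) (ll_null - ll_full))) / (1 - exp((2/n) ll_null))`,
#' the Cox-Snell ratio rescaled to a `[0, 1]` maximum. Any baseline model
#' nested in the full model may play the role of `ll_null`; the threshold
#' sweep uses the covariate-only baseline so the value reads as variance
#' explained by the score.
#'
#' @param ll_null Log-likelihood of the baseline model.
#' @param ll_full Log-likelihood of the full model (`>= ll_null`).
#' @param n Sample size.
#' @return R-squared in `[0, 1]`.
#' @export
#' @examples
#' nagelkerke_r2(-180, -160, 278)
nagelkerke_r2 <- function(ll_null, ll_full, n) {
  if (n <= 0) abort("n must be positive")
  if (ll_full < ll_null - 1e-8) {
    abort("ll_full must be >= ll_null (models must be nested)")
  }
  denom <- 1 - exp(2 / n * ll_null)
  if (denom <= 0) return(0)
  r2 <- (1 - exp(2 / n * (ll_null - ll_full))) / denom
  min(max(r2, 0), 1)
}

#' Rank-statistic ROC AUC
#'
#' `AUC = P(score_case > score_control) + P(tie) / 2`, computed from the
#' Wilcoxon rank sum.
#'
#' @param scores Numeric predictor.
#' @param y 0/1 outcomes (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort("both outcome classes must be present to compute AUC")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Points of the empirical ROC curve
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`, ordered for plotting.
#' @export
roc_points <- function(scores, y) {
  y <- as.integer(y)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord] == 1); fp <- cumsum(y[ord] == 0)
  tibble::tibble(threshold = c(Inf, scores[ord]),
                 fpr = c(0, fp / sum(y == 0)),
                 tpr = c(0, tp / sum(y == 1)))
}

#' Covariate-adjusted logistic regression for conversion
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of a binary
#' conversion outcome on a score plus covariates, reporting per-term
#' odds ratios with Wald confidence intervals, Nagelkerke
#' pseudo-R-squared against the intercept-only model, and the AUC of the
#' fitted linear predictor. Quasi-separation (diverging coefficients) is
#' flagged rather than silently reported.
#'
#' @param data A tibble with the outcome and predictor columns.
#' @param outcome Name of the 0/1 outcome column.
#' @param predictors Character vector of predictor column names; the
#'   first is conventionally the (z-scored) PRS.
#' @param conf_level Confidence level for odds-ratio intervals.
#' @return An object of class `neuroprs_logistic` with [tidy()] and
#'   [glance()] methods.
#' @export
logistic_fit <- function(data, outcome, predictors,
                         conf_level = 0.95) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("outcome has no variation: cannot fit a logistic model",
          class = "neuroprs_data_error")
  }
  df <- as.data.frame(data[predictors])
  keep <- complete.cases(df) & !is.na(y)
  df <- df[keep, , drop = FALSE]; y <- y[keep]
  x <- stats::model.matrix(~ ., data = df)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    abort(paste("singular design; collinear column(s):",
                paste(bad, collapse = ", ")),
          class = "neuroprs_data_error")
  }
  fit <- suppressWarnings(glm(y ~ x - 1, family = binomial()))
  est <- unname(coef(fit))
  se <- sqrt(diag(vcov(fit)))
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  coefs <- tibble::tibble(
    term = colnames(x), estimate = est, std_error = unname(se),
    statistic = est / se, p_value = 2 * pnorm(-abs(est / se)),
    odds_ratio = exp(est),
    or_low = exp(est - zcrit * se), or_high = exp(est + zcrit * se))
  ll_full <- as.numeric(logLik(fit))
  ll_null <- irls_logistic(matrix(1, length(y), 1), y)$ll
  out <- list(
    coefficients = coefs,
    ll_full = ll_full, ll_null = ll_null, n = length(y),
    nagelkerke = nagelkerke_r2(ll_null, ll_full, length(y)),
    auc = roc_auc(fit$linear.predictors, y),
    separated = !fit$converged || any(abs(est) > 30),
    outcome = outcome, predictors = predictors,
    linear_predictors = fit$linear.predictors, y = y)
  class(out) <- "neuroprs_logistic"
  out
}

#' @export
print.neuroprs_logistic <- function(x, ...) {
  cat(sprintf("<logistic fit> n = %d, Nagelkerke R2 = %.4f, AUC = %.3f%s\n",
              x$n, x$nagelkerke, x$auc,
              if (x$separated) " [separation flagged]" else ""))
  print(x$coefficients, n = nrow(x$coefficients))
  invisible(x)
}

#' @method tidy neuroprs_logistic
#' @export
tidy.neuroprs_logistic <- function(x, ...) x$coefficients

#' @method glance neuroprs_logistic
#' @export
glance.neuroprs_logistic <- function(x, ...) {
  tibble::tibble(n = x$n, ll_null = x$ll_null, ll_full = x$ll_full,
                 nagelkerke = x$nagelkerke, auc = x$auc,
                 separated = x$separated)
}

#' Cox proportional-hazards fit for time to conversion
#'
#' Breslow-tie partial-likelihood fit via [survival::coxph()] with the
#' Breslow baseline cumulative hazard; per-profile cumulative risk is
#' `1 - exp(-Lambda0(t) * exp(x beta))`.
#'
#' @param data Tibble with time, event and predictor columns.
#' @param time,event Column names of follow-up time (> 0) and 0/1 event
#'   indicator (at least one event required).
#' @param predictors Character vector of predictor column names.
#' @return An object of class `neuroprs_cox` with [tidy()] / [glance()]
#'   methods; `$baseline` holds the Breslow cumulative hazard.
#' @export
cox_fit <- function(data, time = "time_years", event = "event",
                    predictors) {
  tt <- data[[time]]; ev <- as.integer(data[[event]])
  if (any(tt <= 0, na.rm = TRUE)) abort("all times must be positive")
  if (sum(ev, na.rm = TRUE) == 0) {
    abort("no events: Cox model undefined", class = "neuroprs_data_error")
  }
  df <- as.data.frame(data[predictors])
  constant <- vapply(df, function(v) length(unique(v[!is.na(v)])) < 2,
                     logical(1))
  if (all(constant)) {
    abort("all predictors constant: no information for a Cox fit",
          class = "neuroprs_data_error")
  }
  df$.time <- tt; df$.event <- ev
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", predictors[!constant]), collapse = " + ")))
  fit <- survival::coxph(form, data = df, ties = "breslow")
  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    statistic = unname(est / se),
    p_value = 2 * pnorm(-abs(unname(est / se))),
    hazard_ratio = exp(unname(est)))
  base <- survival::basehaz(fit, centered = FALSE)
  out <- list(coefficients = coefs, fit = fit,
              baseline = tibble::tibble(time = base$time,
                                        cum_hazard = base$hazard),
              ll = fit$loglik[2], n = fit$n, n_events = fit$nevent)
  class(out) <- "neuroprs_cox"
  out
}

#' @export
print.neuroprs_cox <- function(x, ...) {
  cat(sprintf("<cox fit> n = %d, events = %d\n", x$n, x$n_events))
  print(x$coefficients, n = nrow(x$coefficients))
  invisible(x)
}

#' @method tidy neuroprs_cox
#' @export
tidy.neuroprs_cox <- function(x, ...) x$coefficients

#' @method glance neuroprs_cox
#' @export
glance.neuroprs_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, partial_ll = x$ll)
}

#' Cumulative conversion risk for covariate profiles
#'
#' @param cox A `neuroprs_cox` fit.
#' @param newdata Tibble of covariate profiles (columns matching the
#'   fitted terms' source columns).
#' @param times Evaluation times; defaults to the baseline event times.
#' @return Tibble with `profile` (row of `newdata`), `time`, `risk`.
#' @export
cumulative_risk <- function(cox, newdata, times = NULL) {
  lp <- drop(stats::predict(cox$fit, newdata = as.data.frame(newdata),
                            type = "lp", reference = "zero"))
  times <- times %||% cox$baseline$time
  h0 <- stats::approx(cox$baseline$time, cox$baseline$cum_hazard,
                      xout = times, method = "constant", yleft = 0,
                      rule = 2)$y
  tidyr::expand_grid(profile = seq_along(lp), i = seq_along(times)) |>
    dplyr::mutate(time = times[.data$i],
                  risk = 1 - exp(-h0[.data$i] * exp(lp[.data$profile]))) |>
    dplyr::select(-"i")
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction, as used for the cohort's group
#' comparison tables.
#'
#' @param table A 2-by-2 or 2-by-3 (generally r-by-c) count matrix with
#'   positive margins.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chisq_independence(matrix(c(53, 105, 63, 57), nrow = 2))
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) abort("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero margin: chi-square test undefined",
          class = "neuroprs_data_error")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = unname(ct$p.value))
}

#' Pooled-variance two-sample t-test
#'
#' Student's t from group summary statistics (mean, SD, n), or from raw
#' vectors via `x` and `y`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @param x,y Optional raw vectors; when given, summaries are ignored.
#' @return Tibble with `t`, `df`, `p_value`.
#' @export
#' @examples
#' two_sample_t(75.55, 7.00, 234, 73.29, 8.01, 44)
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                         x = NULL, y = NULL) {
  if (!is.null(x) || !is.null(y)) {
    stopifnot(!is.null(x), !is.null(y))
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Split samples into risk groups by score
#'
#' Median split (`k = 2`) or tertile split (`k = 3`); when `n` is not a
#' multiple of `k`, the remainder is assigned to the upper groups (so
#' n = 278 gives 139/139 and 92/93/93). Ties are broken by stable input
#' order.
#'
#' @param z_scores Numeric scores, no missing values.
#' @param k Number of groups (2 or 3 conventionally; any `k <= n`).
#' @return Ordered factor of group labels (`low` < (`middle`) < `high`,
#'   or `group1..k` for other `k`).
#' @export
#' @examples
#' table(stratify_groups(rnorm(278), 3))
stratify_groups <- function(z_scores, k) {
  n <- length(z_scores)
  if (anyNA(z_scores)) abort("scores must not be missing")
  if (n < k) abort(sprintf("n = %d is smaller than k = %d", n, k))
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[(k - rem + 1):k] <- sizes[(k - rem + 1):k] + 1
  labels <- if (k == 2) c("low", "high")
            else if (k == 3) c("low", "middle", "high")
            else paste0("group", seq_len(k))
  r <- rank(z_scores, ties.method = "first")
  factor(rep(labels, sizes)[r], levels = labels, ordered = TRUE)
}

#' Conversion-prediction analysis at the selected threshold
#'
#' Applies the score's outlier mask, then runs the prediction battery:
#' two-sample t of the score between converters and non-converters,
#' covariate-adjusted logistic regression (OR per SD, Nagelkerke
#' R-squared, AUC), Cox survival on time-to-conversion, and the
#' dichotomized / trichotomized risk-group chi-square tests.
#'
#' @param profile A `prs_profile` from [sweep_and_select()].
#' @param cohort Cohort tibble (same samples as the profile).
#' @param covariates Covariate column names.
#' @param outcome 0/1 outcome column name.
#' @param time,event Columns for the Cox fit.
#' @return A list of class `conversion_analysis`: `logistic`, `cox`,
#'   `group_t`, `dichot` / `trichot` (tables + chi-square), `data` (the
#'   masked analysis tibble).
#' @export
analyze_conversion <- function(profile, cohort,
                               covariates = standard_covariates(cohort),
                               outcome = "converted_1yr",
                               time = "time_years", event = "event") {
  dat <- dplyr::inner_join(cohort, profile$scores, by = "sample_id") |>
    dplyr::filter(.data$included)
  y <- dat[[outcome]]
  group_t <- two_sample_t(x = dat$z[y == 1], y = dat$z[y == 0])
  logit <- logistic_fit(dat, outcome, c("z", covariates))
  cox <- cox_fit(dat, time, event, c("z", covariates))
  strat <- function(k) {
    g <- stratify_groups(dat$z, k)
    tab <- table(group = g, converted = factor(y, levels = c(0, 1)))
    list(table = tab, test = chisq_independence(tab),
         rates = prop.table(tab, 1)[, "1"])
  }
  out <- list(logistic = logit, cox = cox, group_t = group_t,
              dichot = strat(2), trichot = strat(3),
              outcome = outcome, n = nrow(dat), data = dat)
  class(out) <- "conversion_analysis"
  out
}

#' @export
print.conversion_analysis <- function(x, ...) {
  cat(sprintf("<conversion analysis> outcome %s, n = %d after masking\n",
              x$outcome, x$n))
  or <- x$logistic$coefficients[x$logistic$coefficients$term == "z", ]
  cat(sprintf("  OR per SD = %.3f [%.3f, %.3f], p = %.3g\n",
              or$odds_ratio, or$or_low, or$or_high, or$p_value))
  cat(sprintf("  Nagelkerke R2 = %.4f, AUC = %.3f\n",
              x$logistic$nagelkerke, x$logistic$auc))
  cat(sprintf("  risk-group chi2: 2 groups %.3f (p = %.3g), 3 groups %.3f (p = %.3g)\n",
              x$dichot$test$statistic, x$dichot$test$p_value,
              x$trichot$test$statistic, x$trichot$test$p_value))
  invisible(x)
}
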