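#' One-sample Mendelian randomization by two-stage least squares
#'
#' Stage 1 regresses the exposure on an intercept, the instrument and
#' covariates; stage 2 regresses the outcome on the fitted exposure and
#' the same covariates. The reported coefficient is the fitted-exposure
#' term: the change in outcome per SD of exposure attributable to the
#' instrument (the exposure is standardized to unit SD first by
#' default). A binary outcome is handled as a linear-probability model.
#' Standard errors are classical: the stage-2 covariance formula is
#' evaluated with residuals recomputed from the observed exposure;
#' heteroskedasticity-robust (HC0) errors are available as an option.
#' The stage-1 instrument F (squared t) is reported and `F < 10` flags a
#' weak instrument.
#'
#' @param z Instrument (numeric vector).
#' @param x Exposure.
#' @param y Outcome (numeric or 0/1).
#' @param covariates Optional tibble / data frame of covariates.
#' @param standardize_exposure Divide the exposure by its SD so the
#'   estimate reads per SD.
#' @param robust Use HC0 sandwich standard errors instead of classical.
#' @return An object of class `mr_result` with [tidy()] / [glance()]
#'   methods; fields include `beta`, `se`, `p_value`, `stage1_beta`,
#'   `stage1_se`, `stage1_f`, `n`, `weak_instrument`.
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(400); x <- 0.5 * z + rnorm(400)
#' y <- -0.3 * x + rnorm(400)
#' tsls_fit(z, x, y)
tsls_fit <- function(z, x, y, covariates = NULL,
                     standardize_exposure = TRUE, robust = FALSE) {
  if (is.null(covariates)) covariates <- tibble::tibble(.rows = length(z))
  covariates <- tibble::as_tibble(covariates)
  ok <- !is.na(z) & !is.na(x) & !is.na(y) & complete.cases(covariates)
  z <- z[ok]; x <- x[ok]; y <- as.numeric(y[ok])
  cmat <- covariate_design(covariates[ok, , drop = FALSE],
                           names(covariates))
  n <- length(z)
  if (n <= ncol(cmat) + 2) abort("too few observations for TSLS")
  if (standardize_exposure) {
    if (sd(x) == 0) abort("exposure has zero variance")
    x <- x / sd(x)
  }
  w1 <- cbind(cmat, instrument = z)
  s1 <- lm.fit(w1, x)
  if (any(is.na(s1$coefficients))) {
    abort("stage-1 design is singular", class = "neuroprs_data_error")
  }
  p1 <- ncol(w1)
  sigma1 <- sum(s1$residuals^2) / (n - p1)
  xtx1_inv <- chol2inv(chol(crossprod(w1)))
  s1_beta <- unname(s1$coefficients["instrument"])
  s1_se <- sqrt(sigma1 * xtx1_inv[p1, p1])
  if (!is.finite(s1_se) || s1_se == 0 || abs(s1_beta) < .Machine$double.eps) {
    if (sum(lm.fit(cmat, z)$residuals^2) < 1e-12) {
      abort("instrument irrelevant: zero partial variance given covariates",
            class = "neuroprs_data_error")
    }
  }
  stage1_f <- (s1_beta / s1_se)^2
  xhat <- x - s1$residuals

  w2 <- cbind(cmat, exposure = xhat)
  p2 <- ncol(w2)
  xtx2 <- crossprod(w2)
  if (rcond(xtx2) < 1e-14) {
    abort("instrument irrelevant: fitted exposure collinear with covariates",
          class = "neuroprs_data_error")
  }
  xtx2_inv <- chol2inv(chol(xtx2))
  beta2 <- drop(xtx2_inv %*% crossprod(w2, y))
  resid <- y - drop(cbind(cmat, exposure = x) %*% beta2)
  if (robust) {
    meat <- crossprod(w2 * resid)
    vc <- xtx2_inv %*% meat %*% xtx2_inv
  } else {
    vc <- sum(resid^2) / (n - p2) * xtx2_inv
  }
  beta <- beta2[p2]
  se <- sqrt(vc[p2, p2])
  tstat <- beta / se
  out <- list(beta = unname(beta), se = unname(se),
              p_value = 2 * pt(-abs(tstat), df = n - p2),
              stage1_beta = s1_beta, stage1_se = unname(s1_se),
              stage1_f = unname(stage1_f), n = n,
              weak_instrument = stage1_f < 10, robust = robust,
              coefficients = beta2, df = n - p2)
  class(out) <- "mr_result"
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> beta = %.4f (SE %.4f, p = %.3g), n = %d\n",
              x$beta, x$se, x$p_value, x$n))
  cat(sprintf("  stage-1 beta = %.4f, F = %.1f%s\n", x$stage1_beta,
              x$stage1_f,
              if (x$weak_instrument) " [weak instrument]" else ""))
  invisible(x)
}

#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  tibble::tibble(term = "exposure", estimate = x$beta, std_error = x$se,
                 statistic = x$beta / x$se, p_value = x$p_value)
}

#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(n = x$n, stage1_beta = x$stage1_beta,
                 stage1_f = x$stage1_f,
                 weak_instrument = x$weak_instrument)
}

#' Per-region MR causal-chain report
#'
#' Runs [tsls_fit()] with the score as instrument and each listed
#' regional measure as exposure against the conversion outcome, with the
#' standard covariate set, and flags the sign pattern of the published
#' chain (negative stage-1 coefficient: higher score, smaller measure;
#' negative TSLS coefficient: larger measure, lower conversion).
#'
#' @param profile A `prs_profile` (masked z-scores are used) or a
#'   numeric score vector aligned to `cohort`.
#' @param cohort Cohort tibble.
#' @param regions Tibble with `region` and `measure` columns (e.g. the
#'   replicated set from [region_replicate()]), or a character vector of
#'   regional column names.
#' @param covariates Covariate column names.
#' @param outcome 0/1 outcome column.
#' @return Tibble: one row per region with stage-1 and TSLS estimates,
#'   `weak_instrument` and `sign_pattern` flags.
#' @export
mr_chain_report <- function(profile, cohort, regions,
                            covariates = standard_covariates(cohort),
                            outcome = "converted_1yr") {
  if (inherits(profile, "prs_profile")) {
    sc <- profile$scores[profile$scores$included, c("sample_id", "z")]
    cohort <- dplyr::inner_join(cohort, sc, by = "sample_id")
    z <- cohort$z
  } else {
    stopifnot(length(profile) == nrow(cohort))
    z <- profile
  }
  cols <- if (is.character(regions)) regions
          else if (nrow(regions)) paste0(regions$region, "_",
                                         regions$measure)
          else character(0)
  if (!length(cols)) {
    return(tibble::tibble(region_column = character(), beta = numeric(),
                          se = numeric(), p_value = numeric(),
                          stage1_beta = numeric(), stage1_f = numeric(),
                          n = integer(), weak_instrument = logical(),
                          sign_pattern = logical()))
  }
  cov_tbl <- cohort[covariates]
  purrr::map_dfr(cols, function(cl) {
    fit <- tsls_fit(z, cohort[[cl]], cohort[[outcome]], cov_tbl)
    tibble::tibble(region_column = cl, beta = fit$beta, se = fit$se,
                   p_value = fit$p_value, stage1_beta = fit$stage1_beta,
                   stage1_f = fit$stage1_f, n = fit$n,
                   weak_instrument = fit$weak_instrument,
                   sign_pattern = fit$stage1_beta < 0 & fit$beta < 0)
  })
}
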