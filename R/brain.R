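#' Covariate-adjusted (partial) Pearson correlation
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares and correlates the residuals. The p-value uses
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of
#' freedom, `k` the number of covariate design columns beyond the
#' intercept. With no covariates this is the plain Pearson correlation
#' and test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Tibble / data frame of covariates (possibly zero
#'   columns); factors are expanded to dummies.
#' @return Tibble with `r`, `p_value`, `n`, `df`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) covariates <- tibble::tibble(.rows = length(x))
  covariates <- tibble::as_tibble(covariates)
  ok <- !is.na(x) & !is.na(y) & complete.cases(covariates)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  cmat <- covariate_design(covariates[ok, , drop = FALSE],
                           names(covariates))
  k <- qr(cmat)$rank - 1
  if (n <= k + 2) abort("need n > k + 2 observations")
  rx <- lm.fit(cmat, x)$residuals
  ry <- lm.fit(cmat, y)$residuals
  if (sd(rx) <= 1e-12 * (sd(x) + 1) || sd(ry) <= 1e-12 * (sd(y) + 1)) {
    abort("zero residual variance: partial correlation undefined",
          class = "neuroprs_data_error")
  }
  r <- cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / max(1 - r^2, 1e-300))
  tibble::tibble(r = r, p_value = 2 * pt(-abs(tstat), df), n = n, df = df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR-adjusted q-values, `q_(i) = min over j >= i of
#' m p_(j) / j`, clipped at 1.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return q-values in the input order.
#' @export
fdr_bh <- function(pvals) {
  p.adjust(pvals, method = "BH")
}

region_columns <- function(cohort,
                           measures = c("surface_area", "thickness",
                                        "volume")) {
  pat <- paste0("_(", paste(measures, collapse = "|"), ")$")
  grep(pat, names(cohort), value = TRUE)
}

#' Score-versus-brain-region association scan
#'
#' Runs a covariate-adjusted Pearson correlation of the z-scored PRS
#' against every regional measure column
#' (`<region>_<surface_area|thickness|volume>`), then applies
#' Benjamini-Hochberg FDR across the chosen family.
#'
#' @param cohort Cohort tibble carrying the regional columns and
#'   covariates.
#' @param z_scores Numeric score vector aligned to `cohort` rows, or a
#'   `prs_profile` (its masked z-scores are joined by `sample_id` and
#'   excluded samples dropped).
#' @param covariates Covariate column names (default
#'   [standard_covariates()]).
#' @param fdr_family `"joint"` corrects across all region-measure tests
#'   together (the conservative default); `"per_measure"` corrects each
#'   measure type separately.
#' @param q_threshold Significance threshold on the q-value.
#' @return A `region_scan` tibble sorted by p: `region`, `measure`,
#'   `r`, `p_value`, `q_value`, `significant`; columns skipped for
#'   missing data are listed in the `skipped` attribute.
#' @export
region_scan <- function(cohort, z_scores,
                        covariates = standard_covariates(cohort),
                        fdr_family = c("joint", "per_measure"),
                        q_threshold = 0.05) {
  fdr_family <- match.arg(fdr_family)
  if (inherits(z_scores, "prs_profile")) {
    sc <- z_scores$scores[z_scores$scores$included, c("sample_id", "z")]
    cohort <- dplyr::inner_join(cohort, sc, by = "sample_id")
    z <- cohort$z
  } else {
    stopifnot(length(z_scores) == nrow(cohort))
    z <- z_scores
  }
  cols <- region_columns(cohort)
  if (!length(cols)) abort("no regional measure columns found",
                           class = "neuroprs_data_error")
  cov_tbl <- cohort[covariates]
  res <- purrr::map(cols, function(cl) {
    v <- cohort[[cl]]
    if (all(is.na(v)) || sd(v, na.rm = TRUE) == 0) return(NULL)
    pp <- partial_pearson(z, v, cov_tbl)
    meas <- stringr::str_extract(cl, "(surface_area|thickness|volume)$")
    tibble::tibble(region = sub(paste0("_", meas, "$"), "", cl),
                   measure = meas, r = pp$r, p_value = pp$p_value,
                   n = pp$n)
  })
  skipped <- cols[vapply(res, is.null, logical(1))]
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) abort("no usable regional columns",
                        class = "neuroprs_data_error")
  out <- if (fdr_family == "joint") {
    dplyr::mutate(out, q_value = fdr_bh(.data$p_value))
  } else {
    dplyr::mutate(out, q_value = fdr_bh(.data$p_value),
                  .by = "measure")
  }
  out <- out |>
    dplyr::mutate(significant = .data$q_value < q_threshold) |>
    dplyr::arrange(.data$p_value)
  attr(out, "skipped") <- skipped
  class(out) <- c("region_scan", class(out))
  out
}

#' Replication scan over a discovery-significant set
#'
#' Re-tests only the regions found significant in a discovery scan, with
#' a second score, at unadjusted p < `p_threshold` and requiring the
#' same sign of correlation.
#'
#' @param scan A `region_scan` result (the discovery scan).
#' @param cohort Cohort tibble.
#' @param z_scores Second score vector or `prs_profile`.
#' @param covariates Covariate column names.
#' @param p_threshold Unadjusted replication threshold.
#' @return Tibble of the discovery-significant set with replication `r`,
#'   `p_value` and a `replicated` flag.
#' @export
region_replicate <- function(scan, cohort, z_scores,
                             covariates = standard_covariates(cohort),
                             p_threshold = 0.05) {
  disc <- dplyr::filter(scan, .data$significant)
  if (!nrow(disc)) {
    return(tibble::tibble(region = character(), measure = character(),
                          r_discovery = numeric(), r = numeric(),
                          p_value = numeric(), replicated = logical()))
  }
  if (inherits(z_scores, "prs_profile")) {
    sc <- z_scores$scores[z_scores$scores$included, c("sample_id", "z")]
    cohort <- dplyr::inner_join(cohort, sc, by = "sample_id")
    z <- cohort$z
  } else {
    z <- z_scores
  }
  cov_tbl <- cohort[covariates]
  purrr::pmap_dfr(disc[c("region", "measure", "r")],
                  function(region, measure, r) {
    col <- paste0(region, "_", measure)
    pp <- partial_pearson(z, cohort[[col]], cov_tbl)
    tibble::tibble(region = region, measure = measure, r_discovery = r,
                   r = pp$r, p_value = pp$p_value,
                   replicated = pp$p_value < p_threshold &
                     sign(pp$r) == sign(r))
  })
}
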