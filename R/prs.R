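#' Align discovery effect sizes to a target panel
#'
#' Matches summary-statistic variants to panel variants by id and
#' harmonizes the effect sign to the panel's counted (`a1`) allele: same
#' orientation keeps the effect, swapped alleles negate it, disagreeing
#' allele sets or strand-ambiguous pairs (A/T, C/G) are dropped and
#' logged.
#'
#' @param summary A summary-statistic tibble with columns `snp`, `a1`,
#'   `a2`, `beta`, `p` (as from [simulate_discovery_summary()] or
#'   [read_gwas_summary()]).
#' @param panel A [genotype_panel()].
#' @return An `aligned_weights` tibble with `variant_id`, `col_index`
#'   (panel column), `beta` (sign-harmonized), `p`; dropped variants are
#'   recorded in the `dropped` attribute.
#' @export
align_alleles <- function(summary, panel) {
  pv <- panel$variants
  hit <- match(summary$snp, pv$variant_id)
  keep <- !is.na(hit)
  if (!any(keep)) {
    abort("no summary variants match the panel", class = "neuroprs_data_error")
  }
  s <- summary[keep, ]
  idx <- hit[keep]
  same <- s$a1 == pv$a1[idx] & s$a2 == pv$a2[idx]
  swap <- s$a1 == pv$a2[idx] & s$a2 == pv$a1[idx]
  ambig <- is_ambiguous_pair(s$a1, s$a2) | is_ambiguous_pair(pv$a1[idx],
                                                            pv$a2[idx])
  ok <- (same | swap) & !ambig
  dropped <- dplyr::bind_rows(
    summary[!keep, ] |> dplyr::mutate(drop_reason = "not_in_panel"),
    s[!ok, ] |> dplyr::mutate(drop_reason = dplyr::if_else(
      ambig[!ok], "ambiguous_strand", "allele_mismatch")))
  if (!any(ok)) {
    abort("no summary variants align to the panel after allele checks",
          class = "neuroprs_data_error")
  }
  out <- tibble::tibble(
    variant_id = s$snp[ok],
    col_index = idx[ok],
    beta = ifelse(swap[ok], -s$beta[ok], s$beta[ok]),
    p = s$p[ok]
  )
  if (nrow(dropped)) {
    inform(sprintf("align_alleles: dropped %d variant(s) (%s)",
                   nrow(dropped),
                   paste(names(table(dropped$drop_reason)),
                         table(dropped$drop_reason), sep = "=",
                         collapse = ", ")))
  }
  attr(out, "dropped") <- dropped
  class(out) <- c("aligned_weights", class(out))
  out
}

#' Composite LD between two panel variants
#'
#' Squared Pearson correlation of unphased dosage vectors over samples
#' non-missing at both variants.
#'
#' @param panel A [genotype_panel()].
#' @param j,k Variant ids or column indices.
#' @param min_n Minimum paired sample count.
#' @return r-squared in `[0, 1]`; 0 when either variant has zero variance.
#' @export
ld_r2 <- function(panel, j, k, min_n = 50) {
  g <- panel$dosage
  if (is.character(j)) j <- match(j, colnames(g))
  if (is.character(k)) k <- match(k, colnames(g))
  x <- g[, j]; y <- g[, k]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_n) {
    abort(sprintf("only %d samples non-missing at both variants (need >= %d)",
                  sum(ok), min_n), class = "neuroprs_data_error")
  }
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  unname(cor(x, y)^2)
}

#' Greedy LD clumping
#'
#' Processes variants in ascending discovery p-value (ties: ascending
#' position). Each not-yet-removed variant becomes an index variant; all
#' unprocessed variants within `window_kb` kilobases whose dosage
#' r-squared with the index exceeds `r2_threshold` are removed. Returns
#' the index variants only.
#'
#' @param weights An `aligned_weights` tibble from [align_alleles()].
#' @param panel The [genotype_panel()] providing dosages and positions.
#' @param r2_threshold Remove neighbours with r-squared strictly above
#'   this value.
#' @param window_kb Physical window half-width in kilobases.
#' @return The retained subset of `weights`, index variants only.
#' @export
clump <- function(weights, panel, r2_threshold = 0.5, window_kb = 250) {
  if (!nrow(weights)) return(weights)
  pos <- panel$variants$pos[weights$col_index]
  chrom <- panel$variants$chrom[weights$col_index]
  ord <- order(weights$p, pos)
  removed <- rep(FALSE, nrow(weights))
  processed <- rep(FALSE, nrow(weights))
  g <- panel$dosage
  window <- window_kb * 1000
  for (o in ord) {
    processed[o] <- TRUE
    if (removed[o]) next
    cand <- which(!processed & !removed & chrom == chrom[o] &
                    abs(pos - pos[o]) <= window)
    if (!length(cand)) next
    x <- g[, weights$col_index[o]]
    r <- suppressWarnings(
      cor(x, g[, weights$col_index[cand], drop = FALSE],
          use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    removed[cand[r^2 > r2_threshold]] <- TRUE
  }
  out <- weights[!removed, ]
  attr(out, "dropped") <- attr(weights, "dropped")
  class(out) <- c("aligned_weights", class(out))
  out
}

# dosage submatrix for weight variants with missing entries imputed to
# 2 * counted-allele frequency among non-missing samples
imputed_dosage <- function(panel, weights) {
  g <- panel$dosage[, weights$col_index, drop = FALSE]
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  g
}

#' Raw polygenic score at a p-value threshold
#'
#' `PRS_i = sum over j with p_j <= p_T of G_ij * beta_j`, with missing
#' dosages replaced by twice the counted-allele frequency among
#' non-missing samples.
#'
#' @param panel A [genotype_panel()].
#' @param weights Clumped `aligned_weights`.
#' @param p_T Discovery p-value inclusion threshold.
#' @return Tibble with `sample_id` and raw `score`; the number of
#'   included variants is in the `n_variants` attribute.
#' @export
prs_score <- function(panel, weights, p_T = 1) {
  sel <- weights$p <= p_T
  if (!any(sel)) {
    warn(sprintf("no variant passes p_T = %g; scores are all zero", p_T))
    out <- tibble::tibble(sample_id = rownames(panel$dosage), score = 0)
    attr(out, "n_variants") <- 0L
    return(out)
  }
  w <- weights[sel, ]
  g <- imputed_dosage(panel, w)
  out <- tibble::tibble(sample_id = rownames(panel$dosage),
                        score = unname(drop(g %*% w$beta)))
  attr(out, "n_variants") <- nrow(w)
  out
}

# Plain IRLS logistic fit on a design matrix; returns coefficients and
# the 0/1-outcome log-likelihood (saturated ll = 0, so ll = -deviance/2).
irls_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  beta <- numeric(ncol(x))
  eta <- drop(x %*% beta)
  for (it in seq_len(max_iter)) {
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- lm.wfit(x, z, w)
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(x %*% beta)
    if (step < tol) break
  }
  mu <- plogis(eta)
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(coef = beta, ll = ll, converged = step < tol || max_iter == 0,
       separated = any(abs(beta) > 30), eta = eta)
}

#' Default covariate set
#'
#' The covariate columns the published analysis adjusted for, restricted
#' to those present: sex, age, site, education years, APOE e4 count and
#' the first four genotype principal components.
#'
#' @param cohort A cohort tibble.
#' @return Character vector of column names.
#' @export
standard_covariates <- function(cohort) {
  intersect(c("sex_reported", "age", "site", "education_years", "apoe4",
              paste0("PC", 1:4)), names(cohort))
}

covariate_design <- function(cohort, covariates) {
  if (!length(covariates)) {
    return(matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- as.data.frame(cohort[covariates])
  stats::model.matrix(~ ., data = df)
}

#' Threshold sweep and best-threshold selection
#'
#' For each threshold on the grid, scores the cohort with the variants at
#' discovery p <= p_T, z-scores the PRS, fits a covariate-adjusted
#' logistic regression of conversion on it, and records the Nagelkerke
#' pseudo-R-squared of the PRS term over the covariate-only baseline. The
#' best threshold maximizes R-squared (ties toward the smaller, sparser
#' threshold). The best score is then z-transformed and samples outside
#' mean +/- 2 SD of the scaled score are masked (scale first, then trim).
#'
#' Thresholds sharing an identical included-variant set reuse one score
#' and one fit.
#'
#' @param panel A [genotype_panel()].
#' @param weights Clumped `aligned_weights`.
#' @param cohort Cohort tibble with the outcome and covariate columns,
#'   rows aligned to the panel samples by `sample_id`.
#' @param covariates Character vector of covariate column names
#'   (default [standard_covariates()]).
#' @param grid Threshold grid; default `seq(0.001, 1, by = 0.001)`
#'   (1000 thresholds).
#' @param outcome Name of the 0/1 outcome column.
#' @param trim_sd Outlier mask half-width on the scaled best score.
#' @return A `prs_profile` object: `$grid` (tibble `p_T`, `n_variants`,
#'   `r2`, `beta`, `p`), `$best_p_T`, `$best_r2`, `$scores` (tibble
#'   `sample_id`, `raw`, `z`, `included`), plus fitting internals reused
#'   by [permutation_correct()].
#' @export
sweep_and_select <- function(panel, weights, cohort,
                             covariates = standard_covariates(cohort),
                             grid = seq(0.001, 1, by = 0.001),
                             outcome = "converted_1yr",
                             trim_sd = 2) {
  stopifnot(nrow(cohort) == nrow(panel$dosage))
  cohort <- cohort[match(rownames(panel$dosage), cohort$sample_id), ]
  y <- cohort[[outcome]]
  if (any(is.na(y))) abort("outcome contains missing values")
  w <- weights[order(weights$p, panel$variants$pos[weights$col_index]), ]
  g <- imputed_dosage(panel, w)
  contrib <- sweep(g, 2, w$beta, `*`)
  cum_scores <- t(apply(contrib, 1, cumsum))

  k_at <- findInterval(grid, w$p)  # variants included at each threshold
  uk <- sort(unique(k_at[k_at > 0]))
  x_cov <- covariate_design(cohort, covariates)
  base <- irls_logistic(x_cov, y)
  n <- length(y)

  fit_k <- function(k, yy, ll_base) {
    sc <- cum_scores[, k]
    if (sd(sc) == 0) return(c(r2 = NA_real_, beta = NA_real_, p = NA_real_))
    z <- as.numeric(scale(sc))
    fit <- irls_logistic(cbind(PRS = z, x_cov), yy)
    if (!fit$converged) return(c(r2 = NA_real_, beta = NA_real_,
                                 p = NA_real_))
    lr <- 2 * (fit$ll - ll_base)
    c(r2 = nagelkerke_r2(ll_base, fit$ll, n), beta = fit$coef[1],
      p = pchisq(max(lr, 0), df = 1, lower.tail = FALSE))
  }
  uk_stats <- vapply(uk, fit_k, c(r2 = 0, beta = 0, p = 0), yy = y,
                     ll_base = base$ll)
  uk_stats <- matrix(uk_stats, nrow = 3,
                     dimnames = list(c("r2", "beta", "p"), NULL))
  skipped <- uk[is.na(uk_stats["r2", ])]
  if (length(skipped)) {
    inform(sprintf("sweep: %d threshold set(s) skipped (degenerate or non-convergent)",
                   length(skipped)))
  }
  stat_of <- function(row) {
    out <- rep(NA_real_, length(grid))
    out[k_at > 0] <- uk_stats[row, match(k_at[k_at > 0], uk)]
    out
  }
  grid_tbl <- tibble::tibble(p_T = grid, n_variants = k_at,
                             r2 = stat_of("r2"), beta = stat_of("beta"),
                             p = stat_of("p"))
  if (all(is.na(grid_tbl$r2))) {
    abort("no threshold produced a usable fit", class = "neuroprs_data_error")
  }
  best_i <- which(grid_tbl$r2 == max(grid_tbl$r2, na.rm = TRUE))[1]
  best_k <- grid_tbl$n_variants[best_i]
  raw <- cum_scores[, best_k]
  z <- as.numeric(scale(raw))
  included <- abs(z - mean(z)) <= trim_sd * sd(z)
  profile <- list(
    grid = grid_tbl,
    best_p_T = grid_tbl$p_T[best_i],
    best_r2 = grid_tbl$r2[best_i],
    best_n_variants = best_k,
    scores = tibble::tibble(sample_id = cohort$sample_id, raw = raw,
                            z = z, included = included),
    outcome = outcome, covariates = covariates, trim_sd = trim_sd,
    n = n, ll_base = base$ll,
    cache = list(cum_scores = cum_scores, uk = uk, x_cov = x_cov, y = y)
  )
  class(profile) <- "prs_profile"
  profile
}

#' @export
print.prs_profile <- function(x, ...) {
  cat("<prs_profile>\n")
  cat(sprintf("  best p_T = %g (%d variants), Nagelkerke R2 = %.4f\n",
              x$best_p_T, x$best_n_variants, x$best_r2))
  cat(sprintf("  %d / %d samples inside the +/- %g SD mask\n",
              sum(x$scores$included), x$n, x$trim_sd))
  if (!is.null(x$perm_p)) {
    cat(sprintf("  permutation-corrected p = %.4g (%d permutations)\n",
                x$perm_p, x$n_perm))
  }
  invisible(x)
}

#' Permutation correction for best-threshold selection
#'
#' Permutes the outcome vector, re-runs the full threshold sweep on each
#' permutation (scores and covariates fixed), and compares the permuted
#' best R-squared values with the observed one:
#' `p = (1 + #\{perm best R2 >= observed\}) / (1 + n_perm)`.
#'
#' @param profile A `prs_profile` from [sweep_and_select()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @return The profile with `perm_p`, `n_perm` and the permuted maxima
#'   (`perm_best_r2`) attached.
#' @export
permutation_correct <- function(profile, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(profile, "prs_profile"))
  if (!is.numeric(n_perm) || n_perm < 100) {
    abort("n_perm must be at least 100", class = "neuroprs_config_error")
  }
  set_seed_if(seed)
  cache <- profile$cache
  n <- profile$n
  z_k <- lapply(cache$uk, function(k) {
    sc <- cache$cum_scores[, k]
    if (sd(sc) == 0) NULL else as.numeric(scale(sc))
  })
  best_perm <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(cache$y)
    ll_base <- irls_logistic(cache$x_cov, yp)$ll
    r2 <- vapply(z_k, function(z) {
      if (is.null(z)) return(NA_real_)
      fit <- irls_logistic(cbind(PRS = z, cache$x_cov), yp)
      if (!fit$converged) return(NA_real_)
      nagelkerke_r2(ll_base, fit$ll, n)
    }, numeric(1))
    if (all(is.na(r2))) NA_real_ else max(r2, na.rm = TRUE)
  }, numeric(1))
  profile$perm_best_r2 <- best_perm
  profile$n_perm <- n_perm
  profile$perm_p <- (1 + sum(best_perm >= profile$best_r2, na.rm = TRUE)) /
    (1 + n_perm)
  profile
}
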