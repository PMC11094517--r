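#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test for deviation from Hardy-Weinberg proportions
#' at a biallelic variant. Conditional on the observed allele counts, the
#' p-value is the total probability of heterozygote counts (necessarily
#' of the same parity) whose conditional probability does not exceed that
#' of the observed count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return The exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(100, 0, 100)  # extreme heterozygote deficit
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) abort("all genotype counts are zero: HWE test undefined")
  n_a1 <- 2 * n_AA + n_Aa
  n_a2 <- 2 * n_aa + n_Aa
  if (n_a1 == 0 || n_a2 == 0) return(1)  # monomorphic: single configuration
  hets <- seq(n_a1 %% 2, min(n_a1, n_a2), by = 2)
  # log P(h) up to a constant: -log((nA-h)/2)! - log h! - log((na-h)/2)! + h log 2
  logp <- -lgamma((n_a1 - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_a2 - hets) / 2 + 1) + hets * log(2)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_Aa, hets)]
  min(sum(prob[prob <= obs * (1 + 1e-12)]), 1)
}

#' Chi-square Hardy-Weinberg test
#'
#' One-degree-of-freedom goodness-of-fit alternative to
#' [hwe_exact_test()], provided for comparison with pipelines that used
#' the asymptotic test.
#'
#' @inheritParams hwe_exact_test
#' @return Asymptotic p-value.
#' @export
hwe_chisq_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n == 0) abort("all genotype counts are zero: HWE test undefined")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  unname(pchisq(stat, df = 1, lower.tail = FALSE))
}

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Quality-control thresholds
#'
#' Presets mirror the two cohorts' published filters: the ADNI-style
#' preset removes variants with call rate < 0.95, MAF < 0.01, exact HWE
#' p < 5e-7 or ambiguous strand, and samples with reported/genetic sex
#' mismatch, PI_HAT > 0.1875, heterozygosity outside mean +/- 5 SD, or
#' call rate < 0.97. The UKBB-style preset relaxes the MAF bound to
#' 0.001.
#'
#' @param preset `"adni"` or `"ukbb"`.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(preset = c("adni", "ukbb")) {
  preset <- match.arg(preset)
  list(
    variant_call_rate = 0.95,
    maf = if (preset == "adni") 0.01 else 0.001,
    hwe_p = 5e-7,
    drop_ambiguous = TRUE,
    sample_call_rate = 0.97,
    het_sd = 5,
    pi_hat = 0.1875
  )
}

#' Per-variant QC metrics
#'
#' @param panel A [genotype_panel()].
#' @return Tibble with `variant_id`, `chrom`, `pos`, `a1`, `a2`,
#'   `call_rate`, `maf`, `hwe_p`, `ambiguous`.
#' @export
variant_qc_table <- function(panel) {
  g <- panel$dosage
  n <- nrow(g)
  call_rate <- colSums(!is.na(g)) / n
  afreq <- colMeans(g, na.rm = TRUE) / 2
  afreq[is.nan(afreq)] <- 0
  maf <- pmin(afreq, 1 - afreq)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_test(sum(x == 2), sum(x == 1), sum(x == 0))
  }, numeric(1))
  dplyr::mutate(panel$variants[c("variant_id", "chrom", "pos", "a1", "a2")],
                call_rate = unname(call_rate), maf = unname(maf),
                hwe_p = hwe_p,
                ambiguous = is_ambiguous_pair(.data$a1, .data$a2))
}

#' Variant-level quality-control filter
#'
#' Removes variants failing call-rate, minor-allele-frequency, exact-HWE
#' or strand-ambiguity filters.
#'
#' @param panel A [genotype_panel()].
#' @param thresholds As from [qc_thresholds()].
#' @return List with the filtered `panel` and a `report` tibble (per
#'   variant: metrics, `pass`, `reason`).
#' @export
filter_variants <- function(panel, thresholds = qc_thresholds("adni")) {
  report <- variant_qc_table(panel)
  reason <- rep(NA_character_, nrow(report))
  reason[report$ambiguous & isTRUE(thresholds$drop_ambiguous)] <- "ambiguous_strand"
  reason[is.na(reason) & report$hwe_p < thresholds$hwe_p] <- "hwe"
  reason[is.na(reason) & report$maf < thresholds$maf] <- "maf"
  reason[is.na(reason) & report$call_rate < thresholds$variant_call_rate] <- "call_rate"
  report$pass <- is.na(reason)
  report$reason <- reason
  keep <- which(report$pass)
  if (!length(keep)) {
    abort("no variants survive variant-level QC", class = "neuroprs_data_error")
  }
  panel <- genotype_panel(panel$dosage[, keep, drop = FALSE],
                          panel$variants[keep, ])
  list(panel = panel, report = report)
}

# Per-pair expected IBS-category sums given unrelated/one-shared/two-shared
# chromosomes, from allele frequencies.
ibs_expectation_sums <- function(p) {
  q <- 1 - p
  list(e0_ibd0 = sum(2 * p^2 * q^2),
       e1_ibd0 = sum(4 * p^3 * q + 4 * p * q^3),
       e2_ibd0 = sum(p^4 + q^4 + 4 * p^2 * q^2),
       e1_ibd1 = sum(2 * p * q),
       e2_ibd1 = sum(1 - 2 * p * q),
       m = length(p))
}

pi_hat_from_counts <- function(n0, n1, n2, ex, overlap) {
  scale <- ex$m / overlap
  z0 <- (n0 * scale) / ex$e0_ibd0
  z1 <- (n1 * scale - z0 * ex$e1_ibd0) / ex$e1_ibd1
  z2 <- (n2 * scale - z0 * ex$e2_ibd0 - z1 * ex$e2_ibd1) / ex$m
  z <- pmin(pmax(cbind(z0, z1, z2), 0), 1)
  z <- z / rowSums(z)
  unname(z[, 3] + z[, 2] / 2)
}

#' Method-of-moments relatedness (PI_HAT) for one sample pair
#'
#' Estimates the proportion of the genome shared identical-by-descent
#' from identity-by-state counts and allele frequencies: P(IBD = 0, 1, 2)
#' are solved by moments, clamped to `[0, 1]` and renormalized, and
#' `PI_HAT = P(IBD = 2) + P(IBD = 1) / 2`.
#'
#' @param panel A [genotype_panel()].
#' @param i,j Sample ids or row indices.
#' @param min_overlap Minimum count of variants non-missing in both.
#' @return PI_HAT in `[0, 1]`.
#' @export
estimate_pi_hat <- function(panel, i, j, min_overlap = 200) {
  g <- panel$dosage
  if (is.character(i)) i <- match(i, rownames(g))
  if (is.character(j)) j <- match(j, rownames(g))
  xi <- g[i, ]; xj <- g[j, ]
  ok <- !is.na(xi) & !is.na(xj)
  if (sum(ok) < min_overlap) {
    abort(sprintf("only %d overlapping non-missing variants (need >= %d)",
                  sum(ok), min_overlap), class = "neuroprs_data_error")
  }
  xi <- xi[ok]; xj <- xj[ok]
  p <- colMeans(g, na.rm = TRUE)[ok] / 2
  keep <- p > 0 & p < 1
  xi <- xi[keep]; xj <- xj[keep]; p <- p[keep]
  d <- abs(xi - xj)
  ex <- ibs_expectation_sums(p)
  pi_hat_from_counts(sum(d == 2), sum(d == 1), sum(d == 0), ex, length(p))
}

#' All-pairs PI_HAT matrix
#'
#' Vectorized method-of-moments relatedness over every sample pair, using
#' indicator-matrix cross-products for the IBS counts. Expected IBS sums
#' are computed over all variants and rescaled by each pair's non-missing
#' overlap fraction (exact when there is no missingness).
#'
#' @param panel A [genotype_panel()].
#' @return Symmetric numeric matrix with `NA` on the diagonal.
#' @export
pi_hat_matrix <- function(panel) {
  g <- panel$dosage
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  miss <- is.na(g)
  a0 <- (g == 0); a0[miss] <- FALSE
  a1 <- (g == 1); a1[miss] <- FALSE
  a2 <- (g == 2); a2[miss] <- FALSE
  storage.mode(a0) <- storage.mode(a1) <- storage.mode(a2) <- "double"
  obs <- 1 - miss
  storage.mode(obs) <- "double"
  n0 <- tcrossprod(a0, a2); n0 <- n0 + t(n0)
  ibs2 <- tcrossprod(a0) + tcrossprod(a1) + tcrossprod(a2)
  overlap <- tcrossprod(obs)
  n1 <- overlap - n0 - ibs2
  ex <- ibs_expectation_sums(p)
  ns <- nrow(g)
  out <- matrix(NA_real_, ns, ns, dimnames = list(rownames(g), rownames(g)))
  idx <- which(upper.tri(overlap) & overlap > 0)
  out[idx] <- pi_hat_from_counts(n0[idx], n1[idx], ibs2[idx], ex,
                                 overlap[idx])
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Greedy LD pruning of a panel
#'
#' Walks variants in position order, keeping a variant only if its
#' dosage r-squared with every already-kept variant inside the physical
#' window stays at or below the threshold. Used before the relatedness
#' scan: the method-of-moments IBD estimator assumes (near-)independent
#' markers, so correlated markers inflate its variance.
#'
#' @param panel A [genotype_panel()].
#' @param r2_threshold Maximum allowed r-squared between kept variants.
#' @param window_kb Physical window in kilobases.
#' @return The pruned [genotype_panel()].
#' @export
ld_prune <- function(panel, r2_threshold = 0.2, window_kb = 250) {
  v <- panel$variants
  ord <- order(v$chrom, v$pos)
  g <- panel$dosage
  window <- window_kb * 1000
  kept <- integer()
  for (j in ord) {
    near <- kept[v$chrom[kept] == v$chrom[j] &
                   abs(v$pos[kept] - v$pos[j]) <= window]
    if (length(near)) {
      r <- suppressWarnings(
        cor(g[, j], g[, near, drop = FALSE],
            use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      if (any(r^2 > r2_threshold)) next
    }
    kept <- c(kept, j)
  }
  kept <- sort(kept)
  genotype_panel(g[, kept, drop = FALSE], v[kept, ])
}

#' Sample-level quality-control filter
#'
#' Removes samples with reported/genetic sex mismatch, call rate below
#' threshold, heterozygosity outside mean +/- `het_sd` SD, and one member
#' of each pair with PI_HAT above threshold (the member with the lower
#' call rate; ties broken by lexicographic id). Reasons are assigned in
#' that precedence order, each computed on the survivors of the previous
#' step, so removal counts reconcile: input = output + per-reason counts.
#'
#' @param panel A [genotype_panel()] (post variant QC).
#' @param cohort Cohort tibble carrying `sample_id`, `sex_reported` and
#'   `sex_genetic` columns (or `NULL` to skip the sex check).
#' @param thresholds As from [qc_thresholds()].
#' @return List with filtered `panel`, filtered `cohort`, and a `report`
#'   tibble (per input sample: metrics, `removed`, `reason`).
#' @export
filter_samples <- function(panel, cohort = NULL,
                           thresholds = qc_thresholds("adni")) {
  g <- panel$dosage
  ids <- rownames(g)
  call_rate <- rowSums(!is.na(g)) / ncol(g)
  het_rate <- rowSums(g == 1, na.rm = TRUE) / rowSums(!is.na(g))
  report <- tibble::tibble(sample_id = ids, call_rate = unname(call_rate),
                           het_rate = unname(het_rate),
                           max_pi_hat = NA_real_,
                           removed = FALSE, reason = NA_character_)
  mark <- function(report, which_ids, why) {
    hit <- report$sample_id %in% which_ids & !report$removed
    report$removed[hit] <- TRUE
    report$reason[hit] <- why
    report
  }
  if (!is.null(cohort) && all(c("sex_reported", "sex_genetic") %in%
                              names(cohort))) {
    cx <- cohort[match(ids, cohort$sample_id), ]
    bad <- ids[!is.na(cx$sex_genetic) & cx$sex_genetic != "unknown" &
                 cx$sex_reported != cx$sex_genetic]
    report <- mark(report, bad, "sex_mismatch")
  }
  alive <- function() report$sample_id[!report$removed]
  report <- mark(report, ids[call_rate < thresholds$sample_call_rate &
                               ids %in% alive()], "call_rate")
  surv <- alive()
  hr <- het_rate[match(surv, ids)]
  mu <- mean(hr); s <- sd(hr)
  if (is.finite(s) && s > 0) {
    bad <- surv[abs(hr - mu) > thresholds$het_sd * s]
    report <- mark(report, bad, "heterozygosity")
  }
  surv <- alive()
  if (length(surv) > 1) {
    pruned <- ld_prune(genotype_panel(g[surv, , drop = FALSE],
                                      panel$variants))
    if (ncol(pruned$dosage) < 200) {
      pruned <- genotype_panel(g[surv, , drop = FALSE], panel$variants)
    }
    ph <- pi_hat_matrix(pruned)
    report$max_pi_hat[match(surv, report$sample_id)] <-
      apply(ph, 1, max, na.rm = TRUE)
    pairs <- which(upper.tri(ph) & ph > thresholds$pi_hat, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(ph[pairs], decreasing = TRUE)
      pairs <- pairs[ord, , drop = FALSE]
      dropped <- character()
      for (r in seq_len(nrow(pairs))) {
        id_a <- surv[pairs[r, 1]]; id_b <- surv[pairs[r, 2]]
        if (id_a %in% dropped || id_b %in% dropped) next
        cr_a <- call_rate[match(id_a, ids)]
        cr_b <- call_rate[match(id_b, ids)]
        drop_id <- if (cr_a < cr_b) id_a
                   else if (cr_b < cr_a) id_b
                   else max(id_a, id_b)
        dropped <- c(dropped, drop_id)
      }
      report <- mark(report, dropped, "relatedness")
      if (length(dropped) > 0.1 * length(surv)) {
        warn(sprintf(paste(
          "relatedness filter removed %d of %d samples; with few",
          "(near-)independent markers PI_HAT is noisy near the %.4f",
          "threshold - consider a larger marker panel"),
          length(dropped), length(surv), thresholds$pi_hat))
      }
    }
  }
  keep <- !report$removed
  out_panel <- genotype_panel(g[report$sample_id[keep], , drop = FALSE],
                              panel$variants)
  out_cohort <- if (is.null(cohort)) NULL else
    cohort[match(report$sample_id[keep], cohort$sample_id), ]
  list(panel = out_panel, cohort = out_cohort, report = report)
}

#' Genotype principal components
#'
#' Standardizes each variant's dosage to mean 0 / variance 1
#' (mean-imputing missing calls), takes the singular value decomposition,
#' and returns the top-`k` per-sample coordinates. Sign convention: the
#' largest-magnitude variant loading of each component is positive.
#'
#' @param panel A [genotype_panel()].
#' @param k Number of components (`k >= 0`; `k = 0` returns ids only).
#' @return Tibble with `sample_id` and columns `PC1 ... PCk`.
#' @export
compute_pcs <- function(panel, k = 4) {
  g <- panel$dosage
  if (k > min(dim(g))) {
    abort(sprintf("k = %d exceeds min(samples, variants) = %d", k,
                  min(dim(g))))
  }
  out <- tibble::tibble(sample_id = rownames(g))
  if (k == 0) return(out)
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  g <- scale(g)
  g[, attr(g, "scaled:scale") == 0] <- 0
  sv <- svd(g, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (c in seq_len(k)) {
    lead <- which.max(abs(sv$v[, c]))
    if (sv$v[lead, c] < 0) scores[, c] <- -scores[, c]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(out, tibble::as_tibble(scores))
}

#' Flag principal-component outliers
#'
#' @param pcs Tibble from [compute_pcs()].
#' @param sd_limit Flag samples beyond this many SD on any component.
#' @param n_components How many leading components to inspect.
#' @return The input tibble with a logical `pc_outlier` column.
#' @export
flag_pc_outliers <- function(pcs, sd_limit = 6, n_components = 4) {
  cols <- intersect(paste0("PC", seq_len(n_components)), names(pcs))
  z <- scale(as.matrix(pcs[cols]))
  pcs$pc_outlier <- if (length(cols)) rowSums(abs(z) > sd_limit) > 0
                    else FALSE
  pcs
}
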