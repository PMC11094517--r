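# Shared fixtures and independent oracles. Fixtures are generated in code
# under fixed seeds; the medium study is memoized because several files
# exercise the same chain.

fixture_env <- new.env(parent = emptyenv())

# medium LD-blocked study used across module tests
fixture_study <- function() {
  if (is.null(fixture_env$study)) {
    cfg <- sim_config(n_target = 250, n_discovery = 3000,
                      n_variants = 6000, n_blocks = 200, n_causal = 40,
                      seed = 42)
    fixture_env$study <- simulate_study(cfg)
    fixture_env$cfg <- cfg
  }
  fixture_env$study
}

fixture_cfg <- function() {
  fixture_study()
  fixture_env$cfg
}

# QC'd panel + cohort with PCs, derived once from the medium study
fixture_qc <- function() {
  if (is.null(fixture_env$qc)) {
    study <- fixture_study()
    thr <- qc_thresholds("adni")
    vq <- filter_variants(study$panel, thr)
    sq <- suppressWarnings(filter_samples(vq$panel, study$cohort, thr))
    pcs <- compute_pcs(sq$panel, 4)
    cohort <- dplyr::left_join(sq$cohort, pcs, by = "sample_id")
    fixture_env$qc <- list(panel = sq$panel, cohort = cohort)
  }
  fixture_env$qc
}

# small random panel without any structure
random_panel <- function(n, m, seed, missing_rate = 0,
                         positions = seq_len(m) * 10000L) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  g <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (missing_rate > 0) g[runif(length(g)) < missing_rate] <- NA_real_
  rownames(g) <- sprintf("s%03d", seq_len(n))
  colnames(g) <- sprintf("v%03d", seq_len(m))
  genotype_panel(g, tibble::tibble(
    variant_id = colnames(g), chrom = "1", pos = positions,
    a1 = "A", a2 = "C", freq = p))
}

# aligned + clumped weights and the full threshold sweep on the medium
# study; memoized for reuse
sweep_fixture <- function() {
  if (is.null(fixture_env$sweep)) {
    qc <- fixture_qc()
    study <- fixture_study()
    aligned <- suppressMessages(align_alleles(study$summary, qc$panel))
    clumped <- clump(aligned, qc$panel)
    fixture_env$sweep <- list(
      clumped = clumped,
      profile = sweep_and_select(qc$panel, clumped, qc$cohort))
  }
  fixture_env$sweep
}

# ---- independent oracles -------------------------------------------------

# Exact HWE p-value by direct evaluation of the absolute conditional
# probabilities (closed-form hypergeometric-type formula), no
# normalization trick shared with the implementation.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a1 <- 2 * n_AA + n_Aa
  n_a2 <- 2 * n_aa + n_Aa
  if (n_a1 == 0 || n_a2 == 0) return(1)
  hets <- seq(n_a1 %% 2, min(n_a1, n_a2), by = 2)
  prob <- vapply(hets, function(h) {
    naa <- (n_a1 - h) / 2
    nbb <- (n_a2 - h) / 2
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
          h * log(2) + lfactorial(n_a1) + lfactorial(n_a2) -
          lfactorial(2 * n))
  }, numeric(1))
  obs <- prob[hets == n_Aa]
  min(sum(prob[prob <= obs * (1 + 1e-12)]), 1)
}

# Brute-force greedy clumping on raw vectors, written from the rule text:
# ascending p (ties: position), each surviving variant indexes and kills
# in-window unprocessed variants with r^2 above threshold.
clump_oracle <- function(dosage, pos, pval, r2_threshold, window_bp) {
  m <- length(pval)
  ord <- order(pval, pos)
  dead <- rep(FALSE, m)
  seen <- rep(FALSE, m)
  keep <- integer()
  for (i in ord) {
    seen[i] <- TRUE
    if (dead[i]) next
    keep <- c(keep, i)
    for (j in seq_len(m)) {
      if (seen[j] || dead[j]) next
      if (abs(pos[j] - pos[i]) > window_bp) next
      r <- suppressWarnings(cor(dosage[, i], dosage[, j],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_threshold) dead[j] <- TRUE
    }
  }
  sort(keep)
}

# PRS by explicit double loop with the same missing-data rule
score_oracle <- function(dosage, beta, pvals, p_T) {
  n <- nrow(dosage)
  out <- numeric(n)
  use <- which(pvals <= p_T)
  freq <- vapply(seq_len(ncol(dosage)), function(j) {
    mean(dosage[, j], na.rm = TRUE) / 2
  }, numeric(1))
  for (i in seq_len(n)) {
    acc <- 0
    for (j in use) {
      gij <- dosage[i, j]
      if (is.na(gij)) gij <- 2 * freq[j]
      acc <- acc + gij * beta[j]
    }
    out[i] <- acc
  }
  out
}

# partial correlation via inversion of the joint correlation matrix
partial_cor_oracle <- function(x, y, C) {
  m <- cbind(x = x, y = y, as.matrix(C))
  om <- solve(cor(m))
  -om["x", "y"] / sqrt(om["x", "x"] * om["y", "y"])
}

# AUC by exhaustive pair counting
auc_oracle <- function(scores, y) {
  cases <- scores[y == 1]; controls <- scores[y == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}
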