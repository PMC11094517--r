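#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic discovery-GWAS + target-cohort
#' generator into a validated list. Defaults describe a desk-scale study:
#' an aMCI-like target cohort of ~300 genotyped patients, a discovery GWAS
#' of 5,000 individuals for a continuous neuroticism-like trait, and a
#' mediation structure in which the true polygenic signal lowers one
#' designated regional surface area which in turn raises conversion risk.
#'
#' Genotypes are biallelic SNVs on one synthetic chromosome with fixed
#' 10 kb spacing, arranged in LD blocks: within a block, each haplotype
#' allele copies its left neighbour with probability `ld_copy_prob`
#' (first-order Markov chain), so adjacent-variant r2 is about
#' `ld_copy_prob^2` at equal allele frequencies and decays geometrically
#' with index distance. Across blocks variants are independent.
#'
#' @param n_target Target-cohort sample count.
#' @param n_discovery Discovery-GWAS sample count (>= 50).
#' @param n_variants Variant count.
#' @param n_blocks Number of LD blocks (variants split contiguously).
#' @param maf_range Length-2 numeric in (0, 0.5]; per-variant base allele
#'   frequencies are drawn uniformly in this range.
#' @param ld_copy_prob Probability in `[0, 1)` that an adjacent haplotype
#'   allele copies its neighbour within a block.
#' @param n_causal Number of causal variants (<= `n_variants`).
#' @param h2 Liability-scale heritability of the discovery phenotype in
#'   `[0, 1]`; residual variance is `1 - h2`.
#' @param gamma_med Effect (per SD of the true score, with a negative sign
#'   applied internally) on the standardized mediator region measure.
#' @param beta_med_out Log-odds effect of the standardized mediator on
#'   1-year conversion.
#' @param beta_direct Log-odds direct effect of the true score on 1-year
#'   conversion.
#' @param base_rate Baseline 1-year conversion probability in (0, 1).
#' @param n_regions Number of brain regions; the cohort table carries
#'   `n_regions` surface-area, thickness and volume columns.
#' @param base_missing_rate Per-entry genotype missingness rate in the
#'   clean panel (QC-style missingness is injected separately by
#'   [inject_qc_violations()]).
#' @param qc_violation_rates Named list of per-filter injection
#'   probabilities (`sex_flip`, `duplicate`, `first_degree`,
#'   `het_inflate`, `missing`), each in `[0, 0.5]`.
#' @param seed Integer seed; stage functions draw from it unless given an
#'   explicit `seed` argument.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_target = 100, n_variants = 200, seed = 1)
#' cfg$n_blocks
sim_config <- function(n_target = 304,
                       n_discovery = 5000,
                       n_variants = 8000,
                       n_blocks = 160,
                       maf_range = c(0.05, 0.5),
                       ld_copy_prob = 0.8,
                       n_causal = 50,
                       h2 = 0.3,
                       gamma_med = 0.5,
                       beta_med_out = -0.9,
                       beta_direct = 0.45,
                       base_rate = 0.15,
                       n_regions = 130,
                       base_missing_rate = 0,
                       qc_violation_rates = list(sex_flip = 0, duplicate = 0,
                                                 first_degree = 0,
                                                 het_inflate = 0, missing = 0),
                       seed = NULL) {
  cfg <- list(n_target = n_target, n_discovery = n_discovery,
              n_variants = n_variants, n_blocks = n_blocks,
              maf_range = maf_range, ld_copy_prob = ld_copy_prob,
              n_causal = n_causal, h2 = h2, gamma_med = gamma_med,
              beta_med_out = beta_med_out, beta_direct = beta_direct,
              base_rate = base_rate, n_regions = n_regions,
              base_missing_rate = base_missing_rate,
              qc_violation_rates = qc_violation_rates, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    abort(sprintf("invalid sim_config field `%s`: %s", field, msg),
          class = "neuroprs_config_error")
  }
  chk_count <- function(field, min = 1) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != round(x)) {
      stop_cfg(field, sprintf("must be a single integer >= %d", min))
    }
  }
  chk_count("n_target"); chk_count("n_discovery"); chk_count("n_variants")
  chk_count("n_blocks"); chk_count("n_causal", min = 0)
  chk_count("n_regions")
  if (cfg$n_causal > cfg$n_variants) {
    stop_cfg("n_causal", "must be <= n_variants")
  }
  if (cfg$n_blocks > cfg$n_variants) {
    stop_cfg("n_blocks", "must be <= n_variants")
  }
  mr <- cfg$maf_range
  if (!is.numeric(mr) || length(mr) != 2 || any(is.na(mr)) ||
      mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2]) {
    stop_cfg("maf_range", "must be an increasing pair in (0, 0.5]")
  }
  chk_prob <- function(field, lo = 0, hi = 1, open_hi = FALSE) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi ||
        (open_hi && x == hi)) {
      stop_cfg(field, sprintf("must be in [%g, %g%s", lo, hi,
                              if (open_hi) ")" else "]"))
    }
  }
  chk_prob("ld_copy_prob", open_hi = TRUE)
  chk_prob("h2")
  chk_prob("base_missing_rate", hi = 0.5)
  if (!is.numeric(cfg$base_rate) || length(cfg$base_rate) != 1 ||
      is.na(cfg$base_rate) || cfg$base_rate <= 0 || cfg$base_rate >= 1) {
    stop_cfg("base_rate", "must be in (0, 1)")
  }
  for (field in c("gamma_med", "beta_med_out", "beta_direct")) {
    if (!is.numeric(cfg[[field]]) || length(cfg[[field]]) != 1 ||
        is.na(cfg[[field]])) {
      stop_cfg(field, "must be a single finite number")
    }
  }
  qr <- cfg$qc_violation_rates
  if (!is.list(qr)) stop_cfg("qc_violation_rates", "must be a named list")
  for (nm in names(qr)) {
    if (!is.numeric(qr[[nm]]) || qr[[nm]] < 0) {
      stop_cfg("qc_violation_rates", sprintf("rate `%s` must be >= 0", nm))
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  target n = %d, discovery n = %d\n", x$n_target,
              x$n_discovery))
  cat(sprintf("  %d variants in %d LD blocks (copy prob %.2f), maf in [%.3f, %.3f]\n",
              x$n_variants, x$n_blocks, x$ld_copy_prob, x$maf_range[1],
              x$maf_range[2]))
  cat(sprintf("  %d causal variants, h2 = %.2f\n", x$n_causal, x$h2))
  cat(sprintf("  mediation: gamma_med = %.2f, beta_med_out = %.2f, beta_direct = %.2f, base rate = %.2f\n",
              x$gamma_med, x$beta_med_out, x$beta_direct, x$base_rate))
  invisible(x)
}

# Derive a stage-specific 32-bit seed from a base seed, or NULL if unseeded.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}
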