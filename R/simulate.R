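#' Genotype panel container
#'
#' A light container for a sample-by-variant dosage matrix plus variant
#' metadata. Dosages count copies of the `a1` allele and lie in
#' \{0, 1, 2\} or `NA` for missing calls.
#'
#' @param dosage Numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids).
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos`,
#'   `a1`, `a2`, `freq` (expected frequency of `a1`, if known).
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  variants <- tibble::as_tibble(variants)
  req <- c("variant_id", "chrom", "pos", "a1", "a2")
  if (!all(req %in% names(variants))) {
    abort(paste("variants must have columns", paste(req, collapse = ", ")))
  }
  if (!identical(colnames(dosage), variants$variant_id)) {
    abort("dosage colnames must equal variants$variant_id, in order")
  }
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

variant_ids <- function(panel) panel$variants$variant_id
sample_ids <- function(panel) rownames(panel$dosage)

# Deterministic variant metadata for a config: ids, positions at fixed
# 10 kb spacing on one chromosome, allele pairs, LD-block index, and the
# per-variant base frequency draw. Consumed by both the target and the
# discovery simulators so their variants agree.
make_variant_map <- function(cfg, seed = derive_seed(cfg$seed, 1L)) {
  set_seed_if(seed)
  m <- cfg$n_variants
  block <- rep(seq_len(cfg$n_blocks), length.out = m)
  block <- sort(block)
  bases <- c("A", "C", "G", "T")
  complement <- c(A = "T", C = "G", G = "C", T = "A")
  a1 <- sample(bases, m, replace = TRUE)
  # arrays mostly avoid strand-ambiguous (A/T, C/G) assays; keep ~10%
  a2 <- vapply(a1, function(b) {
    if (runif(1) < 0.1) complement[[b]]
    else sample(setdiff(bases, c(b, complement[[b]])), 1)
  }, character(1))
  p_base <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  # implied marginal a1 frequency under the copy chain
  freq <- p_base
  cp <- cfg$ld_copy_prob
  for (j in seq_len(m)[-1]) {
    if (block[j] == block[j - 1]) {
      freq[j] <- cp * freq[j - 1] + (1 - cp) * p_base[j]
    }
  }
  tibble::tibble(
    variant_id = sprintf("var%05d", seq_len(m)),
    chrom = "1",
    pos = seq_len(m) * 10000L,
    a1 = unname(a1), a2 = unname(a2),
    block = block, p_base = p_base, freq = freq
  )
}

# One haplotype matrix (n x m, alleles 0/1) under the within-block
# first-order copy chain.
sim_haplotypes <- function(n, vmap, ld_copy_prob) {
  m <- nrow(vmap)
  h <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    fresh <- rbinom(n, 1L, vmap$p_base[j])
    if (j > 1 && vmap$block[j] == vmap$block[j - 1] && ld_copy_prob > 0) {
      copy <- runif(n) < ld_copy_prob
      h[, j] <- ifelse(copy, h[, j - 1], fresh)
    } else {
      h[, j] <- fresh
    }
  }
  h
}

#' Simulate an LD-blocked genotype panel
#'
#' Draws two independent haplotypes per sample under a within-block
#' allele-copying Markov chain (see [sim_config()]) and returns their sum
#' as a dosage panel. Dosages count copies of the `a1` allele. With
#' `cfg$base_missing_rate > 0` a corresponding fraction of entries is set
#' missing at random.
#'
#' @param cfg A [sim_config()].
#' @param n Number of samples (defaults to `cfg$n_target`).
#' @param seed Integer seed; defaults to a value derived from `cfg$seed`.
#' @param id_prefix Prefix for generated sample ids.
#'
#' @return A [genotype_panel()]; `variants$freq` holds each variant's
#'   expected `a1` frequency implied by the copy chain.
#' @export
#' @examples
#' panel <- simulate_genotypes(sim_config(n_target = 50, n_variants = 100,
#'                                        seed = 1))
#' dim(panel)
simulate_genotypes <- function(cfg, n = cfg$n_target,
                               seed = derive_seed(cfg$seed, 2L),
                               id_prefix = "tgt") {
  validate_sim_config(cfg)
  vmap <- make_variant_map(cfg)
  set_seed_if(seed)
  g <- sim_haplotypes(n, vmap, cfg$ld_copy_prob) +
    sim_haplotypes(n, vmap, cfg$ld_copy_prob)
  storage.mode(g) <- "double"
  if (cfg$base_missing_rate > 0) {
    g[runif(length(g)) < cfg$base_missing_rate] <- NA_real_
  }
  rownames(g) <- sprintf("%s%05d", id_prefix, seq_len(n))
  colnames(g) <- vmap$variant_id
  genotype_panel(g, vmap[c("variant_id", "chrom", "pos", "a1", "a2",
                           "freq", "block")])
}

#' Draw sparse true causal effects
#'
#' Assigns standard-normal effect sizes to `cfg$n_causal` randomly chosen
#' variants and zero elsewhere. The phenotype simulators rescale the
#' resulting genetic values to the requested heritability, so only the
#' relative pattern matters.
#'
#' @inheritParams simulate_genotypes
#' @return Named numeric vector of length `cfg$n_variants`.
#' @export
draw_true_betas <- function(cfg, seed = derive_seed(cfg$seed, 3L)) {
  validate_sim_config(cfg)
  vmap <- make_variant_map(cfg)
  set_seed_if(seed)
  beta <- numeric(cfg$n_variants)
  if (cfg$n_causal > 0) {
    idx <- sample.int(cfg$n_variants, cfg$n_causal)
    beta[idx] <- rnorm(cfg$n_causal)
  }
  names(beta) <- vmap$variant_id
  beta
}

# genetic value of each sample under a weight vector, mean-imputing NA
genetic_value <- function(dosage, beta) {
  if (anyNA(dosage)) {
    mu <- colMeans(dosage, na.rm = TRUE)
    idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[idx] <- mu[idx[, 2]]
  }
  drop(dosage %*% beta)
}

#' Simulate discovery GWAS summary statistics
#'
#' Simulates an explicit discovery cohort of `cfg$n_discovery` samples
#' under the same LD process as the target panel, builds a continuous
#' phenotype with heritability `cfg$h2` from the causal effects, and
#' returns per-variant marginal least-squares effect sizes, standard
#' errors and two-sided p-values. Because the discovery cohort carries
#' real LD, marginal effects at non-causal variants reflect LD tagging.
#'
#' @inheritParams simulate_genotypes
#' @param true_betas Named effect vector as from [draw_true_betas()].
#'
#' @return A tibble (`gwas_summary`) with columns `snp`, `chr`, `bp`,
#'   `a1` (effect allele), `a2`, `beta`, `se`, `p`.
#' @export
simulate_discovery_summary <- function(cfg, true_betas,
                                       seed = derive_seed(cfg$seed, 4L)) {
  validate_sim_config(cfg)
  if (cfg$n_discovery < 50) {
    abort("n_discovery < 50: marginal standard errors would be unstable",
          class = "neuroprs_config_error")
  }
  vmap <- make_variant_map(cfg)
  stopifnot(length(true_betas) == nrow(vmap))
  set_seed_if(seed)
  n <- cfg$n_discovery
  g <- sim_haplotypes(n, vmap, cfg$ld_copy_prob) +
    sim_haplotypes(n, vmap, cfg$ld_copy_prob)
  storage.mode(g) <- "double"
  gv <- drop(g %*% true_betas)
  y <- if (sd(gv) > 0 && cfg$h2 > 0) {
    sqrt(cfg$h2) * as.numeric(scale(gv)) + sqrt(1 - cfg$h2) * rnorm(n)
  } else {
    rnorm(n)
  }
  xc <- sweep(g, 2, colMeans(g))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  beta_hat <- drop(crossprod(xc, yc)) / sxx
  beta_hat[sxx == 0] <- 0
  syy <- sum(yc^2)
  sse <- pmax(syy - beta_hat^2 * sxx, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  se[sxx == 0] <- Inf
  tval <- beta_hat / se
  pval <- 2 * pt(-abs(tval), df = n - 2)
  pval[!is.finite(tval)] <- 1
  out <- tibble::tibble(
    snp = vmap$variant_id, chr = vmap$chrom, bp = vmap$pos,
    a1 = vmap$a1, a2 = vmap$a2,
    beta = unname(beta_hat), se = unname(se), p = unname(pval)
  )
  class(out) <- c("gwas_summary", class(out))
  out
}

#' Simulate the target cohort phenotypes and covariates
#'
#' Builds the covariate set (age ~ Normal(75.02, 7.20^2), sex, site,
#' education years, APOE e4 allele count), a standardized true polygenic
#' score `S` from the panel dosages and `true_betas`, one designated
#' mediator region whose standardized surface area is
#' `-gamma_med * S` plus an age loading and noise, `n_regions` each of
#' surface-area / thickness / volume measures (non-mediator regions are
#' noise), and conversion outcomes. The 1-year conversion probability
#' follows `logit(p) = logit(base_rate) + beta_med_out * M + beta_direct
#' * S`; event times are exponential with hazard `-log(1 - p)` so that
#' `P(T <= 1 year)` equals `p` exactly, and are censored at 10 years.
#'
#' @inheritParams simulate_discovery_summary
#' @param panel A [genotype_panel()] from [simulate_genotypes()].
#'
#' @return A tibble with one row per sample: ids, covariates,
#'   `converted_1yr`, `converted_10yr`, `time_years`, `event`, and
#'   `region###_{surface_area,thickness,volume}` columns. Attributes
#'   `mediator_region` (column name) and `true_score` (numeric `S`)
#'   support tests and reports.
#' @export
simulate_target_cohort <- function(cfg, panel, true_betas,
                                   seed = derive_seed(cfg$seed, 5L)) {
  validate_sim_config(cfg)
  stopifnot(inherits(panel, "genotype_panel"))
  set_seed_if(seed)
  n <- nrow(panel$dosage)
  s_raw <- genetic_value(panel$dosage, true_betas)
  s <- if (sd(s_raw) > 0) as.numeric(scale(s_raw)) else rep(0, n)

  age <- rnorm(n, 75.02, 7.20)
  sex <- ifelse(rbinom(n, 1, 0.66) == 1, "male", "female")
  site <- sample(paste0("site", 1:4), n, replace = TRUE)
  education_years <- pmin(pmax(round(rnorm(n, 15.7, 3)), 6), 20)
  apoe4 <- rbinom(n, 2, 0.3)

  # standardized regional measures; mediator is region001 surface area
  age_z <- as.numeric(scale(age))
  med_noise_sd <- sqrt(max(1 - cfg$gamma_med^2 - 0.1^2, 0.05))
  med_std <- -cfg$gamma_med * s - 0.1 * age_z + rnorm(n, 0, med_noise_sd)

  measures <- list(surface_area = c(mu = 2500, sig = 250),
                   thickness = c(mu = 2.4, sig = 0.15),
                   volume = c(mu = 6000, sig = 700))
  region_cols <- list()
  for (meas in names(measures)) {
    mu <- measures[[meas]]["mu"]; sig <- measures[[meas]]["sig"]
    for (r in seq_len(cfg$n_regions)) {
      std <- if (meas == "surface_area" && r == 1) med_std else rnorm(n)
      region_cols[[sprintf("region%03d_%s", r, meas)]] <- mu + sig * std
    }
  }

  eta <- cfg$beta_med_out * med_std + cfg$beta_direct * s
  p1 <- plogis(qlogis(cfg$base_rate) + eta)
  lambda <- -log(1 - p1)
  t_event <- rexp(n, rate = pmax(lambda, 1e-12))
  cohort <- tibble::tibble(
    sample_id = rownames(panel$dosage),
    sex_reported = sex, sex_genetic = sex,
    age = age, site = site, education_years = education_years,
    apoe4 = apoe4,
    converted_1yr = as.integer(t_event <= 1),
    converted_10yr = as.integer(t_event <= 10),
    time_years = pmin(t_event, 10),
    event = as.integer(t_event <= 10)
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(region_cols))
  attr(cohort, "mediator_region") <- "region001_surface_area"
  attr(cohort, "true_score") <- s
  cohort
}

#' Inject quality-control violations into a clean panel and cohort
#'
#' Creates ground-truth-labelled QC failures for testing the filters:
#' reported-sex flips, duplicated samples (near-copies, expected PI_HAT
#' near 1), simulated first-degree relatives (one transmitted allele per
#' variant, expected PI_HAT near 0.5), inflated heterozygosity, and
#' per-sample missingness pushing the call rate below 97%.
#'
#' @inheritParams simulate_target_cohort
#' @param cohort Cohort tibble from [simulate_target_cohort()].
#' @param rates Named list of violation rates (fractions of samples);
#'   defaults to `cfg$qc_violation_rates`. Rates above 0.5 are refused.
#'
#' @return A list with elements `panel`, `cohort` and `labels` (tibble
#'   `sample_id`, `violation`).
#' @export
inject_qc_violations <- function(panel, cohort, cfg,
                                 rates = cfg$qc_violation_rates,
                                 seed = derive_seed(cfg$seed, 6L)) {
  stopifnot(inherits(panel, "genotype_panel"))
  rates <- utils::modifyList(
    list(sex_flip = 0, duplicate = 0, first_degree = 0, het_inflate = 0,
         missing = 0), as.list(rates))
  if (any(unlist(rates) > 0.5)) {
    abort("qc violation rates above 0.5 are refused",
          class = "neuroprs_config_error")
  }
  if (all(unlist(rates) == 0)) {
    return(list(panel = panel, cohort = cohort,
                labels = tibble::tibble(sample_id = character(),
                                        violation = character())))
  }
  set_seed_if(seed)
  g <- panel$dosage
  n <- nrow(g)
  labels <- list()
  take <- function(rate, avoid = character()) {
    k <- round(rate * n)
    if (k == 0) return(character())
    pool <- setdiff(rownames(g)[seq_len(n)], avoid)
    sample(pool, min(k, length(pool)))
  }

  sex_ids <- take(rates$sex_flip)
  if (length(sex_ids)) {
    i <- match(sex_ids, cohort$sample_id)
    cohort$sex_reported[i] <- ifelse(cohort$sex_reported[i] == "male",
                                     "female", "male")
    labels$sex_flip <- sex_ids
  }

  freq <- panel$variants$freq
  new_rows <- list(); new_cohort <- list()
  dup_ids <- take(rates$duplicate, avoid = sex_ids)
  for (id in dup_ids) {
    row <- g[id, ]
    mut <- runif(length(row)) < 0.005
    row[mut] <- rbinom(sum(mut), 2, freq[mut])
    new_id <- paste0(id, "_dup")
    new_rows[[new_id]] <- row
    cr <- cohort[match(id, cohort$sample_id), ]
    cr$sample_id <- new_id
    new_cohort[[new_id]] <- cr
    labels$duplicate <- c(labels$duplicate, id, new_id)
  }
  kin_ids <- take(rates$first_degree, avoid = c(sex_ids, dup_ids))
  for (id in kin_ids) {
    par_g <- g[id, ]
    transmitted <- rbinom(length(par_g), 1, pmin(pmax(par_g / 2, 0), 1))
    transmitted[is.na(par_g)] <- rbinom(sum(is.na(par_g)), 1,
                                        freq[is.na(par_g)])
    other <- rbinom(length(par_g), 1, freq)
    new_id <- paste0(id, "_kid")
    new_rows[[new_id]] <- as.numeric(transmitted + other)
    cr <- cohort[match(id, cohort$sample_id), ]
    cr$sample_id <- new_id
    cr$age <- max(cr$age - 25, 50)
    new_cohort[[new_id]] <- cr
    labels$first_degree <- c(labels$first_degree, id, new_id)
  }
  if (length(new_rows)) {
    g <- rbind(g, do.call(rbind, new_rows))
    cohort <- dplyr::bind_rows(cohort, dplyr::bind_rows(new_cohort))
  }

  het_ids <- take(rates$het_inflate)
  for (id in het_ids) {
    row <- g[id, ]
    hom <- which(!is.na(row) & row != 1)
    flip <- hom[runif(length(hom)) < 0.6]
    g[id, flip] <- 1
  }
  labels$het_inflate <- het_ids

  miss_ids <- take(rates$missing)
  for (id in miss_ids) {
    mask <- runif(ncol(g)) < 0.05
    g[id, mask] <- NA_real_
  }
  labels$missing <- miss_ids

  lab_tbl <- purrr::imap_dfr(labels, function(ids, why) {
    tibble::tibble(sample_id = ids, violation = why)
  })
  list(panel = genotype_panel(g, panel$variants), cohort = cohort,
       labels = lab_tbl)
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [draw_true_betas()], [simulate_discovery_summary()],
#' [simulate_target_cohort()] and [inject_qc_violations()] with
#' stage-specific seeds derived from `cfg$seed`.
#'
#' @inheritParams simulate_genotypes
#' @return A list with `panel`, `cohort`, `summary`, `true_betas`,
#'   `qc_labels` and the `cfg` used.
#' @export
simulate_study <- function(cfg) {
  validate_sim_config(cfg)
  panel <- simulate_genotypes(cfg)
  beta <- draw_true_betas(cfg)
  summ <- simulate_discovery_summary(cfg, beta)
  cohort <- simulate_target_cohort(cfg, panel, beta)
  inj <- inject_qc_violations(panel, cohort, cfg)
  list(panel = inj$panel, cohort = inj$cohort, summary = summ,
       true_betas = beta, qc_labels = inj$labels, cfg = cfg)
}
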