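test_that("sim_config validates fields and names the offender", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(n_causal = 50, n_variants = 10), "n_causal")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(ld_copy_prob = 1), "ld_copy_prob")
  expect_error(sim_config(base_rate = 0), "base_rate")
  expect_error(sim_config(h2 = 1.2), "h2")
})

test_that("genotype simulation is reproducible and dosages are valid", {
  cfg <- sim_config(n_target = 60, n_variants = 150, n_blocks = 5,
                    seed = 11)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$dosage %in% c(0, 1, 2)))
  expect_identical(dim(p1), c(60L, 150L))
  # fixed 10 kb spacing on one chromosome
  expect_equal(diff(p1$variants$pos), rep(10000L, 149))
})

test_that("copy chain induces the expected LD structure", {
  n <- 5000
  # independence case: no copying
  cfg0 <- sim_config(n_target = n, n_variants = 40, n_blocks = 2,
                     n_causal = 5, ld_copy_prob = 0, seed = 5)
  g0 <- simulate_genotypes(cfg0)$dosage
  r2 <- cor(g0)^2
  expect_lt(max(r2[upper.tri(r2)]), 16 / n)  # null r2 ~ chisq_1 / n

  # strong copying at matched frequencies: adjacent r2 high
  cfg1 <- sim_config(n_target = n, n_variants = 10, n_blocks = 1,
                     n_causal = 2, ld_copy_prob = 0.99,
                     maf_range = c(0.3, 0.3), seed = 6)
  g1 <- simulate_genotypes(cfg1)$dosage
  adj <- cor(g1[, 1], g1[, 2])^2
  expect_gt(adj, 0.8)

  # empirical r2 non-increasing in expectation with index distance
  cfg2 <- sim_config(n_target = n, n_variants = 20, n_blocks = 1,
                     n_causal = 2, ld_copy_prob = 0.8, seed = 7)
  g2 <- simulate_genotypes(cfg2)$dosage
  rr <- cor(g2)^2
  by_dist <- vapply(1:10, function(d) {
    mean(rr[cbind(1:(20 - d), (1 + d):20)])
  }, numeric(1))
  expect_true(all(diff(by_dist) < 0.05))   # monotone up to noise
  expect_gt(by_dist[1], by_dist[6])
})

test_that("empirical allele frequencies match the implied marginals", {
  cfg <- sim_config(n_target = 4000, n_variants = 60, n_blocks = 3,
                    n_causal = 10, seed = 8)
  panel <- simulate_genotypes(cfg)
  f_hat <- colMeans(panel$dosage) / 2
  f <- panel$variants$freq
  se <- sqrt(f * (1 - f) / (2 * nrow(panel$dosage)))
  expect_true(all(abs(f_hat - f) < 4 * se))
})

test_that("discovery summary is null-calibrated and recovers effects", {
  # all-null: p-values uniform
  cfg <- sim_config(n_target = 10, n_discovery = 2000, n_variants = 400,
                    n_blocks = 400, n_causal = 0, seed = 9)
  s0 <- simulate_discovery_summary(cfg, rep(0, 400))
  frac <- mean(s0$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 400))

  # single causal variant, no LD: marginal estimate unbiased over replicates
  cfg1 <- sim_config(n_target = 10, n_discovery = 800, n_variants = 30,
                     n_blocks = 30, n_causal = 1, h2 = 0.2, seed = 10)
  beta_true <- c(1, rep(0, 29))
  ests <- vapply(1:40, function(r) {
    s <- simulate_discovery_summary(cfg1, beta_true, seed = 1000 + r)
    s$beta[1]
  }, numeric(1))
  # the phenotype scales the genetic value to h2, so recompute the
  # implied per-dosage effect from the generating model
  vmap_freq <- simulate_genotypes(cfg1, n = 2000, seed = 1)$variants$freq[1]
  implied <- sqrt(cfg1$h2) / sqrt(2 * vmap_freq * (1 - vmap_freq))
  expect_lt(abs(mean(ests) - implied) / implied, 0.1)
  expect_error(
    simulate_discovery_summary(sim_config(n_discovery = 10), rep(0, 8000)),
    "n_discovery")
})

test_that("LD tagging attenuates a neighbour's marginal effect by r", {
  cfg <- sim_config(n_target = 10, n_discovery = 4000, n_variants = 2,
                    n_blocks = 1, ld_copy_prob = 0.9,
                    maf_range = c(0.3, 0.3), n_causal = 1, h2 = 0.3,
                    seed = 12)
  beta_true <- c(1, 0)
  reps <- vapply(1:30, function(r) {
    s <- simulate_discovery_summary(cfg, beta_true, seed = 2000 + r)
    c(s$beta[1], s$beta[2])
  }, numeric(2))
  # expected attenuation is the dosage correlation r (~ copy prob here)
  ratio <- mean(reps[2, ]) / mean(reps[1, ])
  expect_lt(abs(ratio - 0.9), 0.07)
})

test_that("discovery phenotype heritability is recovered by the true score", {
  cfg <- sim_config(n_target = 10, n_discovery = 5000, n_variants = 300,
                    n_blocks = 30, n_causal = 40, h2 = 0.4, seed = 13)
  beta <- draw_true_betas(cfg)
  set.seed(99)
  g <- simulate_genotypes(cfg, n = 5000, seed = 77)$dosage
  gv <- drop(g %*% beta)
  y <- sqrt(0.4) * as.numeric(scale(gv)) + sqrt(0.6) * rnorm(5000)
  expect_lt(abs(summary(lm(y ~ gv))$r.squared - 0.4), 0.05)
})

test_that("target cohort carries the designed structure", {
  cfg <- fixture_cfg()
  study <- fixture_study()
  cohort <- study$cohort
  # 130 regions x 3 measures by default layout
  cfg130 <- sim_config(n_target = 40, n_variants = 100, n_blocks = 5,
                       n_causal = 20, seed = 14)
  panel <- simulate_genotypes(cfg130)
  beta <- draw_true_betas(cfg130)
  c130 <- simulate_target_cohort(cfg130, panel, beta)
  for (meas in c("surface_area", "thickness", "volume")) {
    expect_length(grep(paste0("_", meas, "$"), names(c130)), 130)
  }
  expect_true(all(c130$time_years > 0 & c130$time_years <= 10))
  expect_true(all(c130$apoe4 %in% 0:2))
  # 1-year indicator consistent with event times
  expect_identical(c130$converted_1yr, as.integer(c130$time_years <= 1 &
                                                    c130$event == 1))
})

test_that("null generative model reproduces the base conversion rate", {
  cfg <- sim_config(n_target = 2000, n_variants = 100, n_blocks = 5,
                    n_causal = 20, gamma_med = 0, beta_direct = 0,
                    beta_med_out = 0, base_rate = 0.15, seed = 15)
  panel <- simulate_genotypes(cfg)
  beta <- draw_true_betas(cfg)
  cohort <- simulate_target_cohort(cfg, panel, beta)
  rate <- mean(cohort$converted_1yr)
  expect_lt(abs(rate - 0.15), 3 * sqrt(0.15 * 0.85 / 2000))
})

test_that("mediation chain propagates a positive score-conversion link", {
  # gamma_med > 0 with protective area: higher score -> smaller area ->
  # more conversion, so cor(S, conversion) > 0 in expectation
  cors <- vapply(1:10, function(r) {
    cfg <- sim_config(n_target = 600, n_variants = 80, n_blocks = 4,
                      n_causal = 20, gamma_med = 0.6,
                      beta_med_out = -1.2, beta_direct = 0,
                      seed = 300 + r)
    panel <- simulate_genotypes(cfg)
    beta <- draw_true_betas(cfg)
    cohort <- simulate_target_cohort(cfg, panel, beta)
    cor(attr(cohort, "true_score"), cohort$converted_1yr)
  }, numeric(1))
  expect_gt(mean(cors), 0)
  expect_gt(mean(cors > 0), 0.8)
})

test_that("qc violation injection is labelled and detectable", {
  cfg <- sim_config(n_target = 80, n_variants = 400, n_blocks = 10,
                    n_causal = 20, seed = 16)
  panel <- simulate_genotypes(cfg)
  beta <- draw_true_betas(cfg)
  cohort <- simulate_target_cohort(cfg, panel, beta)

  # all-zero rates: identity
  clean <- inject_qc_violations(panel, cohort, cfg)
  expect_identical(clean$panel, panel)
  expect_identical(clean$cohort, cohort)
  expect_equal(nrow(clean$labels), 0)

  rates <- list(sex_flip = 0.05, duplicate = 0.04, first_degree = 0.04,
                het_inflate = 0.05, missing = 0.05)
  inj <- inject_qc_violations(panel, cohort, cfg, rates = rates, seed = 2)
  lab <- inj$labels
  expect_true(all(c("sex_flip", "duplicate", "first_degree",
                    "het_inflate", "missing") %in% lab$violation))

  # duplicates: PI_HAT near 1
  dup_new <- grep("_dup$", lab$sample_id, value = TRUE)[1]
  dup_src <- sub("_dup$", "", dup_new)
  expect_gt(estimate_pi_hat(inj$panel, dup_src, dup_new), 0.9)

  # first-degree pair: PI_HAT near 0.5
  kid <- grep("_kid$", lab$sample_id, value = TRUE)[1]
  parent <- sub("_kid$", "", kid)
  ph <- estimate_pi_hat(inj$panel, parent, kid)
  expect_lt(abs(ph - 0.5), 0.15)

  # missingness injection: call rate below 0.97
  miss_id <- lab$sample_id[lab$violation == "missing"][1]
  cr <- mean(!is.na(inj$panel$dosage[miss_id, ]))
  expect_lt(cr, 0.97)

  # sex flip recorded in the cohort
  flip_id <- lab$sample_id[lab$violation == "sex_flip"][1]
  row <- inj$cohort[inj$cohort$sample_id == flip_id, ]
  expect_true(row$sex_reported != row$sex_genetic)

  expect_error(
    inject_qc_violations(panel, cohort, cfg,
                         rates = list(sex_flip = 0.6)), "0.5")
})

test_that("study simulation is seed-deterministic end to end", {
  cfg <- sim_config(n_target = 40, n_variants = 120, n_blocks = 6,
                    n_causal = 20, n_discovery = 300, seed = 17)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$cohort, s2$cohort)
})
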