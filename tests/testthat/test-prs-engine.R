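make_summary <- function(panel, beta, p, a1 = panel$variants$a1,
                         a2 = panel$variants$a2) {
  out <- tibble::tibble(snp = panel$variants$variant_id,
                        chr = panel$variants$chrom,
                        bp = panel$variants$pos,
                        a1 = a1, a2 = a2, beta = beta,
                        se = abs(beta) / 2 + 0.01, p = p)
  class(out) <- c("gwas_summary", class(out))
  out
}

test_that("allele alignment keeps, flips and drops correctly", {
  g <- matrix(c(0, 1, 2, 1), 2, 2,
              dimnames = list(c("s1", "s2"), c("v1", "v2")))
  panel <- genotype_panel(g, tibble::tibble(
    variant_id = c("v1", "v2"), chrom = "1", pos = c(1e4, 2e4),
    a1 = c("A", "G"), a2 = c("C", "T"), freq = c(0.3, 0.4)))
  summ <- tibble::tibble(
    snp = c("v1", "v2", "v3"),
    chr = "1", bp = c(1e4, 2e4, 3e4),
    a1 = c("A", "T", "A"), a2 = c("C", "G", "C"),
    beta = c(0.2, 0.2, 0.5), se = 0.1, p = c(0.01, 0.02, 0.03))
  aligned <- suppressMessages(align_alleles(summ, panel))
  expect_equal(aligned$beta, c(0.2, -0.2))   # same orientation, swapped
  expect_equal(aligned$variant_id, c("v1", "v2"))
  dropped <- attr(aligned, "dropped")
  expect_equal(dropped$drop_reason, "not_in_panel")

  # allele-set mismatch is dropped with its reason
  summ2 <- summ[1:2, ]
  summ2$a2[1] <- "G"   # {A,G} vs panel {A,C}
  a2 <- suppressMessages(align_alleles(summ2, panel))
  expect_equal(nrow(a2), 1)
  expect_equal(attr(a2, "dropped")$drop_reason, "allele_mismatch")

  # ambiguous pairs are dropped even when ids and alleles match
  panel_at <- genotype_panel(g, tibble::tibble(
    variant_id = c("v1", "v2"), chrom = "1", pos = c(1e4, 2e4),
    a1 = c("A", "G"), a2 = c("T", "T"), freq = c(0.3, 0.4)))
  summ3 <- make_summary(panel_at, beta = c(0.3, 0.3), p = c(0.1, 0.1))
  a3 <- suppressMessages(align_alleles(summ3, panel_at))
  expect_false("v1" %in% a3$variant_id)
  expect_error(suppressMessages(
    align_alleles(dplyr::mutate(summ, snp = paste0("x", snp)), panel)),
    "no summary variants")
})

test_that("dosage r2 matches definitions and edge cases", {
  panel <- random_panel(200, 6, seed = 31)
  g <- panel$dosage
  g[, 2] <- g[, 1]            # perfect LD
  g[, 3] <- 1                 # zero variance
  p2 <- genotype_panel(g, panel$variants)
  expect_equal(ld_r2(p2, 1, 1), 1)
  expect_equal(ld_r2(p2, 1, 2), 1)
  expect_equal(ld_r2(p2, 1, 3), 0)
  expect_equal(ld_r2(p2, "v004", "v005"),
               cor(g[, 4], g[, 5])^2, tolerance = 1e-12)
  expect_error(ld_r2(random_panel(20, 3, 1), 1, 2), "non-missing")
})

test_that("independent variants show near-zero r2", {
  panel <- random_panel(2000, 20, seed = 32)
  r2 <- vapply(2:20, function(j) ld_r2(panel, 1, j), numeric(1))
  expect_lt(max(r2), 0.05)
})

test_that("clumping keeps the most significant variant per LD region", {
  # hand case: two variants 10 kb apart in strong LD
  set.seed(33)
  x <- rbinom(300, 2, 0.4)
  y <- x; flip <- runif(300) < 0.05
  y[flip] <- rbinom(sum(flip), 2, 0.4)
  g <- cbind(v1 = x, v2 = y)
  rownames(g) <- sprintf("s%03d", 1:300)
  panel <- genotype_panel(g, tibble::tibble(
    variant_id = c("v1", "v2"), chrom = "1", pos = c(100000L, 110000L),
    a1 = "A", a2 = "C", freq = 0.4))
  w <- tibble::tibble(variant_id = c("v1", "v2"), col_index = 1:2,
                      beta = c(0.1, 0.2), p = c(1e-3, 1e-8))
  out <- clump(w, panel)
  expect_equal(out$variant_id, "v2")   # smaller p wins

  # no pair above threshold: identity
  panel2 <- random_panel(400, 10, seed = 34)
  w2 <- tibble::tibble(variant_id = panel2$variants$variant_id,
                       col_index = 1:10, beta = rnorm(10),
                       p = runif(10))
  expect_equal(clump(w2, panel2)$variant_id, w2$variant_id)
})

test_that("clumping equals an independent brute-force oracle", {
  for (rep in 1:200) {
    set.seed(4000 + rep)
    m <- 40; n <- 80
    pos <- sort(sample.int(400000L, m))
    base <- rbinom(n, 2, 0.4)
    g <- sapply(seq_len(m), function(j) {
      if (runif(1) < 0.5) {
        z <- base; swap <- runif(n) < runif(1, 0.05, 0.6)
        z[swap] <- rbinom(sum(swap), 2, 0.4)
        z
      } else rbinom(n, 2, runif(1, 0.1, 0.5))
    })
    rownames(g) <- sprintf("s%03d", seq_len(n))
    colnames(g) <- sprintf("v%03d", seq_len(m))
    pv <- runif(m)
    panel <- genotype_panel(g, tibble::tibble(
      variant_id = colnames(g), chrom = "1", pos = pos, a1 = "A",
      a2 = "C", freq = colMeans(g) / 2))
    w <- tibble::tibble(variant_id = colnames(g), col_index = seq_len(m),
                        beta = rnorm(m), p = pv)
    mine <- clump(w, panel, r2_threshold = 0.5, window_kb = 50)
    oracle <- clump_oracle(g, pos, pv, 0.5, 50000)
    expect_identical(sort(mine$col_index), oracle)
  }
})

test_that("scoring matches the double-loop oracle and hand cases", {
  # hand case: one variant, dosage 2, beta 0.5 -> score 1
  g <- matrix(c(2, 0), 2, 1, dimnames = list(c("s1", "s2"), "v1"))
  panel <- genotype_panel(g, tibble::tibble(
    variant_id = "v1", chrom = "1", pos = 1e4L, a1 = "A", a2 = "C",
    freq = 0.5))
  w <- tibble::tibble(variant_id = "v1", col_index = 1L, beta = 0.5,
                      p = 0.01)
  expect_equal(prs_score(panel, w)$score, c(1, 0))

  # zero weights give zero scores
  w0 <- dplyr::mutate(w, beta = 0)
  expect_equal(prs_score(panel, w0)$score, c(0, 0))

  # random panel with missing entries vs oracle at 1e-12
  panel2 <- random_panel(20, 30, seed = 35, missing_rate = 0.1)
  w2 <- tibble::tibble(variant_id = panel2$variants$variant_id,
                       col_index = 1:30, beta = rnorm(30),
                       p = runif(30))
  for (p_T in c(0.2, 0.6, 1)) {
    mine <- prs_score(panel2, w2, p_T)$score
    oracle <- score_oracle(panel2$dosage, w2$beta, w2$p, p_T)
    expect_equal(mine, oracle, tolerance = 1e-12)
  }

  # nothing passes the threshold: zero scores with a warning
  expect_warning(out <- prs_score(panel2, w2, 1e-9), "no variant")
  expect_true(all(out$score == 0))
})

test_that("z-scored PRS is invariant to allele relabelling", {
  panel <- random_panel(150, 25, seed = 36)
  summ <- make_summary(panel, beta = rnorm(25), p = runif(25))
  flip <- seq(1, 25, by = 2)
  g2 <- panel$dosage
  g2[, flip] <- 2 - g2[, flip]
  v2 <- panel$variants
  tmp <- v2$a1[flip]; v2$a1[flip] <- v2$a2[flip]; v2$a2[flip] <- tmp
  v2$freq[flip] <- 1 - v2$freq[flip]
  panel_flipped <- genotype_panel(g2, v2)

  a1 <- align_alleles(summ, panel)
  a2 <- align_alleles(summ, panel_flipped)
  s1 <- prs_score(panel, a1)$score
  s2 <- prs_score(panel_flipped, a2)$score
  expect_equal(as.numeric(scale(s1)), as.numeric(scale(s2)),
               tolerance = 1e-10)
  # raw scores differ only by a constant
  expect_lt(diff(range((s1 - s2))), 1e-10)
})

test_that("threshold sweep has monotone inclusion and full-grid cover", {
  sw <- sweep_fixture()
  grid <- sw$profile$grid
  expect_equal(nrow(grid), 1000)
  expect_true(all(diff(grid$n_variants) >= 0))
  expect_equal(grid$n_variants[grid$p_T == 1], nrow(sw$clumped))
  # no retained clumped pair within the window exceeds the r2 threshold
  qc <- fixture_qc()
  w <- sw$clumped
  pos <- qc$panel$variants$pos[w$col_index]
  set.seed(37)
  take <- sample(nrow(w), 40)
  for (i in take) {
    near <- which(abs(pos - pos[i]) <= 250000 & seq_along(pos) != i)
    for (j in near) {
      expect_lte(cor(qc$panel$dosage[, w$col_index[i]],
                     qc$panel$dosage[, w$col_index[j]])^2, 0.5 + 1e-12)
    }
  }
})

test_that("best threshold is selected by R2 and scores are z-scaled then trimmed", {
  sw <- sweep_fixture()
  prof <- sw$profile
  expect_equal(prof$best_r2, max(prof$grid$r2, na.rm = TRUE))
  # ties resolved toward the smallest threshold
  first_max <- min(which(prof$grid$r2 == prof$best_r2))
  expect_equal(prof$best_p_T, prof$grid$p_T[first_max])
  z <- prof$scores$z
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_identical(prof$scores$included,
                   abs(z - mean(z)) <= 2 * sd(z))
})

test_that("the 2 SD mask removes roughly the normal tail mass", {
  # over replicates of a normal score the masked share is ~4.6%
  set.seed(38)
  shares <- replicate(200, {
    z <- as.numeric(scale(rnorm(304)))
    mean(abs(z - mean(z)) > 2 * sd(z))
  })
  expect_lt(abs(mean(shares) - 0.0455), 0.01)
})

test_that("best-threshold PRS tracks the true score in simulation", {
  sw <- sweep_fixture()
  study <- fixture_study()
  s_true <- attr(study$cohort, "true_score")
  idx <- match(sw$profile$scores$sample_id, study$cohort$sample_id)
  expect_gt(cor(sw$profile$scores$z, s_true[idx]), 0.3)
})

test_that("permutation correction is significant for signal, honest for noise", {
  sw <- sweep_fixture()
  prof <- permutation_correct(sw$profile, n_perm = 100, seed = 1)
  expect_lt(prof$perm_p, 0.05)
  expect_length(prof$perm_best_r2, 100)
  expect_error(permutation_correct(sw$profile, n_perm = 0), "at least 100")

  # pure-noise weights: corrected p is large
  qc <- fixture_qc()
  set.seed(39)
  noise_w <- sw$clumped
  noise_w$beta <- rnorm(nrow(noise_w))
  noise_w$p <- runif(nrow(noise_w))
  cohort_null <- qc$cohort
  cohort_null$converted_1yr <- sample(cohort_null$converted_1yr)
  prof_null <- sweep_and_select(qc$panel, noise_w, cohort_null,
                                grid = seq(0.05, 1, by = 0.05))
  prof_null <- permutation_correct(prof_null, n_perm = 100, seed = 2)
  expect_gt(prof_null$perm_p, 0.05)
  expect_lt(prof_null$best_r2, 0.1)
})
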