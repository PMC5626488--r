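test_that("per-chromosome joint fit concentrates h2 on the causal chromosome", {
  set.seed(26)
  wins <- 0; reps <- 5
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_samples = 400, n_snps = 300, n_chromosomes = 3,
                      seed = 70 + r)
    geno <- simulate_genotypes(cfg)
    # plant all causal variance on chromosome 1
    chr1 <- which(geno$snps$chr == "1")
    Z <- scale(geno$X[, chr1[1:80]])
    gsc <- drop(Z %*% rnorm(80))
    gsc <- gsc * sqrt(0.6) / sd(gsc)
    y <- gsc + rnorm(400, 0, sqrt(0.4))
    tab <- per_chromosome_h2(geno, y)$table
    if (tab$h2_obs[tab$label == "1"] == max(tab$h2_obs)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("per-chromosome h2 sums to the single-GRM estimate within a joint SE", {
  set.seed(27)
  sim <- sim_quant(n = 500, m = 600, h2 = 0.5, seed = 81, n_chromosomes = 4)
  single <- fit_reml(sim$y, compute_grm(sim$geno))
  ph <- per_chromosome_h2(sim$geno, sim$y)
  expect_true(ph$joint)
  joint_se <- sqrt(sum(ph$table$h2_obs_se^2))
  expect_lt(abs(sum(ph$table$h2_obs) - sum(single$h2_obs)), joint_se)
})

test_that("duplicated chromosomes make the joint fit fall back with a warning", {
  set.seed(28)
  d <- matrix(rbinom(200 * 60, 2, 0.4), 200, 60)
  d2 <- cbind(d, d)  # chromosome 2 duplicates chromosome 1
  g <- toy_geno(d2, chr = rep(c("1", "2"), each = 60))
  y <- rnorm(200)
  expect_warning(ph <- per_chromosome_h2(g, y), "sequential|failed")
  expect_false(ph$joint)
})

test_that("h2-length regression: perfect linear table and degenerate input", {
  tab <- data.frame(label = as.character(1:6),
                    h2_obs = c(0.02, 0.04, 0.06, 0.08, 0.10, 0.12))
  lens <- setNames(c(1, 2, 3, 4, 5, 6) * 1e7, as.character(1:6))
  reg <- h2_length_regression(tab, lengths = lens)
  expect_equal(reg$r, 1, tolerance = 1e-9)
  expect_length(reg$outliers, 0)
  expect_equal(reg$slope, 0.02 / 1e7, tolerance = 1e-12)

  expect_error(h2_length_regression(tab[1:2, ], lengths = lens), "3 points")
  expect_error(h2_length_regression(tab, lengths = setNames(rep(1e7, 6),
                                                            as.character(1:6))),
               "variance")
  # permuting the pairing leaves the magnitude of r exchangeable in [0, 1]
  set.seed(29)
  rs <- replicate(20, {
    t2 <- tab; t2$h2_obs <- sample(t2$h2_obs)
    abs(h2_length_regression(t2, lengths = lens)$r)
  })
  expect_true(all(rs >= 0 & rs <= 1))
})

test_that("MAF-bin partition fit reports the six-bin table", {
  set.seed(30)
  cfg <- sim_config(n_samples = 300, n_snps = 600, seed = 91,
                    per_partition_h2 = c(g = 0.5), causal_fraction = 0.3)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_liability_phenotype(geno, cfg)
  mb <- maf_bin_h2(geno, ph$liability)
  expect_true(all(mb$table$label %in%
                    c("0.01-0.05", "0.05-0.1", "0.1-0.2", "0.2-0.3",
                      "0.3-0.4", "0.4-0.5")))
  expect_equal(sum(mb$table$n_snps), 600)
})

test_that("rare-variant model: full-panel ceiling reduces to the plain fit", {
  set.seed(31)
  sim <- sim_quant(n = 300, m = 400, h2 = 0.5, seed = 101)
  expect_warning(rv <- rare_variant_model_h2(sim$geno, maf_ceiling = 0.5,
                                             y = sim$y), "clamped")
  expect_equal(rv$beta, 1, tolerance = 1e-9)
  expect_equal(rv$c, 0)
  expect_identical(rv$n_subset, 400L)
  plain <- fit_reml(sim$y, compute_grm(sim$geno))
  expect_equal(unname(rv$fit$h2_obs), unname(plain$h2_obs), tolerance = 1e-3)
  expect_error(rare_variant_model_h2(sim$geno, y = sim$y), "explicitly")
  expect_error(rare_variant_model_h2(sim$geno, maf_ceiling = 2, y = sim$y),
               "0.5")
})

test_that("calibration recovers a known attenuation and restores the estimate", {
  # Controlled attenuation round trip: shrink the off-diagonals of a GRM by
  # the factor the calibration model predicts for a known c, then check
  # that (a) the regression recovers c, (b) adjustment inverts the
  # attenuation exactly, and (c) the restored GRM estimates h2 at least as
  # well as the attenuated one.
  set.seed(32)
  for (r in 1:3) {
    sim <- sim_quant(n = 250, m = 400, h2 = 0.5, seed = 110 + r,
                     causal_fraction = 0.5)
    full <- compute_grm(sim$geno)
    va <- var(full$A[lower.tri(full$A)])
    c_true <- 0.03 / va               # sizeable known attenuation (~3%)
    shrink <- 1 - (c_true + 1 / full$n_snps) * va
    atten <- full
    atten$A <- full$A * shrink
    diag(atten$A) <- 1 + (diag(full$A) - 1) * shrink

    # (a) the regression of attenuated on full off-diagonals recovers c
    cal <- estimate_adjustment_c(atten, full)
    expect_equal(cal$c, c_true, tolerance = 1e-6)
    # (b) adjustment inverts the attenuation (to second order in c*var)
    restored <- adjust_grm(atten, cal$c)
    expect_lt(max(abs(restored$A - full$A)) / max(abs(full$A)), 0.01)
    # (c) the restored GRM reproduces the full-GRM heritability inference
    f_full <- fit_reml(sim$y, full)
    f_adj <- fit_reml(sim$y, restored)
    expect_equal(unname(f_adj$h2_obs), unname(f_full$h2_obs), tolerance = 0.02)
  }
})

test_that("region exclusion no-ops on empty regions; conditioning collapses a single locus", {
  set.seed(33)
  sim <- sim_quant(n = 300, m = 300, h2 = 0.4, seed = 121)
  base <- fit_reml(sim$y, compute_grm(sim$geno))
  # a region with no SNPs: identical estimate
  f0 <- region_exclude_or_condition(sim$geno, "exclude",
                                    region = list("9", 1, 2), y = sim$y)
  expect_identical(unname(f0$h2_obs), unname(base$h2_obs))

  # conditioning on the unique causal SNP collapses the genetic component
  collapse <- 0; reps <- 5
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_samples = 400, n_snps = 200, seed = 130 + r,
                      maf_range = c(0.2, 0.5))
    geno <- simulate_genotypes(cfg)
    x <- scale(geno$X[, 7])
    y <- drop(x) * sqrt(0.5) + rnorm(400, 0, sqrt(0.5))
    un <- fit_reml(y, compute_grm(geno))
    cond <- region_exclude_or_condition(geno, "condition",
                                        snp_id = geno$snps$id[7], y = y)
    if (cond$h2_obs < 0.25 * un$h2_obs) collapse <- collapse + 1
  }
  expect_gte(collapse, 4)
  expect_error(region_exclude_or_condition(sim$geno, "condition",
                                           snp_id = "nope", y = sim$y),
               "unknown")
})
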