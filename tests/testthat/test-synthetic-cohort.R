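test_that("genotype simulation is deterministic and matches the MAF spectrum", {
  cfg <- sim_config(n_samples = 200, n_snps = 60, seed = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$X, g2$X)

  # fixed MAF 0.5 at large n: empirical frequency within 3 binomial SEs
  n <- 10000
  cfg2 <- sim_config(n_samples = n, n_snps = 40, maf = rep(0.5, 40), seed = 9)
  g <- simulate_genotypes(cfg2)
  se <- sqrt(0.5 * 0.5 / (2 * n))
  # 4 SEs: with 40 simultaneous SNPs a 3-SE band is exceeded ~10% of the time
  expect_true(all(abs(a1_freq(g) - 0.5) < 4 * se))
  expect_lt(mean(abs(a1_freq(g) - 0.5)), 2 * se)
})

test_that("MAF spec is validated", {
  expect_error(sim_config(n_snps = 3, maf = c(0.1, NaN, 0.2)), "finite")
  expect_error(sim_config(n_snps = 2, maf = c(0.1, 0.7)), "0.5")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
})

test_that("LD blocks induce positive adjacent correlation; block size 1 gives independence", {
  n <- 2000
  cfg <- sim_config(n_samples = n, n_snps = 40, ld_block_size = 1, seed = 2)
  g <- simulate_genotypes(cfg)
  cors <- cor(g$X)
  expect_lt(mean(abs(cors[upper.tri(cors)])), 3 / sqrt(n))

  cfgb <- sim_config(n_samples = n, n_snps = 40, ld_block_size = 5, ld_r = 0.8,
                     seed = 2)
  gb <- simulate_genotypes(cfgb)
  adj <- sapply(seq_len(39), function(j)
    if (j %% 5 != 0) cor(gb$X[, j], gb$X[, j + 1]) else NA)
  expect_gt(mean(adj, na.rm = TRUE), 0.3)
})

test_that("liability model hits the target prevalence and heritability", {
  # null model: no genetic signal, labels independent of any causal score
  cfg0 <- sim_config(n_samples = 3000, n_snps = 100,
                     per_partition_h2 = c(g = 0), prevalence_K = 0.3, seed = 4)
  g0 <- simulate_genotypes(cfg0)
  ph0 <- simulate_liability_phenotype(g0, cfg0)
  sc <- rowSums(scale(g0$X))
  expect_lt(abs(cor(ph0$status, sc)), 3 / sqrt(3000))

  # K = 0.5, h2 = 0.5: case fraction within 3 binomial SEs of 0.5
  cfg1 <- sim_config(n_samples = 5000, n_snps = 2000,
                     per_partition_h2 = c(g = 0.5), prevalence_K = 0.5,
                     causal_fraction = 0.5, seed = 8)
  g1 <- simulate_genotypes(cfg1)
  ph1 <- simulate_liability_phenotype(g1, cfg1)
  expect_lt(abs(mean(ph1$status) - 0.5), 3 * sqrt(0.25 / 5000))
  # realized h2 is recorded and close to target
  expect_lt(abs(sum(ph1$truth$realized_h2) - 0.5), 0.05)

  # partition variance decomposition: A at 0.3 vs B at 0.1 gives 3x variance
  cfg2 <- sim_config(n_samples = 2000, n_snps = 4000,
                     per_partition_h2 = c(A = 0.3, B = 0.1),
                     causal_fraction = 1, seed = 3)
  g2 <- simulate_genotypes(cfg2)
  ph2 <- simulate_liability_phenotype(g2, cfg2)
  ratio <- ph2$truth$realized_h2["A"] / ph2$truth$realized_h2["B"]
  expect_lt(abs(ratio - 3) / 3, 0.2)
})

test_that("per-partition h2 summing to >= 1 is rejected", {
  expect_error(sim_config(per_partition_h2 = c(a = 0.6, b = 0.5)), "< 1")
})

test_that("ascertainment is exact, class-uniform and deterministic", {
  status <- rep(c(1, 0), c(900, 2100))
  idx <- ascertain_case_control(status, 0.66, n = 1000, seed = 3)
  expect_equal(sum(status[idx]), 660)
  expect_length(idx, 1000)
  expect_identical(idx, ascertain_case_control(status, 0.66, n = 1000, seed = 3))
  # target equal to the population prevalence leaves prevalence unchanged
  st2 <- rep(c(1, 0), c(300, 700))
  idx2 <- ascertain_case_control(st2, 0.3, n = 500, seed = 1)
  expect_equal(mean(st2[idx2]), 0.3)
  expect_error(ascertain_case_control(st2, 0.9, n = 500, seed = 1), "deficit")
})

test_that("skin color is ordinal 1-10, mid-scale when degenerate, monotone in dosage", {
  set.seed(1)
  d <- matrix(rbinom(10000 * 3, 2, 0.4), 10000, 3)
  g <- toy_geno(d)
  # zero effects, zero noise: constant mid-scale value
  sc0 <- simulate_skin_color(g, loci = NULL, noise_sd = 0, seed = 1)
  expect_true(all(sc0 == sc0[1]))
  expect_true(sc0[1] %in% 5:6)
  # strong positive effect: mean skin color increasing in dosage
  sc <- simulate_skin_color(g, loci = c(s1 = 2), noise_sd = 0.5, seed = 2)
  mu <- tapply(sc, d[, 1], mean)
  expect_true(all(diff(mu) > 0))
  expect_true(all(sc >= 1 & sc <= 10))
  expect_error(simulate_skin_color(g, loci = c(nope = 1)), "unknown")
})

test_that("annotation labels match fractions exactly and eQTL sets are nested", {
  ids <- sprintf("s%05d", 1:10001)
  ann <- assign_annotations(ids, genic_fraction = 0.49, seed = 6)
  expect_identical(sum(ann$genic), as.integer(round(0.49 * 10001)))
  expect_identical(sum(ann$eqtl_0.01), as.integer(round(0.23 * 10001)))
  # strict subset chain
  expect_true(all(ann$eqtl_0.0001 <= ann$eqtl_0.001))
  expect_true(all(ann$eqtl_0.001 <= ann$eqtl_0.01))
  expect_gt(sum(ann$eqtl_0.001), sum(ann$eqtl_0.0001))
  # synthetic p-values are consistent with the flags
  expect_true(all((ann$eqtl_p < 0.01) == ann$eqtl_0.01))
  # zero fraction gives an empty label set
  ann0 <- assign_annotations(ids[1:100], genic_fraction = 0,
                             eqtl_fractions = c("0.01" = 0), seed = 1)
  expect_identical(sum(ann0$genic), 0L)
  expect_error(assign_annotations(ids[1:10],
                                  eqtl_fractions = c("0.01" = 0.1, "0.001" = 0.3)),
               "nest")
})

test_that("simulate_cohort ascertains to the exact case fraction with ground truth", {
  cfg <- sim_config(n_samples = 300, n_snps = 150, per_partition_h2 = c(g = 0.3),
                    prevalence_K = 0.2, target_case_fraction = 0.5,
                    causal_fraction = 0.3, seed = 12)
  co <- simulate_cohort(cfg)
  expect_identical(sum(co$geno$samples$status), 150L)
  expect_lt(abs(co$truth$realized_prevalence - 0.2), 0.05)
  expect_true(all(unlist(lapply(co$truth$causal, `[[`, "ids")) %in%
                    co$geno$snps$id))
  # determinism end to end
  co2 <- simulate_cohort(cfg)
  expect_identical(co$geno$X, co2$geno$X)
  expect_identical(co$geno$samples$skin_color, co2$geno$samples$skin_color)
})
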