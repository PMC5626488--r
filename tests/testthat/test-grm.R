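test_that("GRM matches the hand-evaluated estimator on tiny cases", {
  # two samples, one SNP, dosages 0 and 2 so p = 0.5:
  # A_12 = (0-1)(2-1)/(2*0.5*0.5) = -2; A_11 = (0-1)^2/0.5 = 2
  g <- toy_geno(matrix(c(0, 2), 2, 1))
  grm <- compute_grm(g)
  expect_equal(grm$A[1, 2], -2)
  expect_equal(grm$A[1, 1], 2)
  # x = 2p zero case: both samples het at p = 0.5 gives A_jj = 0
  g2 <- toy_geno(matrix(c(1, 1, 0, 2), 2, 2))
  expect_equal(compute_grm(g2)$A[1, 1], 1 / 2 * ((1 - 1)^2 / 0.5 + (0 - 1)^2 / 0.5))
})

test_that("GRM equals the naive double-loop reference, including missing calls", {
  set.seed(6)
  d <- matrix(rbinom(20 * 100, 2, runif(100, 0.1, 0.5)), 20, 100)
  d[sample(length(d), 40)] <- NA
  # guard against monomorphic columns after masking
  mono <- apply(d, 2, function(x) var(x, na.rm = TRUE) == 0)
  d <- d[, !mono]
  g <- toy_geno(d)
  grm <- compute_grm(g)
  ref <- naive_grm(d)
  expect_lt(max(abs(grm$A - ref$A)), 1e-10)
  expect_equal(unname(grm$N), ref$N + 0)
})

test_that("GRM moments on simulated unrelateds; monomorphic SNPs are refused", {
  m <- 5000
  # MAF floor away from 0.01: at n = 50 ultra-rare SNPs would go monomorphic
  cfg <- sim_config(n_samples = 50, n_snps = m, maf_range = c(0.1, 0.5),
                    seed = 21)
  g <- simulate_genotypes(cfg)
  grm <- compute_grm(g)
  expect_lt(abs(mean(diag(grm$A)) - 1), 3 / sqrt(m))
  # with in-sample allele frequencies the standardized dosages are exactly
  # mean-centred, so the off-diagonals are tied to the diagonal:
  # mean(off) = -mean(diag)/(n-1) as an identity, and hence near -1/(n-1)
  off <- grm$A[lower.tri(grm$A)]
  expect_equal(mean(off), -mean(diag(grm$A)) / (50 - 1), tolerance = 1e-10)
  expect_lt(abs(mean(off) + 1 / (50 - 1)), 3 / sqrt(m * 50))

  gm <- toy_geno(cbind(c(1, 0, 2), c(0, 0, 0)))
  expect_error(compute_grm(gm), "monomorphic")
})

test_that("union GRM is the N-weighted average of its pieces (complete data)", {
  set.seed(7)
  d <- matrix(rbinom(15 * 80, 2, runif(80, 0.2, 0.5)), 15, 80)
  g <- toy_geno(d)
  full <- compute_grm(g)
  g1 <- compute_grm(g, snps = 1:30)
  g2 <- compute_grm(g, snps = 31:80)
  merged <- (30 * g1$A + 50 * g2$A) / 80
  expect_lt(max(abs(full$A - merged)), 1e-12)
})

test_that("calibration constant estimation and GRM adjustment behave algebraically", {
  set.seed(8)
  cfg <- sim_config(n_samples = 60, n_snps = 400, seed = 31)
  g <- simulate_genotypes(cfg)
  full <- compute_grm(g)
  # G identical to A: beta = 1, raw c = -1/N, clamped to 0 with warning
  expect_warning(cal <- estimate_adjustment_c(full, full), "clamped")
  expect_equal(cal$beta, 1)
  expect_equal(cal$c_raw, -1 / full$n_snps)
  expect_equal(cal$c, 0)
  # constructed slope beta = 1 - var(A)/N gives c = 0 exactly
  va <- var(full$A[lower.tri(full$A)])
  shrunk <- full
  shrunk$A <- full$A * (1 - va / full$n_snps)
  cal2 <- estimate_adjustment_c(shrunk, full)
  expect_lt(abs(cal2$c_raw), 1e-9)

  # adjustment: c > 0 inflates every off-diagonal in magnitude
  adj <- adjust_grm(full, c = 0.5)
  off0 <- full$A[lower.tri(full$A)]
  off1 <- adj$A[lower.tri(adj$A)]
  expect_true(all(abs(off1) >= abs(off0)))
  expect_true(adj$calibration$adjusted)
  # re-adjusting is refused; negative c refused
  expect_error(adjust_grm(adj, 0.1), "already adjusted")
  expect_error(adjust_grm(full, -1), ">= 0")
})

test_that("partition schemes: MAF-bin boundaries, regions, chromosome completeness", {
  d <- matrix(rep(c(0, 1, 2, 1), 25), 100, 6)
  pos <- c(750000L, 749999L, 1000000L, 1250000L, 1250001L, 500L)
  g <- toy_geno(d, chr = c("1", "1", "1", "1", "1", "2"), pos = pos)
  spec <- partition_snps(g, "snp_list_region", snp_list = c("s3", "ghost"),
                         window_kb = 250)
  expect_identical(attr(spec, "n_unmatched"), 1L)
  expect_equal(unname(spec$labels[c("s1", "s2", "s4", "s5", "s6")]),
               c("region", "background", "region", "background", "background"))

  # MAF-bin boundary: 0.05 in the first bin, just above in the second
  mk <- function(p, n = 1000) rbinom(n, 2, p)
  set.seed(9)
  gm <- toy_geno(cbind(mk(0.05), mk(0.2)))
  maf <- snp_maf(gm)
  # force exact frequencies through explicit dosages
  d2 <- cbind(c(rep(1, 100), rep(0, 900)),   # MAF exactly 0.05
              c(rep(1, 101), rep(0, 899)),   # just above 0.05
              c(rep(1, 400), rep(0, 600)))   # 0.2
  g2 <- toy_geno(d2)
  spec2 <- partition_snps(g2, "maf_bin")
  expect_equal(unname(spec2$labels),
               c("0.01-0.05", "0.05-0.1", "0.1-0.2"))

  # chromosome scheme covers every autosomal SNP exactly once
  cfg <- sim_config(n_samples = 30, n_snps = 120, n_chromosomes = 22, seed = 2)
  gg <- simulate_genotypes(cfg)
  spec3 <- partition_snps(gg, "chromosome")
  expect_length(spec3$labels, 120)
  expect_identical(sort(unique(spec3$labels)), sort(as.character(1:22)))
})

test_that("PCA separates structured subpopulations, is orthonormal, flags degeneracy", {
  set.seed(11)
  n <- 120; m <- 600
  p1 <- runif(m, 0.1, 0.5)
  p2 <- pmin(0.95, pmax(0.05, p1 + sample(c(-1, 1), m, TRUE) * 0.25))
  pop <- rep(0:1, each = n / 2)
  d <- t(sapply(pop, function(gp) rbinom(m, 2, if (gp == 0) p1 else p2)))
  keep <- apply(d, 2, var) > 0
  g <- toy_geno(d[, keep])
  pc <- grm_pca(compute_grm(g), k = 5)
  expect_gt(abs(cor(pc$scores[, 1], pop)), 0.9)
  gram <- crossprod(pc$scores)
  expect_lt(max(abs(gram - diag(5))), 1e-8)

  idg <- compute_grm(g)
  idg$A <- diag(nrow(d))
  expect_warning(pcd <- grm_pca(idg, k = 3), "flat")
  expect_true(pcd$degenerate)
  expect_error(grm_pca(idg, k = 200), "k must be")
})
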