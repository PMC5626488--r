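test_that("HWE test: exact proportions, enumeration oracle, monomorphic edge", {
  # perfect HWE proportions: chi-square statistic 0, p = 1
  expect_equal(hwe_test(25, 50, 25, method = "chisq"), 1)
  expect_equal(hwe_test(0, 0, 30), 1)
  expect_warning(p0 <- hwe_test(0, 0, 0), "zero")
  expect_true(is.na(p0))
  expect_error(hwe_test(-1, 2, 3), ">= 0")

  # independent full-enumeration oracle for the exact test
  exact_oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa; nA <- 2 * nAA + nAa; nB <- 2 * n - nA
    het <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
    pr <- sapply(het, function(h) {
      exp(h * log(2) + lfactorial(n) - lfactorial((nA - h) / 2) -
            lfactorial(h) - lfactorial((nB - h) / 2) +
            lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n))
    })
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(nAa, het)] * (1 + 1e-7)])
  }
  for (counts in list(c(50, 0, 100), c(3, 10, 8), c(1, 1, 40), c(12, 2, 2))) {
    expect_equal(hwe_test(counts[1], counts[2], counts[3], method = "exact"),
                 exact_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-12)
  }
})

test_that("chi-square HWE converges to the exact test at GWAS-scale counts", {
  # The probability-ordered exact tail and the chi-square tail classify
  # boundary tables differently, so pointwise agreement tightens only
  # slowly with n: at n = 5000 the two tests agree to ~0.01 typically,
  # with extreme tables off by a few hundredths.
  set.seed(10)
  diffs <- replicate(300, {
    p <- runif(1, 0.2, 0.8)
    g <- table(factor(rbinom(5000, 2, p), levels = 0:2))
    abs(hwe_test(g[[3]], g[[2]], g[[1]], method = "exact") -
          hwe_test(g[[3]], g[[2]], g[[1]], method = "chisq"))
  })
  expect_lt(median(diffs), 0.01)
  expect_lt(max(diffs), 0.05)
})

test_that("differential missingness test matches Fisher/chi-square oracles", {
  # symmetric table: no signal
  expect_equal(differential_missingness_test(5, 95, 5, 95), 1)
  # hypergeometric oracle
  expect_equal(differential_missingness_test(10, 90, 0, 100),
               fisher.test(matrix(c(10, 90, 0, 100), 2, byrow = TRUE))$p.value)
  # degenerate margin: nothing missing anywhere
  expect_equal(differential_missingness_test(0, 100, 0, 100), 1)
})

test_that("SNP filters apply in the documented order on a hand-traced panel", {
  # 6 SNPs: X-linked; MAF 0.005; 10% missing; HWE-violating; two clean
  n <- 150
  set.seed(4)
  clean <- function() rbinom(n, 2, 0.3)
  rare <- c(rep(1, 2), rep(0, n - 2))              # MAF ~0.0067 (< 0.01)
  missing10 <- clean(); missing10[1:15] <- NA      # 10% missing
  hwe_bad <- c(rep(2, 50), rep(0, 100))            # (50, 0, 100)
  d <- cbind(clean(), rare, missing10, hwe_bad, clean(), clean())
  g <- toy_geno(d, chr = c("X", "1", "1", "1", "1", "1"),
                status = rep(c(1, 0), length.out = n))
  res <- filter_snps(g, qc_config("stringent"))
  expect_identical(ncol(res$geno$X), 2L)
  expect_equal(res$report$log$removed,
               c(1, 1, 1, 1, 0))  # autosome, missingness, maf, hwe, diffmiss
  # rerunning on the filtered output is a no-op
  res2 <- filter_snps(res$geno, qc_config("stringent"))
  expect_identical(ncol(res2$geno$X), 2L)
  expect_true(all(res2$report$log$removed == 0))

  # all filters disabled: identity
  res3 <- filter_snps(g, qc_config("none", autosomes_only = FALSE))
  expect_identical(res3$geno$X, g$X)

  # determinism
  resA <- filter_snps(g, qc_config("stringent"))
  expect_identical(resA$report$log, res$report$log)
})

test_that("filter config demands the inputs it needs", {
  g <- toy_geno(matrix(rbinom(40, 2, 0.4), 10, 4))
  expect_error(filter_snps(g, qc_config("stringent")), "status")
  expect_error(filter_samples(g, qc_config("stringent")), "GRM")
})

test_that("sample filters: call rate, greedy relatedness pruning with tie rule", {
  set.seed(5)
  d <- matrix(rbinom(20 * 50, 2, 0.4), 20, 50)
  g <- toy_geno(d)
  grm <- compute_grm(g)
  cfg <- qc_config("none", relatedness_max = 0.95)
  # all relatedness below threshold: no removals
  res <- filter_samples(g, cfg, grm)
  expect_identical(nrow(res$geno$X), 20L)

  # one pair at 0.9 with equal call rates: the later-ordered one is dropped
  A <- diag(20); A[3, 7] <- A[7, 3] <- 0.9
  grm2 <- grm; grm2$A <- A
  res2 <- filter_samples(g, qc_config("none", relatedness_max = 0.05), grm2)
  expect_identical(nrow(res2$geno$X), 19L)
  expect_false("i7" %in% res2$geno$samples$iid)
  expect_true("i3" %in% res2$geno$samples$iid)

  # chain A-B, B-C above threshold, A-C below: the worst pair is (A, B),
  # the tie rule removes the later-ordered B, which also resolves B-C
  A3 <- diag(20); A3[1, 2] <- A3[2, 1] <- 0.7
  A3[2, 3] <- A3[3, 2] <- 0.6; A3[1, 3] <- A3[3, 1] <- 0.01
  grm3 <- grm; grm3$A <- A3
  res3 <- filter_samples(g, qc_config("none", relatedness_max = 0.05), grm3)
  expect_identical(nrow(res3$geno$X), 19L)
  expect_false("i2" %in% res3$geno$samples$iid)
})
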