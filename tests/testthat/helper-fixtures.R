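# Shared fixture builders and independent oracles used across the suite.

# small genotype matrix from an explicit dosage matrix
toy_geno <- function(d, chr = "1", status = NULL, skin = NULL, pos = NULL) {
  d <- as.matrix(d)
  n <- nrow(d); m <- ncol(d)
  samples <- data.frame(fid = paste0("f", seq_len(n)),
                        iid = paste0("i", seq_len(n)))
  if (!is.null(status)) samples$status <- status
  if (!is.null(skin)) samples$skin_color <- skin
  genotype_matrix(d,
                  data.frame(id = paste0("s", seq_len(m)),
                             chr = rep_len(chr, m),
                             pos = pos %||% (seq_len(m) * 1000L),
                             a1 = "A", a2 = "G"),
                  samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent GRM oracle: naive double loop over pairs and SNPs with
# pairwise-complete handling of missing calls
naive_grm <- function(X) {
  n <- nrow(X); m <- ncol(X)
  p <- colMeans(X, na.rm = TRUE) / 2
  A <- matrix(0, n, n)
  N <- matrix(0L, n, n)
  for (j in seq_len(n)) for (k in seq_len(j)) {
    s <- 0; cnt <- 0L
    for (i in seq_len(m)) {
      xj <- X[j, i]; xk <- X[k, i]
      if (!is.na(xj) && !is.na(xk)) {
        s <- s + (xj - 2 * p[i]) * (xk - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
        cnt <- cnt + 1L
      }
    }
    A[j, k] <- A[k, j] <- s / cnt
    N[j, k] <- N[k, j] <- cnt
  }
  list(A = A, N = N)
}

# independent restricted log-likelihood for the single-GRM model
# V = sg * A + se * I, evaluated on an (sg, se) grid via the eigenbasis of
# A with an intercept-only design; returns the grid optimum
grid_reml_oracle <- function(y, A, grid = seq(0.001, 1.2, by = 0.001)) {
  ed <- eigen(A, symmetric = TRUE)
  lam <- ed$values
  yt <- drop(crossprod(ed$vectors, y))
  xt <- drop(crossprod(ed$vectors, rep(1, length(y))))
  best <- c(NA, NA); best_ll <- -Inf
  for (sg in grid) {
    D <- outer(lam, grid, function(l, se) sg * l + se)     # n x G
    W <- 1 / D
    xtwx <- colSums(W * xt^2)
    xtwy <- colSums(W * xt * yt)
    ytwy <- colSums(W * yt^2)
    yPy <- ytwy - xtwy^2 / xtwx
    ll <- -0.5 * (colSums(log(D)) + log(xtwx) + yPy)
    k <- which.max(ll)
    if (ll[k] > best_ll) { best_ll <- ll[k]; best <- c(sg, grid[k]) }
  }
  list(sigma = best, logL = best_ll)
}

# quick quantitative-trait cohort with a single genome-wide component
sim_quant <- function(n, m, h2, seed, causal_fraction = 0.2, ...) {
  cfg <- sim_config(n_samples = n, n_snps = m,
                    per_partition_h2 = c(g = h2),
                    causal_fraction = causal_fraction, seed = seed, ...)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_liability_phenotype(geno, cfg)
  list(geno = geno, y = ph$liability, truth = ph$truth, config = cfg)
}
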