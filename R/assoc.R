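# Per-SNP covariate-adjusted logistic-regression GWAS. The scan fits the
# full per-SNP maximum-likelihood model (additive 0/1/2 genotype coding)
# with a Newton-Raphson iteration vectorized across SNPs; near-separated or
# non-converged SNPs fall back to an efficient-score test computed from the
# covariate-only null fit, and are flagged.

# Vectorized logistic scan: y ~ X + g for every column g of G.
# X must include the intercept. Returns per-SNP estimate, SE, p, status.
logistic_scan <- function(G, y, X, max_iter = 25, tol = 1e-8) {
  n <- nrow(G); m <- ncol(G); p <- ncol(X)
  # null fit (covariates only), used for starting values and score fallback
  null_fit <- stats::glm.fit(X, y, family = stats::binomial())
  b0 <- null_fit$coefficients
  mono <- apply(G, 2, function(g) stats::var(g) == 0)

  B <- matrix(rep(c(b0, 0), m), p + 1, m)   # rows: covariates then genotype
  active <- !mono
  status <- ifelse(mono, "monomorphic", "wald")
  if (p == 1) {
    # intercept-only model: the per-SNP 2x2 Newton systems are solved in
    # closed form, vectorized across SNPs (hot path of permutation scans)
    a <- B[1, ]; b <- B[2, ]
    se <- rep(NA_real_, m)
    for (it in seq_len(max_iter)) {
      ia <- which(active)
      if (!length(ia)) break
      Ga <- G[, ia, drop = FALSE]
      Eta <- rep(a[ia], each = n) + Ga * rep(b[ia], each = n)
      Mu <- stats::plogis(Eta)
      W <- Mu * (1 - Mu)
      Res <- y - Mu
      g1 <- colSums(Res); g2 <- colSums(Ga * Res)
      h11 <- colSums(W); h12 <- colSums(W * Ga); h22 <- colSums(W * Ga * Ga)
      det <- h11 * h22 - h12^2
      bad <- det < 1e-10
      s1 <- (h22 * g1 - h12 * g2) / det
      s2 <- (-h12 * g1 + h11 * g2) / det
      a[ia] <- a[ia] + ifelse(bad, 0, s1)
      b[ia] <- b[ia] + ifelse(bad, 0, s2)
      sep <- bad | abs(b[ia]) > 12
      status[ia[sep]] <- "separated"
      conv <- pmax(abs(s1), abs(s2)) < tol
      se[ia] <- sqrt(h11 / pmax(det, 1e-300))
      active[ia[sep | conv]] <- FALSE
    }
    status[active] <- "nonconverged"
    B[1, ] <- a; B[2, ] <- b
    beta <- b
    beta[status != "wald"] <- NA_real_
    se[status != "wald"] <- NA_real_
    pval <- 2 * stats::pnorm(-abs(beta / se))
    fb <- which(status %in% c("separated", "nonconverged"))
    if (length(fb)) {
      mu0 <- null_fit$fitted.values
      w0 <- mu0 * (1 - mu0)
      Gf <- G[, fb, drop = FALSE]
      U <- colSums(Gf * (y - mu0))
      gbar <- colSums(Gf * w0) / sum(w0)
      Gres <- Gf - rep(gbar, each = n)
      Vs <- colSums(w0 * Gres * Gres)
      pval[fb] <- stats::pchisq(U^2 / Vs, df = 1, lower.tail = FALSE)
      status[fb] <- paste0(status[fb], "_score")
    }
    pval[mono] <- NA_real_
    return(data.frame(beta = beta, se = se, p = pval, status = status))
  }
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    ia <- which(active)
    Ga <- G[, ia, drop = FALSE]
    Eta <- X %*% B[seq_len(p), ia, drop = FALSE] +
      Ga * rep(B[p + 1, ia], each = n)
    Mu <- stats::plogis(Eta)
    W <- Mu * (1 - Mu)
    Res <- y - Mu
    # gradient blocks
    Gr <- rbind(crossprod(X, Res), colSums(Ga * Res))
    # Hessian blocks, per SNP
    Hxx <- array(0, c(p, p, length(ia)))
    for (j1 in seq_len(p)) for (j2 in j1:p) {
      v <- colSums(W * (X[, j1] * X[, j2]))
      Hxx[j1, j2, ] <- v; Hxx[j2, j1, ] <- v
    }
    Hxg <- sapply(seq_len(p), function(j) colSums(W * (X[, j] * Ga)))
    if (length(ia) == 1) Hxg <- matrix(Hxg, nrow = 1)
    Hgg <- colSums(W * Ga * Ga)
    done <- logical(length(ia))
    for (k in seq_along(ia)) {
      H <- rbind(cbind(Hxx[, , k], Hxg[k, ]), c(Hxg[k, ], Hgg[k]))
      step <- tryCatch(solve(H, Gr[, k]), error = function(e) NULL)
      if (is.null(step)) { status[ia[k]] <- "separated"; done[k] <- TRUE; next }
      B[, ia[k]] <- B[, ia[k]] + step
      if (max(abs(step)) < tol) done[k] <- TRUE
      if (abs(B[p + 1, ia[k]]) > 12) { status[ia[k]] <- "separated"; done[k] <- TRUE }
    }
    active[ia[done]] <- FALSE
  }
  status[active] <- "nonconverged"

  beta <- B[p + 1, ]
  se <- rep(NA_real_, m)
  ok <- which(status == "wald")
  if (length(ok)) {
    Ga <- G[, ok, drop = FALSE]
    Eta <- X %*% B[seq_len(p), ok, drop = FALSE] + Ga * rep(beta[ok], each = n)
    Mu <- stats::plogis(Eta)
    W <- Mu * (1 - Mu)
    for (k in seq_along(ok)) {
      Xf <- cbind(X, Ga[, k])
      H <- crossprod(Xf, Xf * W[, k])
      cov1 <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(cov1)) { status[ok[k]] <- "separated"; next }
      se[ok[k]] <- sqrt(cov1[p + 1, p + 1])
    }
  }
  pval <- 2 * stats::pnorm(-abs(beta / se))

  # score-test fallback for separated / non-converged SNPs
  fb <- which(status %in% c("separated", "nonconverged"))
  if (length(fb)) {
    mu0 <- null_fit$fitted.values
    w0 <- mu0 * (1 - mu0)
    XtW0X_inv <- solve(crossprod(X, X * w0))
    Gf <- G[, fb, drop = FALSE]
    U <- colSums(Gf * (y - mu0))
    proj <- X %*% (XtW0X_inv %*% crossprod(X, Gf * w0))
    Gres <- Gf - proj
    Vs <- colSums(w0 * Gres * Gres)
    pval[fb] <- stats::pchisq(U^2 / Vs, df = 1, lower.tail = FALSE)
    status[fb] <- paste0(status[fb], "_score")
    beta[fb] <- NA_real_
  }
  beta[mono] <- NA_real_
  pval[mono] <- NA_real_
  data.frame(beta = beta, se = se, p = pval, status = status)
}

#' Covariate-adjusted logistic-regression GWAS
#'
#' Fits, per SNP, a logistic regression of case-control status on the
#' additive genotype plus covariates; optionally adds the ordinal 1-10
#' skin-color score as a quantitative covariate, dropping (and counting)
#' samples with missing skin color for that model only. Missing genotype
#' calls are dropped per SNP. Reports Wald two-sided p-values;
#' near-separated or non-converged SNPs are flagged and tested with an
#' efficient-score fallback instead of fabricated Wald values; monomorphic
#' SNPs are flagged untested.
#'
#' @param geno a [genotype_matrix()].
#' @param status optional 0/1 phenotype (default: sample table status).
#' @param covariates optional data.frame/matrix of numeric covariates (e.g.
#'   age, sex, ancestry PCs), one row per sample of `geno`.
#' @param include_skin_color add the skin-color covariate (taken from
#'   `skin_color` or the sample table).
#' @param skin_color optional explicit skin-color vector.
#' @return an `assoc_table` data.frame (snp, chr, pos, a1, freq, beta, se,
#'   or, p, n_eff, n_missing, status) with attributes `lambda` (genomic
#'   inflation factor, median chi-square / 0.4549), `covariates`, and
#'   `n_dropped_skin`.
#' @export
gwas_logistic <- function(geno, status = NULL, covariates = NULL,
                          include_skin_color = FALSE, skin_color = NULL) {
  status <- status %||% geno$samples$status
  if (is.null(status) || anyNA(status) || !all(status %in% 0:1))
    stop_gwherit("status must be a complete 0/1 vector")
  n_dropped_skin <- 0L
  keep <- rep(TRUE, nrow(geno$X))
  covnames <- if (is.null(covariates)) character() else colnames(as.data.frame(covariates))
  if (include_skin_color) {
    sc <- skin_color %||% geno$samples$skin_color
    if (is.null(sc))
      stop_gwherit("include_skin_color = TRUE but no skin color available")
    keep <- !is.na(sc)
    n_dropped_skin <- sum(!keep)
    covnames <- c(covnames, "skin_color")
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(geno$X)))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (include_skin_color) X <- cbind(X, skin_color = sc)
  X <- X[keep, , drop = FALSE]
  y <- status[keep]
  csd <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(csd == 0))
    stop_gwherit("constant covariate(s): %s",
                 paste(colnames(X)[-1][csd == 0], collapse = ", "))
  if (qr(X)$rank < ncol(X)) stop_gwherit("covariate matrix is rank deficient")
  G <- geno$X[keep, , drop = FALSE]
  n_missing <- colSums(is.na(G))
  if (any(n_missing > 0)) {
    # vectorized scan on the complete columns; SNPs with missing calls are
    # refit individually on their complete cases (never mean-imputed)
    G0 <- G
    for (j in which(n_missing > 0)) G0[is.na(G0[, j]), j] <- mean(G0[, j], na.rm = TRUE)
    res <- logistic_scan(G0, y, X)
    for (j in which(n_missing > 0)) {
      cc <- !is.na(G[, j])
      sub <- logistic_scan(G[cc, j, drop = FALSE], y[cc], X[cc, , drop = FALSE])
      res[j, ] <- sub[1, ]
    }
  } else {
    res <- logistic_scan(G, y, X)
  }
  out <- data.frame(snp = geno$snps$id, chr = geno$snps$chr,
                    pos = geno$snps$pos, a1 = geno$snps$a1,
                    freq = a1_freq(geno),
                    beta = res$beta, se = res$se, or = exp(res$beta),
                    p = res$p, n_eff = length(y) - n_missing,
                    n_missing = n_missing, status = res$status,
                    row.names = NULL)
  chisq <- stats::qchisq(out$p, df = 1, lower.tail = FALSE)
  attr(out, "lambda") <- stats::median(chisq, na.rm = TRUE) / 0.4549364
  attr(out, "covariates") <- c(covnames)
  attr(out, "n_dropped_skin") <- n_dropped_skin
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Skin-color-stratified GWAS
#'
#' Runs independent scans in the light-skinned (skin color 1-3) and
#' dark-skinned (4-10) strata; samples without skin color are excluded.
#'
#' @inheritParams gwas_logistic
#' @param light_max highest skin-color value counted as light (default 3).
#' @return list(light, dark -- `assoc_table`s, sizes).
#' @export
stratified_gwas <- function(geno, status = NULL, covariates = NULL,
                            skin_color = NULL, light_max = 3) {
  status <- status %||% geno$samples$status
  sc <- skin_color %||% geno$samples$skin_color
  if (is.null(sc)) stop_gwherit("no skin color available")
  has <- !is.na(sc)
  light <- has & sc <= light_max
  dark <- has & sc > light_max
  if (!any(light)) stop_gwherit("light-skinned stratum is empty")
  if (!any(dark)) stop_gwherit("dark-skinned stratum is empty")
  sub <- function(ix) gwas_logistic(
    subset_geno(geno, samples = which(ix)), status[ix],
    if (!is.null(covariates)) as.data.frame(covariates)[ix, , drop = FALSE])
  list(light = sub(light), dark = sub(dark),
       sizes = c(light = sum(light), dark = sum(dark)))
}
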