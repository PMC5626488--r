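# GREML: restricted-maximum-likelihood variance-component estimation with
# one or several GRMs, average-information updates with EM damping,
# liability-scale conversion with ascertainment correction, a
# boundary-corrected likelihood-ratio test, and permutation significance
# for subset heritability.
#
# Model: y = X beta + sum_r g_r + e,  var(y) = V = sum_r A_r sigma_r^2 +
# I sigma_e^2. The restricted log-likelihood is
#   logL = -1/2 [ log|V| + log|X'V^-1 X| + y'Py ],
#   P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1,
# maximized over non-negative components. AI-REML uses the update
# sigma_new = sigma + AI^-1 s with score
#   s_r = -1/2 [ tr(P A_r) - y'P A_r P y ]
# and average-information matrix AI_rs = 1/2 y'P A_r P A_s P y.
# The first iterations use the EM step
#   sigma_r_new = sigma_r + sigma_r^2 (y'P A_r P y - tr(P A_r)) / n,
# which is slower but monotone, to stabilize poor starting values.

#' Liability-threshold model parameters
#'
#' @param K population prevalence of the disease in (0, 1).
#' @param P case fraction of the analyzed sample in (0, 1).
#' @return list(K, P, t, z): t is the probit threshold qnorm(1 - K), z the
#'   standard normal density at t.
#' @export
liability_params <- function(K, P) {
  assert_prob(K, "K"); assert_prob(P, "P")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  structure(list(K = K, P = P, t = t, z = z), class = "liability_params")
}

#' Liability-scale conversion factor
#'
#' The observed-scale heritability of an ascertained 0/1 trait is mapped to
#' the liability scale by the closed-form factor
#' K^2 (1 - K)^2 / (z^2 P (1 - P)), which corrects both for the probit
#' threshold transformation and for case-control ascertainment (P != K).
#' At K = P = 0.5 the factor is exactly pi/2.
#'
#' @param params a [liability_params()].
#' @return the multiplicative factor.
#' @export
liability_factor <- function(params) {
  stopifnot(inherits(params, "liability_params"))
  (params$K * (1 - params$K))^2 / (params$z^2 * params$P * (1 - params$P))
}

#' Convert observed-scale heritability to the liability scale
#'
#' @param h2_obs observed-scale heritability (>= 0).
#' @param params a [liability_params()].
#' @return liability-scale heritability.
#' @export
observed_to_liability <- function(h2_obs, params) {
  if (any(h2_obs < 0)) stop_gwherit("h2_obs must be >= 0")
  h2_obs * liability_factor(params)
}

#' Boundary-corrected likelihood-ratio p-value for a variance component
#'
#' Because the null value sigma^2 = 0 lies on the boundary of the parameter
#' space, the LRT statistic is asymptotically a 50:50 mixture of a point
#' mass at 0 and chi-square(1); for one constrained component
#' p = 0.5 P(chi2_1 > Lambda).
#'
#' @param logL_full,logL_reduced restricted log-likelihoods of the full and
#'   reduced fits.
#' @param df number of constrained variance components (default 1).
#' @return p-value.
#' @export
lrt_pvalue <- function(logL_full, logL_reduced, df = 1) {
  lambda <- 2 * (logL_full - logL_reduced)
  if (lambda < -1e-6)
    stop_gwherit("logL_full < logL_reduced (Lambda = %.3g): inconsistent fits", lambda)
  lambda <- max(lambda, 0)
  if (df == 1)
    0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  else
    0.5 * (stats::pchisq(lambda, df = df, lower.tail = FALSE) +
             stats::pchisq(lambda, df = df - 1, lower.tail = FALSE))
}

# ---- optimizer cores --------------------------------------------------------

# Single-GRM core in the eigenbasis of A: V is diagonal after rotation, so
# every REML iteration is O(n p^2). Used directly and by the permutation
# test (the decomposition is shared across permutations).
reml_eigen_core <- function(yt, Xt, lam, max_iter = 100, tol = 1e-8,
                            n_em = 3) {
  n <- length(yt); p <- ncol(Xt)
  Vp <- stats::var(yt)
  floorv <- 1e-8 * Vp
  sg <- se_ <- Vp / 2
  logL_prev <- -Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    d <- sg * lam + se_
    if (any(d <= 0)) { d <- pmax(d, 1e-12) }
    w <- 1 / d
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    Ti <- tryCatch(solve(XtWX), error = function(e)
      stop_gwherit("design matrix singular under the fitted covariance"))
    beta <- Ti %*% crossprod(XtW, yt)
    r <- yt - drop(Xt %*% beta)
    Pyt <- w * r
    yPy <- sum(r * Pyt)
    logL <- -0.5 * (sum(log(d)) + determinant(XtWX)$modulus[1] + yPy)
    trPA_g <- sum(w * lam) - sum(Ti * crossprod(Xt, Xt * (w^2 * lam)))
    trPA_e <- sum(w) - sum(Ti * crossprod(Xt, Xt * w^2))
    APy_g <- lam * Pyt
    Pv <- function(v) w * v - w * drop(Xt %*% (Ti %*% crossprod(Xt, w * v)))
    PAPy_g <- Pv(APy_g)
    PAPy_e <- Pv(Pyt)
    yPAPy_g <- sum(Pyt * APy_g)
    yPAPy_e <- sum(Pyt * Pyt)
    score <- -0.5 * c(trPA_g - yPAPy_g, trPA_e - yPAPy_e)
    AI <- 0.5 * matrix(c(sum(APy_g * PAPy_g), sum(APy_g * PAPy_e),
                         sum(APy_g * PAPy_e), sum(Pyt * PAPy_e)), 2, 2)
    if (abs(logL - logL_prev) < tol && iter > 1) { converged <- TRUE; break }
    logL_prev <- logL
    if (iter <= n_em) {
      sg <- sg + sg^2 * (yPAPy_g - trPA_g) / n
      se_ <- se_ + se_^2 * (yPAPy_e - trPA_e) / n
    } else {
      delta <- tryCatch(solve(AI, score), error = function(e)
        stop_gwherit("average-information matrix singular: variance components unidentifiable"))
      sg <- sg + delta[1]
      se_ <- se_ + delta[2]
    }
    sg <- max(sg, floorv); se_ <- max(se_, floorv)
  }
  se_comp <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, 2))
  # covariate SEs under the fitted V
  beta_se <- sqrt(diag(Ti))
  list(sigma = c(sg, se_), se = se_comp, logL = logL, iterations = iter,
       converged = converged, beta = drop(beta), beta_se = beta_se, AI = AI)
}

# General dense core for R >= 2 GRMs.
reml_dense_core <- function(y, X, Alist, max_iter = 100, tol = 1e-8,
                            n_em = 3) {
  n <- length(y); R <- length(Alist)
  Vp <- stats::var(y)
  floorv <- 1e-8 * Vp
  sigma <- rep(Vp / (R + 1), R + 1)
  logL_prev <- -Inf
  converged <- FALSE
  I_n <- diag(n)
  for (iter in seq_len(max_iter)) {
    V <- sigma[R + 1] * I_n
    for (r in seq_len(R)) V <- V + sigma[r] * Alist[[r]]
    ch <- tryCatch(chol(V), error = function(e)
      stop_gwherit("fitted covariance not positive definite"))
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    Ti <- solve(XtViX)
    P <- Vi - ViX %*% Ti %*% t(ViX)
    Py <- drop(P %*% y)
    yPy <- sum(y * Py)
    logL <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] + yPy)
    trPA <- numeric(R + 1)
    APy <- vector("list", R + 1)
    for (r in seq_len(R)) {
      trPA[r] <- sum(P * Alist[[r]])
      APy[[r]] <- drop(Alist[[r]] %*% Py)
    }
    trPA[R + 1] <- sum(diag(P))
    APy[[R + 1]] <- Py
    PAPy <- lapply(APy, function(v) drop(P %*% v))
    yPAPy <- vapply(APy, function(v) sum(Py * v), numeric(1))
    score <- -0.5 * (trPA - yPAPy)
    AI <- matrix(0, R + 1, R + 1)
    for (r in seq_len(R + 1)) for (s in r:(R + 1))
      AI[r, s] <- AI[s, r] <- 0.5 * sum(APy[[r]] * PAPy[[s]])
    if (abs(logL - logL_prev) < tol && iter > 1) { converged <- TRUE; break }
    logL_prev <- logL
    if (iter <= n_em) {
      sigma <- sigma + sigma^2 * (yPAPy - trPA) / n
    } else {
      delta <- tryCatch(solve(AI, score), error = function(e)
        stop_gwherit("average-information matrix singular: variance components unidentifiable (collinear GRMs?)"))
      sigma <- sigma + delta
    }
    sigma <- pmax(sigma, floorv)
  }
  se_comp <- tryCatch(sqrt(diag(solve(AI))), error = function(e)
    rep(NA_real_, R + 1))
  beta <- drop(Ti %*% crossprod(X, drop(Vi %*% y)))
  list(sigma = sigma, se = se_comp, logL = logL, iterations = iter,
       converged = converged, beta = beta, beta_se = sqrt(diag(Ti)), AI = AI)
}

#' Fit variance components by AI-REML
#'
#' Maximizes the restricted log-likelihood of a mixed linear model with one
#' random genetic effect per GRM plus a residual, via average-information
#' updates with expectation-maximization damping in the first iterations
#' and variance floors at 1e-8 of the phenotypic variance. Convergence is
#' declared when successive restricted log-likelihoods differ by less than
#' `tol`.
#'
#' @param y numeric phenotype (0/1 for case-control traits, analyzed on the
#'   observed scale).
#' @param grms a single [grm][compute_grm] or a (optionally named) list.
#' @param X optional covariate matrix/data.frame (an intercept is always
#'   added).
#' @param liability optional [liability_params()]; when supplied,
#'   liability-scale heritabilities are reported alongside observed-scale
#'   ones.
#' @param max_iter,tol optimizer controls.
#' @return a `reml_fit`: per-component variances `sigma` (named, residual
#'   last), standard errors `se` from the inverse average-information
#'   matrix, restricted log-likelihood `logL`, per-component `h2_obs` and
#'   (if requested) `h2_liability`, fixed effects `beta` with `beta_se`,
#'   `converged` flag and iteration count.
#' @export
fit_reml <- function(y, grms, X = NULL, liability = NULL,
                     max_iter = 100, tol = 1e-8) {
  if (inherits(grms, "grm")) grms <- list(grms)
  if (!length(grms) || !all(vapply(grms, inherits, logical(1), "grm")))
    stop_gwherit("grms must be a grm object or a list of them")
  R <- length(grms)
  names(grms) <- names(grms) %||% paste0("G", seq_len(R))
  n <- length(y)
  ids <- grms[[1]]$ids
  if (length(ids) != n) stop_gwherit("phenotype length %d != GRM dimension %d",
                                     n, length(ids))
  for (g in grms) if (!identical(g$ids, ids))
    stop_gwherit("all GRMs must cover the same ordered samples")
  if (anyNA(y)) stop_gwherit("phenotype contains missing values")
  if (stats::var(y) == 0) stop_gwherit("phenotype is constant")
  Xm <- cbind(`(Intercept)` = rep(1, n), if (!is.null(X)) as.matrix(X))
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    bad <- colnames(Xm)[qrX$pivot[seq(qrX$rank + 1, ncol(Xm))]]
    stop_gwherit("covariate matrix is rank deficient (collinear: %s)",
                 paste(bad, collapse = ", "))
  }
  offvar <- vapply(grms, function(g) stats::var(offdiag(g$A)), numeric(1))
  if (all(offvar < 1e-12))
    stop_gwherit("all GRMs are (near) identity: genetic and residual components are unidentifiable")

  if (R == 1) {
    ed <- eigen(grms[[1]]$A, symmetric = TRUE)
    yt <- drop(crossprod(ed$vectors, y))
    Xt <- crossprod(ed$vectors, Xm)
    core <- reml_eigen_core(yt, Xt, ed$values, max_iter, tol)
  } else {
    core <- reml_dense_core(y, Xm, lapply(grms, `[[`, "A"), max_iter, tol)
  }
  if (!core$converged)
    warning(sprintf("REML did not converge in %d iterations", core$iterations))
  sigma <- stats::setNames(core$sigma, c(names(grms), "residual"))
  total <- sum(sigma)
  h2_obs <- sigma[seq_len(R)] / total
  # SE of h2 via the delta method on sigma_r / total
  h2_se <- rep(NA_real_, R)
  Vcov <- tryCatch(solve(core$AI), error = function(e) NULL)
  if (!is.null(Vcov)) {
    for (r in seq_len(R)) {
      grad <- rep(-sigma[r] / total^2, R + 1)
      grad[r] <- grad[r] + 1 / total
      h2_se[r] <- sqrt(drop(t(grad) %*% Vcov %*% grad))
    }
  }
  fit <- list(sigma = sigma,
              se = stats::setNames(core$se, names(sigma)),
              logL = core$logL,
              h2_obs = stats::setNames(as.vector(h2_obs), names(grms)),
              h2_obs_se = stats::setNames(h2_se, names(grms)),
              beta = stats::setNames(core$beta, colnames(Xm)),
              beta_se = stats::setNames(core$beta_se, colnames(Xm)),
              converged = core$converged, iterations = core$iterations,
              n = n, liability = liability)
  if (!is.null(liability)) {
    f <- liability_factor(liability)
    fit$h2_liability <- fit$h2_obs * f
    fit$h2_liability_se <- fit$h2_obs_se * f
  }
  structure(fit, class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit (n = %d, logL = %.4f, %s in %d iterations)\n",
              x$n, x$logL,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  comps <- names(x$h2_obs)
  for (r in seq_along(comps)) {
    cat(sprintf("  %-12s sigma2 = %.4f (SE %.4f), h2_obs = %.4f (SE %.4f)",
                comps[r], x$sigma[r], x$se[r], x$h2_obs[r], x$h2_obs_se[r]))
    if (!is.null(x$h2_liability))
      cat(sprintf(", h2_liab = %.4f", x$h2_liability[r]))
    cat("\n")
  }
  cat(sprintf("  %-12s sigma2 = %.4f (SE %.4f)\n", "residual",
              x$sigma[length(x$sigma)], x$se[length(x$se)]))
  invisible(x)
}

#' Permutation test for subset heritability
#'
#' Shuffles the case-control labels uniformly (covariates stay attached to
#' samples; only the labels move), refits REML per permutation on the same
#' GRM, and reports the empirical p-value: the proportion of permutations
#' whose heritability estimate reaches the observed one. Ties count as
#' exceedances under the default `"inclusive"` rule (conservative); the
#' `"strict"` rule counts only permutations that exceed the observed value.
#'
#' @param grm a single [grm][compute_grm].
#' @param y 0/1 (or numeric) phenotype.
#' @param X optional covariates.
#' @param B number of permutations.
#' @param seed integer seed.
#' @param tie_rule `"inclusive"` or `"strict"`.
#' @return list(observed -- the observed `reml_fit` h2, p, permuted --
#'   vector of permuted h2 values, B_effective, n_failed, fit).
#' @export
h2_permutation_test <- function(grm, y, X = NULL, B = 1000, seed = 1L,
                                tie_rule = c("inclusive", "strict")) {
  tie_rule <- match.arg(tie_rule)
  if (B < 1) stop_gwherit("B must be >= 1")
  stopifnot(inherits(grm, "grm"))
  Xm <- cbind(`(Intercept)` = rep(1, length(y)), if (!is.null(X)) as.matrix(X))
  ed <- eigen(grm$A, symmetric = TRUE)
  Xt <- crossprod(ed$vectors, Xm)
  run <- function(yy) {
    core <- reml_eigen_core(drop(crossprod(ed$vectors, yy)), Xt, ed$values)
    core$sigma[1] / sum(core$sigma)
  }
  obs <- run(y)
  set.seed(seed)
  perm <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    perm[b] <- tryCatch(run(y[sample.int(length(y))]), error = function(e) NA_real_)
  }
  ok <- !is.na(perm)
  n_failed <- sum(!ok)
  if (n_failed)
    warning(sprintf("%d permutation fit(s) failed and were excluded", n_failed))
  pv <- if (tie_rule == "inclusive") mean(perm[ok] >= obs) else mean(perm[ok] > obs)
  list(observed = obs, p = pv, permuted = perm[ok],
       B_effective = sum(ok), n_failed = n_failed, tie_rule = tie_rule)
}
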