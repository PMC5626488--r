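# Genetic relatedness matrix engine: GRM construction from standardized
# dosages with pairwise-complete handling of missing calls, the
# regression-based calibration (beta, c) for imperfect LD between genotyped
# and causal SNPs, SNP partitioning schemes, and GRM-based PCA.

new_grm <- function(A, N, ids, n_snps, calibration = NULL) {
  structure(list(A = A, N = N, ids = ids, n_snps = n_snps,
                 calibration = calibration %||%
                   list(c = NA_real_, beta = NA_real_, adjusted = FALSE)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, %s SNPs%s\n", length(x$ids),
              format(x$n_snps),
              if (isTRUE(x$calibration$adjusted))
                sprintf(" (adjusted, c = %.3g)", x$calibration$c) else ""))
  invisible(x)
}

#' Compute the genetic relatedness matrix
#'
#' For individuals j, k the relatedness is the average over SNPs of
#' (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)), where x is the A1
#' dosage and p_i the A1 frequency estimated from the analysis sample
#' (cases and controls pooled). Missing genotypes are handled
#' pairwise-complete: each pair is averaged over the N_jk SNPs non-missing
#' in both samples, and N_jk is recorded.
#'
#' @param geno a [genotype_matrix()].
#' @param snps optional subset of SNP ids (or index) to build the GRM from.
#' @return a `grm` object: symmetric matrix `A`, pairwise SNP counts `N`,
#'   sample `ids`, `n_snps`, and an (unset) calibration record.
#' @export
compute_grm <- function(geno, snps = NULL) {
  g <- if (is.null(snps)) geno else subset_geno(geno, snps = snps)
  X <- g$X
  n <- nrow(X); m <- ncol(X)
  if (n < 2) stop_gwherit("need at least 2 samples to compute a GRM")
  p <- colMeans(X, na.rm = TRUE) / 2
  mono <- which(!is.finite(p) | p <= 0 | p >= 1)
  if (length(mono))
    stop_gwherit("monomorphic SNP(s) in GRM subset: %s",
                 paste(utils::head(g$snps$id[mono], 5), collapse = ", "))
  Z <- sweep(X, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = n)
  if (anyNA(Z)) {
    M <- !is.na(Z)
    Z[!M] <- 0
    N <- tcrossprod(M * 1)
    if (any(N == 0)) stop_gwherit("a sample pair shares no non-missing SNPs")
    A <- tcrossprod(Z) / N
  } else {
    N <- matrix(m, n, n)
    A <- tcrossprod(Z) / m
  }
  new_grm(A, N, g$samples$iid, m)
}

#' Estimate the GRM calibration constant c
#'
#' Regresses the off-diagonal entries of a subset GRM (e.g. built from SNPs
#' with MAF below a ceiling) on those of the full-panel GRM; the slope beta
#' satisfies beta = 1 - (c + 1/N) var(A_jk), giving
#' c = (1 - beta)/var(A_jk) - 1/N, the correction for prediction error from
#' imperfect LD between genotyped and causal SNPs. A negative estimate
#' (possible through sampling noise) is clamped to 0 with a warning.
#'
#' @param grm_subset,grm_full `grm` objects over the same ordered samples.
#' @return list(beta, c, c_raw, var_A).
#' @export
estimate_adjustment_c <- function(grm_subset, grm_full) {
  if (!identical(grm_subset$ids, grm_full$ids))
    stop_gwherit("GRMs must cover the same ordered samples")
  a <- offdiag(grm_full$A)
  g <- offdiag(grm_subset$A)
  va <- stats::var(a)
  if (va <= 0) stop_gwherit("full GRM has zero off-diagonal variance")
  beta <- stats::cov(g, a) / va
  c_raw <- (1 - beta) / va - 1 / grm_full$n_snps
  c_est <- c_raw
  if (c_raw < 0) {
    warning(sprintf("estimated c = %.3g is negative (sampling noise); clamped to 0",
                    c_raw))
    c_est <- 0
  }
  list(beta = beta, c = c_est, c_raw = c_raw, var_A = va)
}

#' Adjust a GRM for prediction error
#'
#' Rescales the off-diagonal entries by 1 / (1 - (c + 1/N) var(A_jk)) --
#' the inverse of the attenuation implied by the calibration regression --
#' and maps diagonals as 1 + (A_jj - 1) times the same factor, so that
#' c = 0 with large N is (near) the identity. Adjusting an already adjusted
#' GRM is refused.
#'
#' @param grm a `grm` object.
#' @param c non-negative calibration constant.
#' @return the adjusted `grm` (calibration record filled, `adjusted` flag
#'   set).
#' @export
adjust_grm <- function(grm, c) {
  if (c < 0) stop_gwherit("c must be >= 0")
  if (isTRUE(grm$calibration$adjusted))
    stop_gwherit("GRM is already adjusted; refusing to adjust twice")
  va <- stats::var(offdiag(grm$A))
  denom <- 1 - (c + 1 / grm$n_snps) * va
  if (denom <= 0) stop_gwherit("pathological c: scale factor would be <= 0")
  s <- 1 / denom
  A <- grm$A * s
  diag(A) <- 1 + (diag(grm$A) - 1) * s
  new_grm(A, grm$N, grm$ids, grm$n_snps,
          calibration = list(c = c, beta = 1 - (c + 1 / grm$n_snps) * va,
                             adjusted = TRUE))
}

#' Partition SNPs by a genomic scheme
#'
#' Schemes: `"chromosome"` (label = chromosome), `"maf_bin"` (six bins
#' \[0.01, 0.05\], (0.05, 0.1\], (0.1, 0.2\], (0.2, 0.3\], (0.3, 0.4\],
#' (0.4, 0.5\]; a MAF of exactly 0.05 falls in the first bin), `"genic"`
#' (genic vs intergenic from an annotation table), `"eqtl_threshold"`
#' (eQTL vs non-eQTL at one significance threshold), `"snp_list_region"`
#' (inside vs outside a +/- window around listed SNPs; listed SNPs absent
#' from the panel are counted and reported, not silently dropped).
#'
#' @param geno a [genotype_matrix()].
#' @param scheme partition scheme name.
#' @param annotation annotation data.frame (snp_id, genic, eqtl flags), for
#'   the genic and eqtl schemes.
#' @param eqtl_threshold one of 0.01, 0.001, 0.0001 selecting the flag
#'   column for the eqtl scheme.
#' @param snp_list character vector of SNP ids (region scheme).
#' @param window_kb half-width of the region window in kb (region scheme;
#'   required).
#' @return a `partition_spec`: list(scheme, labels -- named character vector
#'   over autosomal SNP ids -- and label universe). For the region scheme
#'   the number of listed SNPs not found is in attribute `n_unmatched`.
#' @export
partition_snps <- function(geno, scheme = c("chromosome", "maf_bin", "genic",
                                            "eqtl_threshold", "snp_list_region"),
                           annotation = NULL, eqtl_threshold = NULL,
                           snp_list = NULL, window_kb = NULL) {
  scheme <- match.arg(scheme)
  auto <- geno$snps$chr %in% as.character(1:22)
  ids <- geno$snps$id[auto]
  n_unmatched <- 0L
  if (scheme == "chromosome") {
    labels <- geno$snps$chr[auto]
  } else if (scheme == "maf_bin") {
    maf <- snp_maf(geno)[auto]
    edges <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
    binlab <- c("0.01-0.05", "0.05-0.1", "0.1-0.2", "0.2-0.3", "0.3-0.4",
                "0.4-0.5")
    b <- cut(maf, breaks = edges, labels = binlab, include.lowest = TRUE,
             right = TRUE)
    if (anyNA(b)) {
      warning(sprintf("%d SNPs with MAF < 0.01 left unlabelled by the maf_bin scheme",
                      sum(is.na(b))))
      ids <- ids[!is.na(b)]; b <- b[!is.na(b)]
    }
    labels <- as.character(b)
  } else if (scheme == "genic") {
    if (is.null(annotation)) stop_gwherit("genic scheme needs an annotation table")
    gflag <- annotation$genic[match(ids, annotation$snp_id)]
    if (anyNA(gflag)) stop_gwherit("annotation table missing %d panel SNPs",
                                   sum(is.na(gflag)))
    labels <- ifelse(gflag, "genic", "intergenic")
  } else if (scheme == "eqtl_threshold") {
    if (is.null(annotation) || is.null(eqtl_threshold))
      stop_gwherit("eqtl scheme needs an annotation table and a threshold")
    cand <- unique(sprintf("eqtl_%s", c(format(eqtl_threshold, scientific = FALSE),
                                        format(eqtl_threshold))))
    col <- cand[cand %in% names(annotation)][1]
    if (is.na(col))
      stop_gwherit("annotation table has no column %s", cand[1])
    flag <- as.logical(annotation[[col]][match(ids, annotation$snp_id)])
    if (anyNA(flag)) stop_gwherit("annotation table missing %d panel SNPs",
                                  sum(is.na(flag)))
    labels <- ifelse(flag, "eqtl", "non_eqtl")
  } else { # snp_list_region
    if (is.null(snp_list) || is.null(window_kb))
      stop_gwherit("region scheme needs snp_list and window_kb")
    ix <- match(snp_list, geno$snps$id)
    n_unmatched <- sum(is.na(ix))
    if (n_unmatched)
      message(sprintf("%d listed SNP(s) not genotyped in the panel; excluded from region definition",
                      n_unmatched))
    ix <- ix[!is.na(ix)]
    w <- window_kb * 1000
    inreg <- rep(FALSE, sum(auto))
    chr <- geno$snps$chr[auto]; pos <- geno$snps$pos[auto]
    for (i in ix) {
      hit <- chr == geno$snps$chr[i] &
        pos >= geno$snps$pos[i] - w & pos <= geno$snps$pos[i] + w
      inreg <- inreg | hit
    }
    labels <- ifelse(inreg, "region", "background")
  }
  structure(list(scheme = scheme,
                 labels = stats::setNames(labels, ids),
                 universe = sort(unique(labels))),
            class = "partition_spec", n_unmatched = n_unmatched)
}

#' Principal components from a GRM
#'
#' Eigendecomposes the GRM; components are unit-norm eigenvectors ordered
#' by descending eigenvalue, each with its largest-magnitude loading made
#' positive. Samples lying more than 6 standard deviations from the mean on
#' either of the top 2 PCs are flagged as ancestry outliers.
#'
#' @param grm a `grm` object.
#' @param k number of components, k < n.
#' @param outlier_sd flagging threshold in SD units (default 6).
#' @return list(scores -- n x k matrix, eigenvalues, outlier -- logical
#'   vector, degenerate -- TRUE when the spectrum is (near) flat, as for an
#'   identity-like GRM).
#' @export
grm_pca <- function(grm, k = 20, outlier_sd = 6) {
  n <- length(grm$ids)
  if (k >= n) stop_gwherit("k must be < n (%d)", n)
  e <- eigen(grm$A, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- grm$ids
  colnames(V) <- paste0("PC", seq_len(k))
  spread <- max(e$values) - min(e$values)
  degenerate <- spread < 1e-8 * max(abs(e$values), 1)
  if (degenerate)
    warning("GRM spectrum is (near) flat; principal components are not meaningful")
  z <- scale(V[, seq_len(min(2, k)), drop = FALSE])
  outlier <- apply(abs(z) > outlier_sd, 1, any)
  list(scores = V, eigenvalues = e$values[seq_len(k)],
       outlier = stats::setNames(as.vector(outlier), grm$ids),
       degenerate = degenerate)
}
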