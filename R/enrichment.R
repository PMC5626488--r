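# Permutation test for over-representation of annotated (cis-eQTL) SNPs
# among the top association signals. Case-control labels are shuffled while
# genotypes stay fixed, which preserves the LD structure among SNPs; the
# covariates stay attached to their samples so the null retains the
# covariate structure while breaking any genotype-phenotype association.

#' Empirical p-value from permuted counts
#'
#' @param observed observed annotated count.
#' @param permuted vector of permuted counts.
#' @param tie_rule `"inclusive"` (proportion of permutations >= observed;
#'   default, conservative) or `"strict"` (> observed; anti-conservative
#'   when permuted counts tie the observed one, e.g. at saturation).
#' @return empirical p in \[0, 1\].
#' @export
empirical_p <- function(observed, permuted, tie_rule = c("inclusive", "strict")) {
  tie_rule <- match.arg(tie_rule)
  if (!length(permuted)) stop_gwherit("permuted counts are empty")
  if (tie_rule == "inclusive") mean(permuted >= observed)
  else mean(permuted > observed)
}

# deterministic top-k selection: ascending p, then larger |estimate|, then id
.top_k <- function(tab, k) {
  ord <- order(tab$p, -abs(ifelse(is.na(tab$beta), 0, tab$beta)), tab$snp,
               na.last = TRUE)
  utils::head(ord, k)
}

#' Permutation test for eQTL enrichment among top GWAS hits
#'
#' Runs the observed association scan, counts flagged (cis-eQTL) SNPs among
#' the `top_k` most significant SNPs (ties broken deterministically by
#' smaller p, then larger absolute estimate, then SNP id), then repeats the
#' full scan `B` times with case-control labels shuffled and covariates
#' fixed to their samples, and reports the empirical p-value of the
#' observed count against the permuted counts.
#'
#' @param geno a [genotype_matrix()].
#' @param status 0/1 phenotype (default: sample table).
#' @param covariates optional covariate data.frame.
#' @param eqtl_flags logical vector (named by SNP id, or in panel order)
#'   marking cis-eQTL SNPs; must cover every tested SNP.
#' @param top_k number of top SNPs to score (e.g. 1000 or 2000).
#' @param B number of permutations (e.g. 1000).
#' @param seed integer seed.
#' @param include_skin_color add the skin-color covariate to every scan.
#' @param tie_rule passed to [empirical_p()].
#' @return an `enrichment_result`: observed count, permuted counts,
#'   empirical p, top_k, B_effective, covariate regime, seed.
#' @export
eqtl_enrichment <- function(geno, status = NULL, covariates = NULL,
                            eqtl_flags, top_k, B = 1000, seed = 1L,
                            include_skin_color = FALSE,
                            tie_rule = c("inclusive", "strict")) {
  tie_rule <- match.arg(tie_rule)
  status <- status %||% geno$samples$status
  m <- ncol(geno$X)
  if (top_k > m) stop_gwherit("top_k (%d) exceeds the number of tested SNPs (%d)",
                              top_k, m)
  if (B < 1) stop_gwherit("B must be >= 1")
  if (!is.null(names(eqtl_flags))) {
    flags <- as.logical(eqtl_flags[geno$snps$id])
  } else flags <- as.logical(eqtl_flags)
  if (length(flags) != m || anyNA(flags))
    stop_gwherit("eqtl_flags must cover every tested SNP")
  scan <- function(st) gwas_logistic(geno, st, covariates,
                                     include_skin_color = include_skin_color)
  obs_tab <- scan(status)
  observed <- sum(flags[.top_k(obs_tab, top_k)])
  set.seed(seed)
  permuted <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    st <- status[sample.int(length(status))]
    permuted[b] <- tryCatch(sum(flags[.top_k(scan(st), top_k)]),
                            error = function(e) NA_real_)
  }
  ok <- !is.na(permuted)
  if (any(!ok))
    warning(sprintf("%d permutation scan(s) failed and were dropped", sum(!ok)))
  structure(list(observed = observed, permuted = permuted[ok],
                 p = empirical_p(observed, permuted[ok], tie_rule),
                 top_k = top_k, B_effective = sum(ok),
                 include_skin_color = include_skin_color,
                 tie_rule = tie_rule, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("eQTL enrichment: %d flagged among top %d (empirical p = %.4g, B = %d%s)\n",
              x$observed, x$top_k, x$p, x$B_effective,
              if (x$include_skin_color) ", skin-color adjusted" else ""))
  invisible(x)
}
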