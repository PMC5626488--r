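# SNP and sample quality control: Hardy-Weinberg testing (exact and
# asymptotic), differential-missingness testing, and ordered filter
# pipelines for two regimes ("standard" and "stringent", the latter the
# stricter criteria recommended for heritability estimation where
# artifactual case-control frequency differences inflate estimates).

#' QC configuration
#'
#' @param regime `"standard"` (MAF < 0.02 removed, missingness > 2% removed,
#'   HWE p <= 1e-4 removed, sample call rate <= 95% removed),
#'   `"stringent"` (MAF < 0.01, missingness > 5%, HWE p < 0.05,
#'   differential missingness p < 0.05, call rate <= 99%, relatedness >
#'   0.05), or `"none"`. Individual thresholds can be overridden; NULL
#'   disables a filter.
#' @param maf_min SNPs with MAF strictly below this are removed.
#' @param snp_missing_max SNPs with missingness strictly above this are
#'   removed.
#' @param hwe_p_min HWE p-value threshold.
#' @param hwe_inclusive if TRUE, p equal to the threshold is also removed
#'   (the standard regime's "p <= 1e-4"); stringent uses strict "<".
#' @param differential_missingness_p_min threshold for the case-control
#'   differential missingness test; requires status.
#' @param sample_call_rate_min samples with call rate <= this are removed.
#' @param relatedness_max off-diagonal GRM threshold for greedy relatedness
#'   pruning; requires a GRM.
#' @param autosomes_only drop non-autosomal SNPs first.
#' @return a `qc_config` list.
#' @export
qc_config <- function(regime = c("stringent", "standard", "none"),
                      maf_min = NULL, snp_missing_max = NULL,
                      hwe_p_min = NULL, hwe_inclusive = NULL,
                      differential_missingness_p_min = NULL,
                      sample_call_rate_min = NULL, relatedness_max = NULL,
                      autosomes_only = TRUE) {
  regime <- match.arg(regime)
  def <- switch(regime,
    standard = list(maf_min = 0.02, snp_missing_max = 0.02,
                    hwe_p_min = 1e-4, hwe_inclusive = TRUE,
                    differential_missingness_p_min = NULL,
                    sample_call_rate_min = 0.95, relatedness_max = NULL),
    stringent = list(maf_min = 0.01, snp_missing_max = 0.05,
                     hwe_p_min = 0.05, hwe_inclusive = FALSE,
                     differential_missingness_p_min = 0.05,
                     sample_call_rate_min = 0.99, relatedness_max = 0.05),
    none = list(maf_min = NULL, snp_missing_max = NULL, hwe_p_min = NULL,
                hwe_inclusive = FALSE, differential_missingness_p_min = NULL,
                sample_call_rate_min = NULL, relatedness_max = NULL))
  ovr <- list(maf_min = maf_min, snp_missing_max = snp_missing_max,
              hwe_p_min = hwe_p_min, hwe_inclusive = hwe_inclusive,
              differential_missingness_p_min = differential_missingness_p_min,
              sample_call_rate_min = sample_call_rate_min,
              relatedness_max = relatedness_max)
  for (nm in names(ovr)) if (!is.null(ovr[[nm]])) def[[nm]] <- ovr[[nm]]
  for (nm in setdiff(names(def), "hwe_inclusive"))
    if (!is.null(def[[nm]]) && (def[[nm]] < 0 || def[[nm]] > 1))
      stop_gwherit("threshold %s must be in [0, 1]", nm)
  def$autosomes_only <- isTRUE(autosomes_only)
  def$regime <- regime
  structure(def, class = "qc_config")
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Exact test (enumeration over all heterozygote counts compatible with the
#' observed allele counts) when any expected genotype class count is below
#' 5, otherwise a 1-df chi-square test on the three genotype classes.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @param method `"auto"` (default switch described above), `"exact"` or
#'   `"chisq"`.
#' @return p-value in \[0, 1\]; NA with a warning if all counts are zero.
#'   Monomorphic SNPs return 1 (no heterozygote deficit is possible).
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_gwherit("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) { warning("all genotype counts are zero; HWE undefined"); return(NA_real_) }
  nA <- 2 * n_AA + n_Aa
  p <- nA / (2 * n)
  if (p == 0 || p == 1) return(1)
  if (method == "auto") {
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    method <- if (any(expected < 5)) "exact" else "chisq"
  }
  if (method == "chisq") {
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  hwe_exact_p(n_AA, n_Aa, n_aa)
}

# Exact HWE p-value by full enumeration of heterozygote counts at fixed
# allele counts: p = sum of probabilities of tables no more probable than
# the observed one, under the conditional (hypergeometric-type) null.
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n - nA
  rare <- min(nA, nB)
  het <- seq(rare %% 2, rare, by = 2)  # heterozygote counts share parity of rare
  # probability of each heterozygote count (log scale)
  hAA <- (nA - het) / 2
  haa <- (nB - het) / 2
  logp <- het * log(2) + lgamma(n + 1) - lgamma(hAA + 1) - lgamma(het + 1) -
    lgamma(haa + 1) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

#' Differential missingness test between cases and controls
#'
#' Two-sided test on the 2x2 missing-by-status table: Fisher's exact test
#' when any expected cell count is below 5, otherwise a chi-square test
#' without continuity correction.
#'
#' @param miss_case,called_case,miss_ctrl,called_ctrl non-negative counts.
#' @return p-value; 1 if a table margin is zero (no information).
#' @export
differential_missingness_test <- function(miss_case, called_case,
                                          miss_ctrl, called_ctrl) {
  counts <- c(miss_case, called_case, miss_ctrl, called_ctrl)
  if (any(counts < 0)) stop_gwherit("counts must be >= 0")
  tab <- matrix(counts, 2, 2, byrow = TRUE)  # rows: case/ctrl; cols: miss/called
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 5)) return(stats::fisher.test(tab)$p.value)
  stats::chisq.test(tab, correct = FALSE)$p.value
}

.qc_report <- function(axis, steps, removed, n_in, n_out) {
  structure(list(axis = axis,
                 log = data.frame(step = steps, removed = removed),
                 n_in = n_in, n_out = n_out),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC (%s): %d -> %d\n", x$axis, x$n_in, x$n_out))
  for (i in seq_len(nrow(x$log)))
    cat(sprintf("  %-28s removed %d\n", x$log$step[i], x$log$removed[i]))
  invisible(x)
}

#' Filter SNPs
#'
#' Filters are applied in a fixed order -- autosome-only, missingness, MAF,
#' HWE, differential missingness -- each computed on the then-surviving SNP
#' set, and itemized in the report.
#'
#' @param geno a [genotype_matrix()].
#' @param config a [qc_config()].
#' @param status optional 0/1 case-control vector (required when the
#'   differential-missingness filter is enabled; defaults to the status
#'   column of the sample table).
#' @return list(geno, report).
#' @export
filter_snps <- function(geno, config, status = NULL) {
  stopifnot(inherits(config, "qc_config"))
  status <- status %||% geno$samples$status
  if (!is.null(config$differential_missingness_p_min) &&
      (is.null(status) || all(is.na(status))))
    stop_gwherit("differential-missingness filter enabled but no case-control status supplied")
  keep <- rep(TRUE, ncol(geno$X))
  steps <- character(); removed <- integer()
  note <- function(name, drop) {
    steps <<- c(steps, name); removed <<- c(removed, sum(drop))
    keep[keep][drop] <<- FALSE
  }
  if (config$autosomes_only) {
    cur <- geno$snps$chr[keep]
    note("non_autosomal", !cur %in% as.character(1:22))
  }
  if (!is.null(config$snp_missing_max)) {
    miss <- colMeans(is.na(geno$X[, keep, drop = FALSE]))
    note("missingness", miss > config$snp_missing_max)
  }
  if (!is.null(config$maf_min)) {
    maf <- snp_maf(geno)[keep]
    note("maf", maf < config$maf_min)
  }
  if (!is.null(config$hwe_p_min)) {
    Xk <- geno$X[, keep, drop = FALSE]
    pv <- vapply(seq_len(ncol(Xk)), function(j) {
      x <- Xk[, j]
      hwe_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
               sum(x == 0, na.rm = TRUE))
    }, numeric(1))
    drop <- if (isTRUE(config$hwe_inclusive)) pv <= config$hwe_p_min
            else pv < config$hwe_p_min
    note("hwe", !is.na(drop) & drop)
  }
  if (!is.null(config$differential_missingness_p_min)) {
    Xk <- geno$X[, keep, drop = FALSE]
    is_case <- status == 1
    pv <- vapply(seq_len(ncol(Xk)), function(j) {
      x <- Xk[, j]
      differential_missingness_test(
        sum(is.na(x) & is_case), sum(!is.na(x) & is_case),
        sum(is.na(x) & !is_case), sum(!is.na(x) & !is_case))
    }, numeric(1))
    note("differential_missingness", pv < config$differential_missingness_p_min)
  }
  out <- subset_geno(geno, snps = which(keep))
  list(geno = out,
       report = .qc_report("snps", steps, removed, ncol(geno$X), ncol(out$X)))
}

#' Filter samples
#'
#' The call-rate filter runs first; then greedy relatedness pruning: while
#' any pair's GRM entry exceeds `relatedness_max`, the member of the
#' currently-worst pair with the lower call rate is dropped (ties broken by
#' dropping the later-ordered sample).
#'
#' @param geno a [genotype_matrix()].
#' @param config a [qc_config()].
#' @param grm optional [grm][compute_grm] over (a superset of) the samples;
#'   required when the relatedness filter is enabled.
#' @return list(geno, report).
#' @export
filter_samples <- function(geno, config, grm = NULL) {
  stopifnot(inherits(config, "qc_config"))
  if (!is.null(config$relatedness_max) && is.null(grm))
    stop_gwherit("relatedness filter enabled but no GRM supplied")
  keep <- rep(TRUE, nrow(geno$X))
  steps <- character(); removed <- integer()
  cr <- sample_call_rate(geno)
  if (!is.null(config$sample_call_rate_min)) {
    drop <- cr <= config$sample_call_rate_min & cr < 1
    steps <- c(steps, "call_rate"); removed <- c(removed, sum(drop))
    keep[drop] <- FALSE
  }
  if (!is.null(config$relatedness_max)) {
    ids <- geno$samples$iid[keep]
    gi <- match(ids, grm$ids)
    if (anyNA(gi)) stop_gwherit("GRM does not cover all surviving samples")
    A <- grm$A[gi, gi, drop = FALSE]
    diag(A) <- -Inf
    crk <- cr[keep]
    alive <- rep(TRUE, length(ids))
    n_rel <- 0L
    repeat {
      Aa <- A[alive, alive, drop = FALSE]
      if (!length(Aa) || max(Aa) <= config$relatedness_max) break
      w <- which(Aa == max(Aa), arr.ind = TRUE)[1, ]
      pair <- which(alive)[w]
      cr1 <- crk[pair[1]]; cr2 <- crk[pair[2]]
      victim <- if (cr1 < cr2) pair[1]
                else if (cr2 < cr1) pair[2]
                else max(pair)  # tie: drop the later-ordered sample
      alive[victim] <- FALSE
      n_rel <- n_rel + 1L
    }
    steps <- c(steps, "relatedness"); removed <- c(removed, n_rel)
    keep[keep][!alive] <- FALSE
  }
  out <- subset_geno(geno, samples = which(keep))
  list(geno = out,
       report = .qc_report("samples", steps, removed, nrow(geno$X), nrow(out$X)))
}
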