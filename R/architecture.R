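# Genetic-architecture orchestration: joint per-chromosome heritability,
# heritability-versus-chromosome-length regression with outlier calls,
# MAF-bin partitioning, the rare-variant (calibrated subset GRM) model,
# and region exclusion / index-SNP conditioning.

# joint multi-GRM fit over a partition; falls back to per-label single-GRM
# fits if the joint fit fails or does not converge
.partition_fit <- function(geno, part, y, X, liability, min_snps = 2) {
  labs <- part$universe
  grms <- list()
  for (lab in labs) {
    ids <- names(part$labels)[part$labels == lab]
    if (length(ids) < min_snps) {
      warning(sprintf("partition label %s has %d SNP(s); dropped", lab, length(ids)))
      next
    }
    grms[[lab]] <- compute_grm(geno, snps = ids)
  }
  if (!length(grms)) stop_gwherit("no partition label has enough SNPs")
  joint <- TRUE
  fit <- tryCatch({
    f <- fit_reml(y, grms, X = X, liability = liability)
    if (!f$converged) stop("joint fit did not converge")
    f
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("joint multi-GRM fit failed; falling back to sequential per-label fits")
    joint <- FALSE
    fits <- lapply(grms, function(g)
      fit_reml(y, g, X = X, liability = liability))
    tab <- data.frame(
      label = names(grms),
      n_snps = vapply(grms, function(g) g$n_snps, numeric(1)),
      sigma = vapply(fits, function(f) unname(f$sigma[1]), numeric(1)),
      h2_obs = vapply(fits, function(f) unname(f$h2_obs[1]), numeric(1)),
      h2_obs_se = vapply(fits, function(f) unname(f$h2_obs_se[1]), numeric(1)),
      row.names = NULL)
    fit <- fits[[1]]
  } else {
    tab <- data.frame(label = names(grms),
                      n_snps = vapply(grms, function(g) g$n_snps, numeric(1)),
                      sigma = unname(fit$sigma[seq_along(grms)]),
                      h2_obs = unname(fit$h2_obs),
                      h2_obs_se = unname(fit$h2_obs_se),
                      row.names = NULL)
  }
  if (!is.null(liability)) {
    f <- liability_factor(liability)
    tab$h2_liability <- tab$h2_obs * f
    tab$h2_liability_se <- tab$h2_obs_se * f
  }
  structure(list(table = tab, fit = fit, joint = joint, scheme = part$scheme),
            class = "partition_h2")
}

#' @export
print.partition_h2 <- function(x, ...) {
  cat(sprintf("Partitioned heritability (%s, %s fit)\n", x$scheme,
              if (x$joint) "joint" else "sequential"))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-chromosome heritability from a single joint fit
#'
#' Builds one GRM per chromosome and fits all of them simultaneously in one
#' REML analysis, so each chromosome's component is estimated conditional
#' on the others.
#'
#' @param geno a [genotype_matrix()].
#' @param y phenotype (default: sample table status).
#' @param X optional covariates.
#' @param liability optional [liability_params()].
#' @return a `partition_h2` (per-label table + the joint `reml_fit`).
#' @export
per_chromosome_h2 <- function(geno, y = NULL, X = NULL, liability = NULL) {
  y <- y %||% geno$samples$status
  part <- partition_snps(geno, "chromosome")
  if (length(part$universe) < 2)
    stop_gwherit("need at least 2 chromosomes for a per-chromosome partition")
  .partition_fit(geno, part, y, X, liability)
}

#' Regression of per-chromosome heritability on chromosome length
#'
#' Ordinary least squares of h2 on physical length, with the Pearson
#' correlation and its p-value, the pointwise 95% confidence band of the
#' fitted line, and per-chromosome outlier calls (outside the band). Under
#' a polygenic architecture with risk spread evenly along the genome the
#' relationship is linear; strong outliers indicate risk concentrated in
#' few regions.
#'
#' @param h2_table a `partition_h2` table (or data.frame with columns
#'   `label`, `h2_obs`).
#' @param lengths named numeric vector of chromosome lengths in base pairs;
#'   by default the genotyped span (max pos - min pos) per chromosome when
#'   `geno` is supplied.
#' @param geno optional [genotype_matrix()] used to derive default lengths.
#' @return list(slope, intercept, r, p, band -- per-chromosome fit and 95%
#'   bounds, outliers).
#' @export
h2_length_regression <- function(h2_table, lengths = NULL, geno = NULL) {
  tab <- if (inherits(h2_table, "partition_h2")) h2_table$table else h2_table
  if (is.null(lengths)) {
    if (is.null(geno)) stop_gwherit("supply lengths or geno")
    sp <- split(geno$snps$pos, geno$snps$chr)
    lengths <- vapply(sp, function(p) diff(range(p)), numeric(1))
  }
  len <- lengths[as.character(tab$label)]
  if (anyNA(len)) stop_gwherit("missing length for label(s): %s",
                               paste(tab$label[is.na(len)], collapse = ", "))
  if (nrow(tab) < 3) stop_gwherit("need at least 3 points")
  if (stats::var(len) == 0) stop_gwherit("chromosome lengths have zero variance")
  df <- data.frame(h2 = tab$h2_obs, len = as.numeric(len))
  lmfit <- stats::lm(h2 ~ len, data = df)
  ct <- stats::cor.test(df$len, df$h2)
  band <- stats::predict(lmfit, interval = "confidence", level = 0.95)
  outlier <- df$h2 < band[, "lwr"] | df$h2 > band[, "upr"]
  list(slope = unname(stats::coef(lmfit)[2]),
       intercept = unname(stats::coef(lmfit)[1]),
       r = unname(ct$estimate), p = ct$p.value,
       band = data.frame(label = tab$label, length = df$len, h2 = df$h2,
                         fit = band[, "fit"], lwr = band[, "lwr"],
                         upr = band[, "upr"], outlier = outlier),
       outliers = as.character(tab$label[outlier]))
}

#' Heritability partitioned by minor-allele-frequency bin
#'
#' Six bins spanning (0.01, 0.5\] (see [partition_snps()]); one GRM per
#' non-empty bin, fit jointly.
#'
#' @inheritParams per_chromosome_h2
#' @return a `partition_h2`.
#' @export
maf_bin_h2 <- function(geno, y = NULL, X = NULL, liability = NULL) {
  y <- y %||% geno$samples$status
  part <- partition_snps(geno, "maf_bin")
  if (length(part$universe) == 1)
    warning("all SNPs fall in one MAF bin; degenerates to a single-GRM fit")
  .partition_fit(geno, part, y, X, liability)
}

#' Heritability partitioned by annotation (genic or cis-eQTL status)
#'
#' @inheritParams per_chromosome_h2
#' @param annotation annotation table (snp_id, genic, eqtl flags).
#' @param scheme `"genic"` or `"eqtl_threshold"`.
#' @param eqtl_threshold threshold selecting the flag column for the eqtl
#'   scheme (0.01, 0.001 or 0.0001).
#' @return a `partition_h2`.
#' @export
annotation_h2 <- function(geno, annotation, scheme = c("genic", "eqtl_threshold"),
                          eqtl_threshold = 0.01, y = NULL, X = NULL,
                          liability = NULL) {
  scheme <- match.arg(scheme)
  y <- y %||% geno$samples$status
  part <- partition_snps(geno, scheme, annotation = annotation,
                         eqtl_threshold = eqtl_threshold)
  .partition_fit(geno, part, y, X, liability)
}

#' Heritability under a rare-causal-variant model with GRM calibration
#'
#' Builds the GRM from SNPs with MAF at or below a ceiling, estimates the
#' calibration constant c by regressing its off-diagonals on the full-panel
#' GRM, adjusts the subset GRM, and fits REML on the adjusted matrix. The
#' MAF ceiling must be given explicitly.
#'
#' @inheritParams per_chromosome_h2
#' @param maf_ceiling causal-variant MAF ceiling in (0, 0.5].
#' @return list(fit -- `reml_fit` on the adjusted GRM, beta, c, n_subset).
#' @export
rare_variant_model_h2 <- function(geno, maf_ceiling, y = NULL, X = NULL,
                                  liability = NULL) {
  if (missing(maf_ceiling) || is.null(maf_ceiling))
    stop_gwherit("maf_ceiling must be supplied explicitly")
  if (maf_ceiling <= 0 || maf_ceiling > 0.5)
    stop_gwherit("maf_ceiling must be in (0, 0.5]")
  y <- y %||% geno$samples$status
  maf <- snp_maf(geno)
  sel <- which(maf <= maf_ceiling & maf > 0)
  if (!length(sel)) stop_gwherit("no SNPs with MAF <= %g", maf_ceiling)
  grm_full <- compute_grm(geno)
  grm_sub <- if (length(sel) == ncol(geno$X)) grm_full
             else compute_grm(geno, snps = sel)
  cal <- estimate_adjustment_c(grm_sub, grm_full)
  adj <- adjust_grm(grm_sub, cal$c)
  fit <- fit_reml(y, adj, X = X, liability = liability)
  list(fit = fit, beta = cal$beta, c = cal$c, c_raw = cal$c_raw,
       n_subset = length(sel))
}

#' Re-estimate heritability excluding a region or conditioning on a SNP
#'
#' `exclude` mode drops all SNPs in a (chromosome, start, end) region from
#' the GRM; `condition` mode adds the named SNP's dosage as a fixed
#' covariate (the mixed-model analogue of conditioning on an index SNP).
#'
#' @inheritParams per_chromosome_h2
#' @param region list/vector (chr, start, end), 1-based inclusive
#'   (exclude mode).
#' @param snp_id SNP to condition on (condition mode).
#' @param mode `"exclude"` or `"condition"`.
#' @return a `reml_fit`; provenance in attribute `provenance`.
#' @export
region_exclude_or_condition <- function(geno, mode = c("exclude", "condition"),
                                        region = NULL, snp_id = NULL,
                                        y = NULL, X = NULL, liability = NULL) {
  mode <- match.arg(mode)
  y <- y %||% geno$samples$status
  if (mode == "exclude") {
    if (is.null(region) || length(region) < 3)
      stop_gwherit("exclude mode needs region = (chr, start, end)")
    chr <- as.character(region[[1]])
    start <- as.numeric(region[[2]]); end <- as.numeric(region[[3]])
    inreg <- geno$snps$chr == chr & geno$snps$pos >= start & geno$snps$pos <= end
    grm <- compute_grm(geno, snps = which(!inreg))
    fit <- fit_reml(y, grm, X = X, liability = liability)
    attr(fit, "provenance") <- list(mode = "exclude", region = region,
                                    n_excluded = sum(inreg))
  } else {
    if (is.null(snp_id)) stop_gwherit("condition mode needs snp_id")
    j <- match(snp_id, geno$snps$id)
    if (is.na(j)) stop_gwherit("unknown SNP id: %s", snp_id)
    dos <- geno$X[, j]
    if (anyNA(dos)) dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
    Xc <- cbind(if (!is.null(X)) as.matrix(X), conditioned_snp = dos)
    grm <- compute_grm(geno)
    fit <- fit_reml(y, grm, X = Xc, liability = liability)
    attr(fit, "provenance") <- list(mode = "condition", snp_id = snp_id)
  }
  fit
}
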