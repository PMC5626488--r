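# Synthetic cohort generator: biallelic genotypes with an optional
# block-exchangeable LD structure, a liability-threshold disease model with
# partition-specific heritability, case-control ascertainment to a target
# case fraction, an ordinal 1-10 skin-color covariate driven by designated
# pigmentation loci, and genic/cis-eQTL annotation labels. Ground truth is
# recorded so downstream estimators can be validated.

#' Simulation configuration
#'
#' @param n_samples number of samples in the final (ascertained) cohort.
#' @param n_snps number of SNPs.
#' @param maf optional explicit per-SNP A1 frequencies in (0, 0.5]; overrides
#'   `maf_range`.
#' @param maf_range range for uniformly drawn MAFs (default 0.01-0.5).
#' @param n_chromosomes number of autosomes SNPs are spread over (1-22).
#' @param ld_block_size SNPs per correlated block; 1 = independent SNPs.
#' @param ld_r latent pairwise correlation within an LD block (Gaussian
#'   copula on the allele-generating latents).
#' @param per_partition_h2 named numeric vector: liability-scale variance
#'   fraction contributed by each SNP partition; values must sum to < 1.
#' @param causal_fraction fraction of SNPs with nonzero effect within each
#'   partition.
#' @param snp_partition optional character vector (length `n_snps`) mapping
#'   SNPs to the names of `per_partition_h2`; by default SNPs are split into
#'   equal contiguous chunks, one per partition.
#' @param prevalence_K population prevalence of the disease in (0, 1).
#' @param target_case_fraction case fraction of the ascertained sample.
#' @param skin_color_loci named numeric vector: effect (skin-color units per
#'   A1 allele) of designated pigmentation SNPs; names are SNP indices or
#'   ids. NULL = skin color is noise around the scale midpoint.
#' @param skin_color_noise_sd standard deviation of skin-color noise.
#' @param superpop_multiplier size of the simulated super-population as a
#'   multiple of `n_samples`; NULL picks the smallest multiple expected to
#'   supply the required cases and controls with 25% headroom.
#' @param genic_fraction fraction of SNPs labelled genic.
#' @param eqtl_fractions named fractions of SNPs flagged as skin cis-eQTLs at
#'   the 0.01 / 0.001 / 0.0001 significance thresholds (must be
#'   non-increasing; the flag sets are nested).
#' @param seed integer seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 2000, n_snps = 2000,
                       maf = NULL, maf_range = c(0.01, 0.5),
                       n_chromosomes = 22,
                       ld_block_size = 1, ld_r = 0.8,
                       per_partition_h2 = c(genome = 0.18),
                       causal_fraction = 0.05,
                       snp_partition = NULL,
                       prevalence_K = 0.02,
                       target_case_fraction = 0.66,
                       skin_color_loci = NULL,
                       skin_color_noise_sd = 1,
                       superpop_multiplier = NULL,
                       genic_fraction = 0.49,
                       eqtl_fractions = c("0.01" = 0.23, "0.001" = 0.10,
                                          "0.0001" = 0.06),
                       seed = 1L) {
  if (n_samples < 1 || n_snps < 1)
    stop_gwherit("n_samples and n_snps must be >= 1")
  if (!is.null(maf)) {
    if (length(maf) != n_snps) stop_gwherit("maf must have length n_snps")
    if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5))
      stop_gwherit("explicit MAFs must be finite and in (0, 0.5]")
  } else {
    if (any(!is.finite(maf_range)) || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop_gwherit("maf_range must be within (0, 0.5]")
  }
  per_partition_h2 <- unlist(per_partition_h2)  # YAML maps arrive as lists
  if (is.null(names(per_partition_h2)) || any(per_partition_h2 < 0))
    stop_gwherit("per_partition_h2 must be a named non-negative vector")
  if (sum(per_partition_h2) >= 1)
    stop_gwherit("per_partition_h2 values sum to %.3f; must be < 1",
                 sum(per_partition_h2))
  assert_prob(prevalence_K, "prevalence_K")
  assert_prob(target_case_fraction, "target_case_fraction")
  if (!is.null(snp_partition)) {
    if (length(snp_partition) != n_snps)
      stop_gwherit("snp_partition must have length n_snps")
    if (!all(snp_partition %in% names(per_partition_h2)))
      stop_gwherit("snp_partition labels must match names(per_partition_h2)")
  }
  if (ld_block_size < 1) stop_gwherit("ld_block_size must be >= 1")
  if (ld_r < 0 || ld_r >= 1) stop_gwherit("ld_r must be in [0, 1)")
  ef <- as.numeric(eqtl_fractions)
  if (any(ef < 0 | ef > 1) || is.unsorted(rev(ef)))
    stop_gwherit("eqtl_fractions must be in [0,1] and non-increasing (nested sets)")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genotype panel
#'
#' Dosages are drawn per allele from a Gaussian copula: within an LD block
#' the two allele-generating latents of adjacent SNPs share a block factor
#' with pairwise correlation `ld_r`, then are thresholded at the normal
#' quantile of the allele frequency, so adjacent SNPs are positively
#' correlated while marginal frequencies match the MAF spectrum.
#'
#' @param config a [sim_config()].
#' @param n_override optionally simulate this many samples instead of
#'   `config$n_samples` (used internally to build the super-population).
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(config, n_override = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- n_override %||% config$n_samples
  m <- config$n_snps
  p <- config$maf %||% stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(p)  # latent < thr  =>  carry one A1 allele

  draw_alleles <- function() {
    L <- config$ld_block_size
    if (L <= 1 || config$ld_r == 0) {
      Z <- matrix(stats::rnorm(n * m), n, m)
    } else {
      blocks <- rep(seq_len(ceiling(m / L)), each = L)[seq_len(m)]
      f <- matrix(stats::rnorm(n * max(blocks)), n)[, blocks, drop = FALSE]
      Z <- sqrt(config$ld_r) * f +
        sqrt(1 - config$ld_r) * matrix(stats::rnorm(n * m), n, m)
    }
    Z < matrix(thr, n, m, byrow = TRUE)
  }
  d <- draw_alleles() + draw_alleles()
  storage.mode(d) <- "double"

  chr <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- unlist(lapply(split(seq_len(m), chr), function(ix)
    cumsum(sample.int(50000L, length(ix), replace = TRUE))), use.names = FALSE)
  snps <- data.frame(id = sprintf("snp%06d", seq_len(m)),
                     chr = as.character(chr), pos = pos,
                     a1 = "A", a2 = "G")
  samples <- data.frame(fid = sprintf("F%06d", seq_len(n)),
                        iid = sprintf("I%06d", seq_len(n)),
                        sex = sample(1:2, n, replace = TRUE),
                        age = pmin(90, pmax(18, round(stats::rnorm(n, 55, 10)))))
  genotype_matrix(d, snps, samples)
}

# standardized genotypes using empirical per-SNP mean and sd
.standardize <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (any(sd == 0)) stop_gwherit("monomorphic SNP among causal set")
  sweep(sweep(X, 2, mu), 2, sd, "/")
}

#' Simulate case-control status under a liability-threshold model
#'
#' Liability = sum over partitions of (standardized genotypes x effects) +
#' normal residual; a sample is a case iff its liability exceeds the probit
#' threshold of the population prevalence K. Effects are drawn i.i.d. normal
#' and rescaled within each partition so the realized genetic variance
#' equals the target heritability exactly.
#'
#' @param geno a [genotype_matrix()], complete (no missing) at causal SNPs.
#' @param config a [sim_config()].
#' @return list with `status` (0/1 vector), `liability`, and `truth`
#'   (causal ids, liability effects, realized per-partition h2, realized
#'   prevalence, threshold, seed).
#' @export
simulate_liability_phenotype <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "phenotype"))
  m <- ncol(geno$X); n <- nrow(geno$X)
  h2 <- config$per_partition_h2
  part <- config$snp_partition %||%
    rep(names(h2), each = ceiling(m / length(h2)))[seq_len(m)]
  score <- matrix(0, n, length(h2), dimnames = list(NULL, names(h2)))
  causal <- stats::setNames(vector("list", length(h2)), names(h2))
  for (lab in names(h2)) {
    ix <- which(part == lab)
    if (h2[[lab]] == 0 || !length(ix)) { causal[[lab]] <- list(); next }
    nc <- max(1L, round(config$causal_fraction * length(ix)))
    ci <- sort(sample(ix, nc))
    if (anyNA(geno$X[, ci]))
      stop_gwherit("missing genotype calls at causal SNPs")
    Z <- .standardize(geno$X[, ci, drop = FALSE])
    u <- stats::rnorm(nc)
    g <- drop(Z %*% u)
    # rescale so realized genetic variance hits the target exactly
    g <- g * sqrt(h2[[lab]]) / stats::sd(g)
    u <- u * sqrt(h2[[lab]]) / stats::sd(drop(Z %*% u))
    score[, lab] <- g
    causal[[lab]] <- list(ids = geno$snps$id[ci], effects = u)
  }
  gtot <- rowSums(score)
  resid <- stats::rnorm(n, 0, sqrt(1 - sum(h2)))
  liab <- gtot + resid
  t0 <- stats::qnorm(1 - config$prevalence_K)
  status <- as.integer(liab > t0)
  realized_h2 <- apply(score, 2, stats::var) / stats::var(liab)
  truth <- list(causal = causal,
                realized_h2 = realized_h2,
                realized_prevalence = mean(status),
                threshold = t0,
                seed = config$seed)
  list(status = status, liability = liab, truth = truth)
}

#' Ascertain a case-control sample to a target case fraction
#'
#' @param status 0/1 vector over the source population.
#' @param target_case_fraction desired case fraction of the subset.
#' @param n size of the returned subset; defaults to the largest size the
#'   available cases and controls can support.
#' @param seed integer seed.
#' @return integer index vector into `status` with exactly
#'   `round(n * target_case_fraction)` cases, selected uniformly at random
#'   within each class; case indices first.
#' @export
ascertain_case_control <- function(status, target_case_fraction, n = NULL,
                                   seed = 1L) {
  assert_prob(target_case_fraction, "target_case_fraction")
  set.seed(seed)
  cases <- which(status == 1); controls <- which(status == 0)
  if (is.null(n))
    n <- min(floor(length(cases) / target_case_fraction),
             floor(length(controls) / (1 - target_case_fraction)))
  n_case <- round(n * target_case_fraction)
  n_ctrl <- n - n_case
  if (length(cases) < n_case)
    stop_gwherit("need %d cases but only %d available (deficit %d)",
                 n_case, length(cases), n_case - length(cases))
  if (length(controls) < n_ctrl)
    stop_gwherit("need %d controls but only %d available (deficit %d)",
                 n_ctrl, length(controls), n_ctrl - length(controls))
  c(sort(sample(cases, n_case)), sort(sample(controls, n_ctrl)))
}

#' Simulate an ordinal 1-10 skin-color score
#'
#' Skin color = round(midpoint + weighted pigmentation-locus score + noise),
#' clipped to 1..10, mirroring a self-reported 1 (very fair) to 10 (dark
#' brown) questionnaire scale. The construction is monotone in the weighted
#' locus score before noise.
#'
#' @param geno a [genotype_matrix()].
#' @param loci named numeric vector of per-A1-allele effects; names are SNP
#'   ids present in `geno`.
#' @param noise_sd noise standard deviation.
#' @param seed integer seed.
#' @return integer vector in 1..10.
#' @export
simulate_skin_color <- function(geno, loci = NULL, noise_sd = 1, seed = 1L) {
  set.seed(seed)
  n <- nrow(geno$X)
  score <- rep(5.5, n)
  if (!is.null(loci) && length(loci)) {
    ix <- match(names(loci), geno$snps$id)
    if (anyNA(ix))
      stop_gwherit("unknown pigmentation locus id: %s",
                   paste(names(loci)[is.na(ix)], collapse = ", "))
    score <- score + drop((geno$X[, ix, drop = FALSE] - 1) %*% as.numeric(loci))
  }
  val <- round(score + stats::rnorm(n, 0, noise_sd))
  as.integer(pmin(10, pmax(1, val)))
}

#' Assign genic and nested cis-eQTL annotation labels to SNPs
#'
#' Draws label sets matching the requested fractions exactly (after
#' rounding); the eQTL flag sets are nested across thresholds
#' (0.0001 within 0.001 within 0.01). A synthetic per-SNP eQTL p-value
#' consistent with the flags is included so the table can be round-tripped
#' through threshold-based flagging.
#'
#' @param snp_ids character vector of SNP ids.
#' @param genic_fraction fraction labelled genic.
#' @param eqtl_fractions named non-increasing fractions for thresholds
#'   0.01 / 0.001 / 0.0001.
#' @param seed integer seed.
#' @return data.frame (snp_id, genic, eqtl flags per threshold, eqtl_p).
#' @export
assign_annotations <- function(snp_ids, genic_fraction = 0.49,
                               eqtl_fractions = c("0.01" = 0.23,
                                                  "0.001" = 0.10,
                                                  "0.0001" = 0.06),
                               seed = 1L) {
  assert_prob(genic_fraction, "genic_fraction", open = FALSE)
  ef <- as.numeric(eqtl_fractions)
  thr <- as.numeric(names(eqtl_fractions))
  if (any(ef < 0 | ef > 1)) stop_gwherit("eqtl_fractions must be in [0, 1]")
  if (is.unsorted(rev(ef)))
    stop_gwherit("eqtl_fractions must be non-increasing so flag sets nest")
  set.seed(seed)
  m <- length(snp_ids)
  genic <- logical(m)
  genic[sample.int(m, round(genic_fraction * m))] <- TRUE
  flags <- matrix(FALSE, m, length(ef),
                  dimnames = list(NULL, sprintf("eqtl_%s", names(eqtl_fractions))))
  current <- seq_len(m)
  for (j in seq_along(ef)) {
    keep <- sample(current, min(length(current), round(ef[j] * m)))
    flags[keep, j] <- TRUE
    current <- keep
  }
  # synthetic p-values consistent with the threshold flags
  p <- stats::runif(m, max(thr), 1)
  for (j in seq_along(thr)) {
    lo <- if (j < length(thr)) thr[j + 1] else 0
    only <- flags[, j] & (if (j < length(thr)) !flags[, j + 1] else TRUE)
    p[only] <- stats::runif(sum(only), lo, thr[j])
  }
  data.frame(snp_id = snp_ids, genic = genic, flags, eqtl_p = p,
             check.names = FALSE)
}

#' Simulate a complete ascertained case-control cohort
#'
#' Simulates a super-population under the liability-threshold model,
#' ascertains it to the target case fraction, attaches skin color and
#' annotation labels, and records ground truth.
#'
#' @param config a [sim_config()].
#' @return list with elements `geno` (ascertained [genotype_matrix()] whose
#'   samples carry `status` and `skin_color`), `truth`, `annotations`, and
#'   `superpop_size`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  need_cases <- round(n * config$target_case_fraction)
  need_ctrls <- n - need_cases
  mult <- config$superpop_multiplier %||%
    max(1, ceiling(1.25 * max(need_cases / config$prevalence_K,
                              need_ctrls / (1 - config$prevalence_K)) / n))
  n_pop <- mult * n
  geno <- simulate_genotypes(config, n_override = n_pop)
  ph <- simulate_liability_phenotype(geno, config)
  idx <- ascertain_case_control(ph$status, config$target_case_fraction, n = n,
                                seed = derive_seed(config$seed, "ascertain"))
  sc_loci <- NULL
  if (!is.null(config$skin_color_loci)) {
    sc_loci <- config$skin_color_loci
    if (is.null(names(sc_loci)) || !all(names(sc_loci) %in% geno$snps$id)) {
      # allow numeric indices as names
      nm <- suppressWarnings(as.integer(names(sc_loci)))
      if (!anyNA(nm)) names(sc_loci) <- geno$snps$id[nm]
    }
  }
  cohort <- subset_geno(geno, samples = idx)
  cohort$samples$status <- ph$status[idx]
  cohort$samples$skin_color <- simulate_skin_color(
    cohort, sc_loci, config$skin_color_noise_sd,
    seed = derive_seed(config$seed, "skin"))
  ann <- assign_annotations(cohort$snps$id, config$genic_fraction,
                            config$eqtl_fractions,
                            seed = derive_seed(config$seed, "annot"))
  list(geno = cohort, truth = ph$truth, annotations = ann,
       superpop_size = n_pop, config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits PLINK bed/bim/fam, a phenotype table, a covariate table (sex, age,
#' skin color), an annotation TSV and a JSON ground-truth sidecar.
#'
#' @param cohort result of [simulate_cohort()].
#' @param prefix output path prefix.
#' @export
write_cohort <- function(cohort, prefix) {
  write_plink(cohort$geno, prefix)
  s <- cohort$geno$samples
  utils::write.table(data.frame(s$fid, s$iid, s$status),
                     paste0(prefix, ".pheno"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(s$fid, s$iid, s$age, s$sex,
               ifelse(is.na(s$skin_color), -9, s$skin_color)),
    paste0(prefix, ".covar"), quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$annotations, paste0(prefix, ".annot.tsv"),
                     quote = FALSE, row.names = FALSE, sep = "\t")
  truth <- cohort$truth
  jsonlite::write_json(truth, paste0(prefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
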