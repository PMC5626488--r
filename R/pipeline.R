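# Config-driven end-to-end runner: QC -> GRM -> PCA -> REML (liability
# scale) -> partitioned heritability -> GWAS (with/without skin color) ->
# eQTL enrichment, with every stage's parameters and seeds serialized into
# a consolidated report.

.pipeline_defaults <- list(
  qc_regime = "stringent",
  prevalence_K = 0.02,
  n_pcs_heritability = 20,
  n_pcs_association = 2,
  partitions = c("chromosome", "maf_bin"),
  gwas_skin_color = FALSE,
  enrichment = NULL,   # list(top_k, B, eqtl_threshold, skin_color)
  permutations = 0,
  seed = 1L,
  out_dir = NULL,
  simulate = NULL,     # sim_config arguments
  input_prefix = NULL
)

#' Validate and normalize a pipeline configuration
#'
#' All problems are collected and reported together, not first-failure.
#'
#' @param config a list, or path to a YAML file.
#' @return a normalized `pipeline_config` with defaults materialized, or an
#'   error listing every problem found.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config), error = function(e)
      stop_gwherit("cannot parse config: %s", conditionMessage(e)))
  }
  if (!is.list(config)) stop_gwherit("config must be a list or a YAML file path")
  errs <- character()
  unknown <- setdiff(names(config), names(.pipeline_defaults))
  if (length(unknown))
    errs <- c(errs, sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(.pipeline_defaults, config)
  if (is.null(cfg$simulate) && is.null(cfg$input_prefix))
    errs <- c(errs, "one of simulate: or input_prefix: is required")
  if (!is.null(cfg$prevalence_K) &&
      (!is.numeric(cfg$prevalence_K) || cfg$prevalence_K <= 0 || cfg$prevalence_K >= 1))
    errs <- c(errs, sprintf("prevalence_K must be in (0,1), got %s",
                            format(cfg$prevalence_K)))
  valid_schemes <- c("chromosome", "maf_bin", "genic", "eqtl_threshold")
  bad <- setdiff(cfg$partitions, valid_schemes)
  if (length(bad))
    errs <- c(errs, sprintf("unknown partition scheme(s) %s; valid: %s",
                            paste(bad, collapse = ", "),
                            paste(valid_schemes, collapse = ", ")))
  if (!cfg$qc_regime %in% c("standard", "stringent", "none"))
    errs <- c(errs, sprintf("unknown qc_regime '%s'", cfg$qc_regime))
  if (!is.null(cfg$input_prefix) &&
      !file.exists(paste0(cfg$input_prefix, ".bed")))
    errs <- c(errs, sprintf("input file %s.bed does not exist", cfg$input_prefix))
  if (length(errs))
    stop_gwherit("invalid pipeline config:\n  - %s", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on simulated or user-supplied
#' data and returns (and optionally writes) a consolidated report with all
#' heritability tables, GWAS summaries, enrichment results, seeds and
#' thresholds. Existing outputs are not overwritten unless `overwrite`.
#'
#' @param config a [validate_config()]-acceptable list or YAML path.
#' @param overwrite allow writing into a non-empty output directory.
#' @return the consolidated report (list), invisibly written as JSON when
#'   `out_dir` is configured.
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  report <- list(config = unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                 stages = list())
  if (!is.null(cfg$out_dir)) {
    if (dir.exists(cfg$out_dir) && length(dir(cfg$out_dir)) && !overwrite)
      stop_gwherit("output directory %s is non-empty; pass overwrite = TRUE",
                   cfg$out_dir)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop_gwherit("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    report$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    val
  }

  # --- data ---
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% derive_seed(cfg$seed, "simulate")
    cohort <- stage("simulate", simulate_cohort(do.call(sim_config, sim_args)))
    geno <- cohort$geno
    annotation <- cohort$annotations
    report$truth <- list(realized_h2 = cohort$truth$realized_h2,
                         realized_prevalence = cohort$truth$realized_prevalence)
  } else {
    geno <- stage("read", read_plink(cfg$input_prefix))
    annotation <- NULL
    af <- paste0(cfg$input_prefix, ".annot.tsv")
    if (file.exists(af)) annotation <- read_table(af, "annotation")
  }
  status <- geno$samples$status
  if (is.null(status) || all(is.na(status)))
    stop_gwherit("no case-control status available")
  if ((isTRUE(cfg$gwas_skin_color) ||
       isTRUE(cfg$enrichment$skin_color %||% FALSE)) &&
      is.null(geno$samples$skin_color))
    stop_gwherit("skin-color-adjusted analysis requested but data has no skin color")

  # --- QC ---
  qc <- stage("qc", {
    qcc <- qc_config(cfg$qc_regime)
    qcc$relatedness_max <- NULL  # relatedness pruning needs the GRM; below
    filter_snps(geno, qcc, status)
  })
  geno <- qc$geno
  report$qc <- list(snp_log = qc$report$log, n_snps = ncol(geno$X))

  # --- GRM + PCA ---
  grm <- stage("grm", compute_grm(geno))
  pca <- stage("pca", grm_pca(grm, k = max(cfg$n_pcs_heritability,
                                           cfg$n_pcs_association)))
  report$pca <- list(n_outliers = sum(pca$outlier))

  # --- REML on the liability scale ---
  lp <- liability_params(cfg$prevalence_K, mean(status))
  Xh <- pca$scores[, seq_len(cfg$n_pcs_heritability), drop = FALSE]
  fit <- stage("reml", fit_reml(status, grm, X = Xh, liability = lp))
  null_logL <- .reml_null_logL(status, Xh)
  report$heritability <- list(
    h2_obs = unname(fit$h2_obs), h2_obs_se = unname(fit$h2_obs_se),
    h2_liability = unname(fit$h2_liability),
    h2_liability_se = unname(fit$h2_liability_se),
    logL = fit$logL, p_lrt = lrt_pvalue(fit$logL, null_logL),
    K = lp$K, P = lp$P)

  # --- partitions ---
  report$partitions <- list()
  for (scheme in cfg$partitions) {
    ph <- stage(paste0("partition_", scheme), switch(
      scheme,
      chromosome = per_chromosome_h2(geno, status, Xh, lp),
      maf_bin = maf_bin_h2(geno, status, Xh, lp),
      genic = annotation_h2(geno, annotation, "genic", y = status, X = Xh,
                            liability = lp),
      eqtl_threshold = annotation_h2(geno, annotation, "eqtl_threshold",
                                     eqtl_threshold = 0.01, y = status,
                                     X = Xh, liability = lp)))
    report$partitions[[scheme]] <- ph$table
    if (scheme == "chromosome" && nrow(ph$table) >= 3)
      report$length_regression <- stage("length_regression", {
        lr <- h2_length_regression(ph, geno = geno)
        lr[c("slope", "intercept", "r", "p", "outliers")]
      })
  }

  # --- permutation significance of the h2 (optional) ---
  if (cfg$permutations > 0) {
    pt <- stage("h2_permutation",
                h2_permutation_test(grm, status, Xh, B = cfg$permutations,
                                    seed = derive_seed(cfg$seed, "perm")))
    report$h2_permutation <- list(p = pt$p, B = pt$B_effective)
  }

  # --- GWAS ---
  Xa <- as.data.frame(pca$scores[, seq_len(cfg$n_pcs_association), drop = FALSE])
  if (!is.null(geno$samples$age)) Xa$age <- geno$samples$age
  if (!is.null(geno$samples$sex)) Xa$sex <- geno$samples$sex
  gw <- stage("gwas", gwas_logistic(geno, status, Xa))
  report$gwas <- list(lambda = attr(gw, "lambda"),
                      n_tested = sum(gw$status != "monomorphic"),
                      top = utils::head(gw[order(gw$p), c("snp", "chr", "or", "p")], 5))
  if (isTRUE(cfg$gwas_skin_color)) {
    gws <- stage("gwas_skin", gwas_logistic(geno, status, Xa,
                                            include_skin_color = TRUE))
    report$gwas_skin_color <- list(
      lambda = attr(gws, "lambda"),
      n_dropped_skin = attr(gws, "n_dropped_skin"),
      top = utils::head(gws[order(gws$p), c("snp", "chr", "or", "p")], 5))
  }

  # --- enrichment ---
  if (!is.null(cfg$enrichment)) {
    en <- cfg$enrichment
    thr <- en$eqtl_threshold %||% 0.01
    col <- sprintf("eqtl_%s", format(thr, scientific = FALSE))
    flags <- stats::setNames(as.logical(annotation[[col]]), annotation$snp_id)
    er <- stage("enrichment", eqtl_enrichment(
      geno, status, Xa, flags, top_k = en$top_k %||% 100,
      B = en$B %||% 100, seed = derive_seed(cfg$seed, "enrich"),
      include_skin_color = isTRUE(en$skin_color)))
    report$enrichment <- list(observed = er$observed, p = er$p,
                              top_k = er$top_k, B = er$B_effective,
                              eqtl_threshold = thr,
                              skin_color = er$include_skin_color)
  }

  if (!is.null(cfg$out_dir)) {
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns",
                         force = TRUE)
  }
  report
}

# restricted log-likelihood of the no-genetic-variance model (V = sigma2 I),
# used for the LRT on the single-GRM heritability
.reml_null_logL <- function(y, X = NULL) {
  Xm <- cbind(1, if (!is.null(X)) as.matrix(X))
  n <- length(y); p <- ncol(Xm)
  r <- stats::lm.fit(Xm, y)$residuals
  s2 <- sum(r^2) / (n - p)
  -0.5 * ((n - p) * log(s2) + determinant(crossprod(Xm))$modulus[1] +
            sum(r^2) / s2)
}
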