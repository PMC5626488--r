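#' Genotype matrix container
#'
#' Holds an n x m dosage matrix (counts of the A1 allele, values 0/1/2 or NA
#' for missing calls) together with per-SNP and per-sample metadata. This is
#' the central data structure consumed by QC, GRM construction and the
#' association scan.
#'
#' @param dosage integer/numeric matrix, samples in rows, SNPs in columns;
#'   entries in \{0, 1, 2\} or NA.
#' @param snps data.frame with columns `id`, `chr` (character label, "1".."22"
#'   for autosomes), `pos` (1-based), `a1`, `a2`.
#' @param samples data.frame with columns `fid`, `iid` and optionally `sex`
#'   (1/2), `age`, `status` (0 control / 1 case) and `skin_color` (ordinal
#'   1-10, NA allowed).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  if (!is.data.frame(snps) || !all(c("id", "chr", "pos", "a1", "a2") %in% names(snps)))
    stop_gwherit("snps must be a data.frame with columns id, chr, pos, a1, a2")
  if (!is.data.frame(samples) || !all(c("fid", "iid") %in% names(samples)))
    stop_gwherit("samples must be a data.frame with columns fid, iid")
  if (nrow(samples) != nrow(dosage) || nrow(snps) != ncol(dosage))
    stop_gwherit("dosage is %d x %d but there are %d samples and %d SNPs",
                 nrow(dosage), ncol(dosage), nrow(samples), nrow(snps))
  if (anyDuplicated(snps$id)) stop_gwherit("duplicate SNP ids")
  if (anyDuplicated(samples$iid)) stop_gwherit("duplicate sample ids")
  if (any(snps$pos < 1)) stop_gwherit("SNP positions must be >= 1")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0) || any(bad > 2) || any(bad != round(bad))))
    stop_gwherit("dosages must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "double"
  dimnames(dosage) <- list(samples$iid, snps$id)
  snps$chr <- as.character(snps$chr)
  structure(list(X = dosage, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d missing calls)\n",
              nrow(x$X), ncol(x$X), sum(is.na(x$X))))
  if (!is.null(x$samples$status) && !all(is.na(x$samples$status)))
    cat(sprintf("  cases: %d, controls: %d\n",
                sum(x$samples$status == 1, na.rm = TRUE),
                sum(x$samples$status == 0, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$X)

#' A1 allele frequency per SNP, computed from non-missing calls
#' @param geno a [genotype_matrix()].
#' @return named numeric vector of A1 frequencies.
#' @export
a1_freq <- function(geno) colMeans(geno$X, na.rm = TRUE) / 2

#' Minor allele frequency per SNP
#'
#' Always computed from the non-missing dosage calls, never trusted from
#' metadata.
#' @inheritParams a1_freq
#' @return named numeric vector in \[0, 0.5\].
#' @export
snp_maf <- function(geno) {
  f <- a1_freq(geno)
  pmin(f, 1 - f)
}

#' Per-SNP missingness fraction
#' @inheritParams a1_freq
#' @export
snp_missingness <- function(geno) colMeans(is.na(geno$X))

#' Per-sample genotype call rate
#' @inheritParams a1_freq
#' @export
sample_call_rate <- function(geno) rowMeans(!is.na(geno$X))

#' Subset a genotype matrix by samples and/or SNPs
#'
#' Preserves the stored order of the retained rows/columns; never reorders.
#'
#' @inheritParams a1_freq
#' @param samples logical/integer/character index over samples (iid).
#' @param snps logical/integer/character index over SNP ids.
#' @return a [genotype_matrix()].
#' @export
subset_geno <- function(geno, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(geno$X)) else samples
  vi <- if (is.null(snps)) seq_len(ncol(geno$X)) else snps
  if (is.character(si)) si <- match(si, geno$samples$iid)
  if (is.character(vi)) vi <- match(vi, geno$snps$id)
  if (anyNA(si)) stop_gwherit("unknown sample id in subset")
  if (anyNA(vi)) stop_gwherit("unknown SNP id in subset")
  genotype_matrix(geno$X[si, vi, drop = FALSE],
                  geno$snps[vi, , drop = FALSE],
                  geno$samples[si, , drop = FALSE])
}
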