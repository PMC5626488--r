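# Whitespace-delimited table readers for phenotype / covariate / annotation /
# SNP-list inputs. Per-sample tables are keyed by the first two columns
# (FID, IID); annotation tables are keyed by SNP id. Missing-value codes -9
# and NA are normalized to NA.

.normalize_missing <- function(x) {
  x[x %in% c("-9", "NA", "")] <- NA
  x
}

#' Read a keyed analysis table
#'
#' @param path file path, whitespace- or tab-delimited, with a header for
#'   `annotation` tables and no header (FID IID value...) for per-sample
#'   tables.
#' @param schema one of `"phenotype"` (FID IID status), `"covariate"`
#'   (FID IID followed by numeric covariates; a column named or positioned as
#'   skin color must lie in 1-10), `"annotation"` (header row; column `snp_id`
#'   plus logical/0-1 flags or an `eqtl_p` column), `"snp_list"` (one SNP id
#'   per line, optionally chr/pos columns).
#' @param skin_color_col for `covariate` tables, the index (among the value
#'   columns) holding the ordinal 1-10 skin-color score, or NULL.
#' @return a data.frame; the number of missing values normalized per column
#'   is attached as attribute `n_missing`.
#' @export
read_table <- function(path, schema = c("phenotype", "covariate", "annotation",
                                        "snp_list"),
                       skin_color_col = NULL) {
  schema <- match.arg(schema)
  if (schema == "annotation") {
    tab <- utils::read.table(path, header = TRUE, colClasses = NA,
                             stringsAsFactors = FALSE)
    if (!"snp_id" %in% names(tab))
      stop_gwherit("annotation table must have a snp_id column")
    flags <- intersect(c("eqtl_0.01", "eqtl_0.001", "eqtl_0.0001"), names(tab))
    if ("eqtl_p" %in% names(tab)) {
      for (thr in c(0.01, 0.001, 1e-4))
        tab[[sprintf("eqtl_%s", format(thr, scientific = FALSE))]] <- tab$eqtl_p < thr
      flags <- c("eqtl_0.01", "eqtl_0.001", "eqtl_0.0001")
    }
    if (length(flags) >= 2) {
      for (i in seq_len(length(flags) - 1)) {
        a <- as.logical(tab[[flags[i + 1]]]); b <- as.logical(tab[[flags[i]]])
        if (any(a & !b, na.rm = TRUE))
          stop_gwherit("eQTL flags are not nested: %s is not a subset of %s",
                       flags[i + 1], flags[i])
      }
    }
    return(tab)
  }
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (schema == "snp_list") {
    names(tab)[1] <- "snp_id"
    if (ncol(tab) >= 3) names(tab)[2:3] <- c("chr", "pos")
    if (ncol(tab) >= 3) tab$pos <- as.integer(tab$pos)
    return(tab)
  }
  if (ncol(tab) < 3)
    stop_gwherit("%s table needs at least 3 columns (FID IID value...)", schema)
  names(tab)[1:2] <- c("fid", "iid")
  n_missing <- 0L
  for (j in 3:ncol(tab)) {
    v <- .normalize_missing(tab[[j]])
    n_missing <- n_missing + sum(is.na(v))
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v)))
      stop_gwherit("non-numeric value in column %d of %s (first bad row: %d)",
                   j, path, which(is.na(num) & !is.na(v))[1])
    tab[[j]] <- num
  }
  if (schema == "phenotype") {
    names(tab)[3] <- "status"
    bad <- which(!is.na(tab$status) & !tab$status %in% c(0, 1, 2))
    if (length(bad))
      stop_gwherit("phenotype values must be 0/1 (or 1/2 coded), row %d is %g",
                   bad[1], tab$status[bad[1]])
    if (all(tab$status %in% c(1, 2, NA))) tab$status <- tab$status - 1
  }
  if (schema == "covariate" && !is.null(skin_color_col)) {
    j <- 2L + skin_color_col
    names(tab)[j] <- "skin_color"
    sc <- tab[[j]]
    bad <- which(!is.na(sc) & (sc < 1 | sc > 10 | sc != round(sc)))
    if (length(bad))
      stop_gwherit("skin color must be an integer in 1-10; row %d has %g",
                   bad[1], sc[bad[1]])
  }
  attr(tab, "n_missing") <- n_missing
  tab
}
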