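# PLINK binary (bed/bim/fam) and GCTA binary GRM readers/writers.
#
# bed layout: magic bytes 0x6C 0x1B, mode byte 0x01 (SNP-major), then
# ceil(n/4) bytes per SNP, 4 samples per byte, 2 bits each, low bits first.
# 2-bit codes (dosage = count of A1): 00 -> hom A1 (2), 01 -> missing,
# 10 -> het (1), 11 -> hom A2 (0).

.bed_code_from_dosage <- c(`2` = 0L, `1` = 2L, `0` = 3L)   # NA -> 1L
.dosage_from_bed_code <- c(2, NA, 1, 0)                    # index = code + 1

#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam`
#'   are written.
#' @return invisibly, the prefix.
#' @export
write_plink <- function(geno, prefix) {
  n <- nrow(geno$X); m <- ncol(geno$X)
  bim <- data.frame(chr = geno$snps$chr, id = geno$snps$id, cm = 0,
                    pos = geno$snps$pos, a1 = geno$snps$a1, a2 = geno$snps$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  s <- geno$samples
  pheno <- if (is.null(s$status)) rep(-9L, n) else ifelse(is.na(s$status), -9L, s$status + 1L)
  sex <- if (is.null(s$sex)) rep(0L, n) else ifelse(is.na(s$sex), 0L, s$sex)
  fam <- data.frame(fid = s$fid, iid = s$iid, pat = 0L, mat = 0L,
                    sex = sex, pheno = pheno)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  code <- matrix(1L, nrow = 4L * ceiling(n / 4), ncol = m)  # pad with "missing"
  d <- geno$X
  cd <- matrix(1L, n, m)
  cd[!is.na(d) & d == 2] <- 0L
  cd[!is.na(d) & d == 1] <- 2L
  cd[!is.na(d) & d == 0] <- 3L
  code[seq_len(n), ] <- cd
  # pack 4 codes per byte, low bit-pair = first sample
  i1 <- seq(1L, nrow(code), by = 4L)
  bytes <- code[i1, , drop = FALSE] + 4L * code[i1 + 1L, , drop = FALSE] +
    16L * code[i1 + 2L, , drop = FALSE] + 64L * code[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam file set
#'
#' Only the SNP-major dialect (mode byte 0x01) is supported. Sample and SNP
#' order is taken from the fam/bim files and never altered.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` trio.
#' @return a [genotype_matrix()]. The fam phenotype column (1/2 coding) is
#'   mapped to `status` 0/1; -9 and 0 become NA.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chr", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = file.info(paste0(prefix, ".bed"))$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B))
    stop_gwherit("not a PLINK bed file: bad magic bytes")
  if (raw[3] == as.raw(0x00))
    stop_gwherit("sample-major bed files (mode byte 0x00) are not supported")
  if (raw[3] != as.raw(0x01))
    stop_gwherit("unrecognized bed mode byte: 0x%02x", as.integer(raw[3]))
  bps <- ceiling(n / 4)
  expected <- 3 + bps * m
  if (length(raw) != expected)
    stop_gwherit("bed payload size mismatch: expected %d bytes (n=%d, m=%d), found %d",
                 expected, n, m, length(raw))
  bytes <- as.integer(raw[-(1:3)])
  codes <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L, (bytes %/% 64L) %% 4L)
  dim(codes) <- c(4L * bps, m)
  d <- matrix(.dosage_from_bed_code[codes[seq_len(n), , drop = FALSE] + 1L], n, m)
  status <- ifelse(fam$pheno %in% c(1, 2), fam$pheno - 1, NA)
  samples <- data.frame(fid = fam$fid, iid = fam$iid,
                        sex = ifelse(fam$sex %in% c(1, 2), fam$sex, NA),
                        status = status)
  genotype_matrix(d, bim[c("id", "chr", "pos", "a1", "a2")], samples)
}

#' Write a GRM in the GCTA binary dialect
#'
#' Writes `prefix.grm.bin` (32-bit floats, lower triangle including the
#' diagonal, row-major), `prefix.grm.N.bin` (pairwise SNP counts, same
#' layout) and `prefix.grm.id` (FID IID, tab-separated).
#'
#' @param grm a [grm][compute_grm] object.
#' @param prefix output path prefix.
#' @export
write_grm_bin <- function(grm, prefix) {
  n <- length(grm$ids)
  lt <- function(M) M[upper.tri(M, diag = TRUE)]  # col-major upper == row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt(t(grm$A))), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(lt(t(grm$N))), con, size = 4)
  close(con)
  utils::write.table(data.frame(grm$ids, grm$ids),
                     paste0(prefix, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read a GRM in the GCTA binary dialect
#'
#' @param prefix path prefix of the `.grm.bin`/`.grm.N.bin`/`.grm.id` trio.
#' @return a [grm][compute_grm] object (calibration state unset).
#' @export
read_grm_bin <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           colClasses = "character")
  if (anyDuplicated(ids[[2]]))
    stop_gwherit("duplicate sample ids in %s.grm.id", prefix)
  n <- nrow(ids)
  sz <- file.info(paste0(prefix, ".grm.bin"))$size
  if (sz != 4 * n * (n + 1) / 2)
    stop_gwherit("grm.bin size %d is not 4*n(n+1)/2 for n=%d ids", sz, n)
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = n * (n + 1) / 2, size = 4)
  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- vals
  A <- t(A)
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  N <- matrix(0, n, n)
  nf <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nf)) {
    nv <- readBin(nf, "numeric", n = n * (n + 1) / 2, size = 4)
    N[upper.tri(N, diag = TRUE)] <- nv
    N <- t(N)
    N[upper.tri(N)] <- t(N)[upper.tri(N)]
  } else N[] <- NA
  new_grm(A, N, ids[[2]],
          n_snps = if (file.exists(nf)) max(N) else NA_real_)
}
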