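#' Read a PLINK binary genotype trio
#'
#' Reads `<prefix>.bed` / `<prefix>.bim` / `<prefix>.fam` into a
#' [genotype_dataset()].  Only the SNP-major layout (magic bytes
#' `0x6C 0x1B`, mode byte `0x01`) is supported; genotypes are decoded as
#' counts of the `.bim` A1 allele, with the PLINK missing code mapped to
#' `NA`.  The on-disk phenotype coding 1 = control / 2 = case is mapped
#' to 0/1 in memory.
#'
#' @param prefix path prefix of the trio (no extension).
#' @return A `GenotypeDataset`.
#' @seealso [write_plink()]
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (f in paths) if (!file.exists(f)) stop("file not found: ", f)

  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"))
  bim_cols <- c("chrom", "snp_id", "cm", "pos_bp", "allele1", "allele2")
  bim <- if (file.size(paths[2]) > 0) {
    read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
               colClasses = c("character", "character", "numeric",
                              "integer", "character", "character"),
               col.names = bim_cols)
  } else {
    data.frame(chrom = character(0), snp_id = character(0), cm = numeric(0),
               pos_bp = integer(0), allele1 = character(0),
               allele2 = character(0))
  }
  n <- nrow(fam)
  p <- nrow(bim)
  if (!all(fam$pheno %in% c(1L, 2L)))
    stop("non-binary phenotype in .fam (expected 1 = control, 2 = case)")

  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paths[1], "raw", n = 3 + p * bytes_per_snp + 1)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", paths[1])
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported (mode byte != 0x01)")
  payload <- raw[-(1:3)]
  if (length(payload) != p * bytes_per_snp)
    stop(sprintf(".bed payload has %d bytes; expected %d for %d samples x %d SNPs",
                 length(payload), p * bytes_per_snp, n, p))

  # 2-bit codes packed from the least significant bit:
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  if (p == 0) {
    g <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    lut <- plink_decode_table()
    codes <- lut[as.integer(payload) + 1L, , drop = FALSE]  # (p*bps) x 4
    g <- matrix(t(codes), nrow = 4 * bytes_per_snp)[seq_len(n), , drop = FALSE]
  }
  snps <- bim[, c("snp_id", "chrom", "pos_bp", "allele1", "allele2")]
  genotype_dataset(g, snps, fam$pheno - 1L)
}

# 256 x 4 lookup: byte value -> four A1 counts (NA = missing).
plink_decode_table <- function() {
  map <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  b <- 0:255
  cbind(map[bitwAnd(b, 3L) + 1L],
        map[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
        map[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
        map[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
}

#' Write a PLINK binary genotype trio
#'
#' Inverse of [read_plink()]: writes `<prefix>.bed` (SNP-major),
#' `<prefix>.bim` and `<prefix>.fam`.  Genotypes must be hard calls in
#' `{0, 1, 2, NA}`; the phenotype is written as 1 = control / 2 = case.
#'
#' @param ds a `GenotypeDataset`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(ds, prefix) {
  g <- ds$genotypes
  if (!all(g %in% c(0, 1, 2) | is.na(g)))
    stop("write_plink requires hard-call genotypes in {0, 1, 2, NA}")
  n <- ds$n
  p <- ds$p
  code <- matrix(0L, nrow = n, ncol = p)          # 2-bit codes
  code[!is.na(g) & g == 2] <- 0L
  code[!is.na(g) & g == 1] <- 2L
  code[!is.na(g) & g == 0] <- 3L
  code[is.na(g)] <- 1L
  pad <- 4 * ceiling(n / 4) - n
  if (pad > 0) code <- rbind(code, matrix(3L, pad, p))  # pad with hom A2
  # pack 4 samples per byte, LSB first
  i1 <- seq(1, nrow(code), by = 4)
  bytes <- code[i1, , drop = FALSE] +
    bitwShiftL(code[i1 + 1, , drop = FALSE], 2L) +
    bitwShiftL(code[i1 + 2, , drop = FALSE], 4L) +
    bitwShiftL(code[i1 + 3, , drop = FALSE], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (length(bytes)) writeBin(as.raw(as.vector(bytes)), con)

  bim <- data.frame(chrom = ds$snps$chrom, snp_id = ds$snps$snp_id,
                    cm = rep(0, p), pos_bp = ds$snps$pos_bp,
                    allele1 = ds$snps$allele1, allele2 = ds$snps$allele2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
                    pid = 0L, mid = 0L, sex = 0L, pheno = ds$phenotype + 1L)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
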