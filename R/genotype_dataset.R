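#' Assemble a genotype dataset
#'
#' The container consumed by every stage of the package: an `n x p`
#' additive-coded genotype matrix (counts of allele 1, `NA` = missing),
#' per-SNP metadata and a binary phenotype.
#'
#' @param genotypes numeric matrix, `n` individuals by `p` SNPs, entries
#'   in `{0, 1, 2, NA}` (fractional values are allowed after mean
#'   imputation).
#' @param snps data frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `allele1`, `allele2`; one row per SNP.  A `maf` column is
#'   (re)computed from the genotypes.
#' @param phenotype integer vector of length `n`; 0 = control, 1 = case.
#' @return An object of class `GenotypeDataset`: a list with elements
#'   `genotypes`, `snps`, `phenotype`, `n`, `p`.
#' @examples
#' g <- matrix(c(0, 1, 2, 1, 0, 2), nrow = 3)
#' snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
#'                    pos_bp = c(100L, 200L), allele1 = "A", allele2 = "G")
#' ds <- genotype_dataset(g, snps, c(0L, 1L, 1L))
#' ds$p
#' @export
genotype_dataset <- function(genotypes, snps, phenotype) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  stopifnot(nrow(snps) == p, length(phenotype) == n)
  phenotype <- as.integer(phenotype)
  if (!all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be binary (0 = control, 1 = case)")
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "chrom", "pos_bp", "allele1", "allele2")
  miss <- setdiff(req, names(snps))
  if (length(miss)) stop("snps is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(snps$snp_id)) stop("snp_id values must be unique")
  if (any(snps$pos_bp <= 0)) stop("pos_bp must be positive")
  snps$maf <- compute_maf(genotypes)
  rownames(snps) <- NULL
  colnames(genotypes) <- snps$snp_id
  structure(list(genotypes = genotypes, snps = snps,
                 phenotype = phenotype, n = n, p = p),
            class = "GenotypeDataset")
}

#' @export
print.GenotypeDataset <- function(x, ...) {
  cat(sprintf("GenotypeDataset: %d individuals x %d SNPs (%d cases, %d controls)\n",
              x$n, x$p, sum(x$phenotype == 1L), sum(x$phenotype == 0L)))
  nm <- sum(is.na(x$genotypes))
  if (nm > 0) cat(sprintf("  %d missing genotype calls\n", nm))
  invisible(x)
}

# Minor allele frequency per column, from non-missing hard calls.
compute_maf <- function(genotypes) {
  f <- colMeans(genotypes, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

# Subset SNP columns, keeping bookkeeping of original column indices
# (used after hide_causal so detections can be scored in the original
# index space).
subset_snps <- function(ds, keep) {
  orig <- attr(ds, "orig_index")
  if (is.null(orig)) orig <- seq_len(ds$p)
  out <- genotype_dataset(ds$genotypes[, keep, drop = FALSE],
                          ds$snps[keep, , drop = FALSE], ds$phenotype)
  attr(out, "orig_index") <- orig[keep]
  out
}

# Original-space column indices of a (possibly subset) dataset.
orig_index <- function(ds) {
  orig <- attr(ds, "orig_index")
  if (is.null(orig)) seq_len(ds$p) else orig
}
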