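#' Quality-control filter on minor allele frequency and Hardy-Weinberg
#'
#' Keeps exactly the SNPs with MAF >= `maf_min` and a Hardy-Weinberg
#' goodness-of-fit p-value >= `hwe_alpha`; column order is preserved.
#' The HWE test is a 1-df chi-squared goodness-of-fit on the pooled
#' (cases + controls) genotype counts against the expected
#' \eqn{(q^2, 2pq, p^2)} proportions, with the allele frequency
#' estimated from the same counts.  MAF and HWE counts use non-missing
#' hard calls only.
#'
#' @param ds a `GenotypeDataset` (hard calls; missing allowed).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_alpha HWE p-value threshold (default 1e-4).
#' @return The filtered `GenotypeDataset`; may have `p = 0`.
#' @export
qc_filter <- function(ds, maf_min = 0.01, hwe_alpha = 1e-4) {
  stopifnot(maf_min >= 0, maf_min < 0.5, hwe_alpha > 0, hwe_alpha < 1)
  maf <- compute_maf(ds$genotypes)
  maf[is.na(maf)] <- 0
  keep_maf <- maf >= maf_min
  hwe_p <- apply(ds$genotypes, 2, hwe_pvalue)
  keep <- keep_maf & (hwe_p >= hwe_alpha | is.na(hwe_p))
  subset_snps(ds, which(keep))
}

# 1-df chi-squared HWE goodness-of-fit p-value from a genotype column.
# Returns NA for monomorphic columns (no test possible; the MAF filter
# removes them anyway).
hwe_pvalue <- function(g) {
  g <- g[!is.na(g)]
  n0 <- sum(g == 0); n1 <- sum(g == 1); n2 <- sum(g == 2)
  N <- n0 + n1 + n2
  if (N == 0) return(NA_real_)
  f1 <- (2 * n2 + n1) / (2 * N)          # frequency of allele 1
  if (f1 <= 0 || f1 >= 1) return(NA_real_)
  expd <- N * c((1 - f1)^2, 2 * f1 * (1 - f1), f1^2)
  stat <- sum((c(n0, n1, n2) - expd)^2 / expd)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Mean-impute missing genotypes
#'
#' Replaces every missing entry of a SNP column by that column's mean
#' genotype among non-missing individuals; non-missing entries are
#' unchanged.  Downstream model fitting requires a complete matrix.
#'
#' @param ds a `GenotypeDataset`.
#' @return A `GenotypeDataset` with no missing entries.
#' @export
impute_missing <- function(ds) {
  g <- ds$genotypes
  nmiss <- colSums(is.na(g))
  if (any(nmiss == ds$n))
    stop("SNP(s) with all genotypes missing: ",
         paste(ds$snps$snp_id[nmiss == ds$n], collapse = ", "))
  if (any(nmiss > 0)) {
    mu <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  out <- genotype_dataset(g, ds$snps, ds$phenotype)
  out$snps$maf <- ds$snps$maf  # keep hard-call MAF
  attr(out, "orig_index") <- attr(ds, "orig_index")
  out
}
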