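# Small dataset constructors shared across tests.

# Wrap a genotype matrix and phenotype with minimal SNP metadata.
mk_dataset <- function(g, y, chrom = NULL) {
  g <- as.matrix(g)
  p <- ncol(g)
  if (is.null(chrom)) chrom <- rep("1", p)
  snps <- data.frame(snp_id = sprintf("s%03d", seq_len(p)),
                     chrom = as.character(chrom),
                     pos_bp = stats::ave(seq_len(p), chrom, FUN = seq_along) * 100L,
                     allele1 = rep("A", p), allele2 = rep("G", p),
                     stringsAsFactors = FALSE)
  genotype_dataset(g, snps, y)
}

# Random hard-call dataset under Hardy-Weinberg, independent SNPs.
random_dataset <- function(n, p, maf = NULL, seed = NULL, case_prob = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(p, 0.1, 0.5)
  g <- vapply(maf, function(m) rbinom(n, 2, m), numeric(n))
  mk_dataset(g, rbinom(n, 1, case_prob))
}

# Independent R oracle for the Firth objective: penalized log-likelihood
# at beta, computed from first principles (no shared code with src/).
oracle_pll <- function(X, y, beta) {
  eta <- as.numeric(X %*% beta)
  pii <- plogis(eta)
  W <- pii * (1 - pii)
  ll <- sum(y * eta - log1p(exp(eta)))
  ld <- determinant(crossprod(X * sqrt(W)), logarithm = TRUE)$modulus
  ll + 0.5 * as.numeric(ld)
}

# Generic-optimizer oracle for the Firth fit (BFGS on -oracle_pll).
oracle_firth_fit <- function(X, y, start = NULL) {
  if (is.null(start)) start <- numeric(ncol(X))
  o <- optim(start, function(b) -oracle_pll(X, y, b), method = "BFGS",
             control = list(reltol = 1e-15, maxit = 500))
  o$par
}
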