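#' Cochran-Armitage trend test
#'
#' 1-df chi-squared test for a linear trend of case probability in the
#' additive genotype dose, with scores (0, 1, 2):
#' \deqn{\chi^2 = \frac{N\,(N\sum_i s_i r_i - R \sum_i s_i n_i)^2}
#'   {R\,(N-R)\,\big(N \sum_i s_i^2 n_i - (\sum_i s_i n_i)^2\big)}}
#' where \eqn{r_i}/\eqn{n_i} are the case/total counts at genotype
#' \eqn{s_i} and \eqn{R} the total number of cases.  This common form
#' (no \eqn{N-1} correction) is algebraically the Rao score statistic of
#' the logistic trend model at the fitted intercept-only null.
#'
#' @param ds a `GenotypeDataset` (complete hard calls for the tested SNP).
#' @param snp SNP column index.
#' @return List with `statistic` and upper-tail `p`.
#' @export
cochran_armitage <- function(ds, snp) {
  g <- ds$genotypes[, snp]
  if (anyNA(g)) g <- g[!is.na(g)]
  y <- ds$phenotype[!is.na(ds$genotypes[, snp])]
  if (length(unique(g)) < 2) stop("constant genotype column: SNP ", snp)
  stat <- ca_stat(g, y)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Trend statistic on raw vectors (vectorized helper; also used for the
# marginal ordering).  Works for dose values beyond {0,1,2} as well,
# reducing to U^2 / (pq * Sxx).
ca_stat <- function(g, y) {
  N <- length(y)
  R <- sum(y)
  U <- sum(g * y) - R * sum(g) / N
  Sxx <- sum(g^2) - sum(g)^2 / N
  V <- (R / N) * (1 - R / N) * Sxx
  if (V <= 0) return(0)
  U^2 / V
}

#' Rao score test for adding one SNP to a fitted logistic model
#'
#' Computes the 1-df efficient-score statistic \eqn{U^2/V} for the
#' candidate column \eqn{z}, where \eqn{U = z^T(y - \hat\pi)} and, by
#' default, \eqn{V} is the efficient information of \eqn{z} after
#' projecting out the fitted design under weights
#' \eqn{\hat\pi(1-\hat\pi)}.  No refit of the enlarged model is needed,
#' which is what makes the conditional candidate ordering of the search
#' cheap.
#'
#' @param ds a `GenotypeDataset`.
#' @param fit a `ModelFit` to condition on (the SNP must not be in it).
#' @param snp candidate SNP column index.
#' @param efficient if `FALSE`, use the naive variance \eqn{z^T W z}
#'   without projection (faster, anti-conservative; default `TRUE`).
#' @return The score statistic (>= 0).  A candidate collinear with the
#'   fitted design returns 0 with a warning.
#' @export
score_test <- function(ds, fit, snp, efficient = TRUE) {
  if (snp %in% fit$snp_indices) stop("SNP ", snp, " already in the model")
  as.numeric(score_stats(ds, fit, snp, efficient = efficient))
}

# Vectorized score statistics for many candidate columns at once.
score_stats <- function(ds, fit, snps, efficient = TRUE) {
  X <- design_matrix(ds, fit$snp_indices)
  pi_hat <- fit$fitted
  w <- pi_hat * (1 - pi_hat)
  Z <- ds$genotypes[, snps, drop = FALSE]
  if (anyNA(Z)) stop("genotypes contain missing values; run impute_missing() first")
  U <- as.numeric(crossprod(Z, ds$phenotype - pi_hat))
  V <- as.numeric(colSums(Z^2 * w))
  if (efficient) {
    B <- crossprod(X * w, Z)                       # (k+1) x q
    XtWX <- crossprod(X * sqrt(w))
    R <- chol(XtWX)
    S <- backsolve(R, forwardsolve(t(R), B))
    V <- V - colSums(B * S)
  }
  stat <- unname(ifelse(V > 1e-10, U^2 / pmax(V, 1e-300), 0))
  if (any(V <= 1e-10))
    warning("candidate column(s) collinear with the fitted design; statistic set to 0")
  stat
}

#' Order candidate SNPs for the directed forward search
#'
#' Produces the pre-specified candidate order the fast stepwise search
#' walks: by descending marginal Cochran-Armitage statistic
#' (`method = "marginal"`) or by descending conditional score statistic
#' given `fit` (`method = "conditional"`).  Ties break by ascending SNP
#' index.  SNPs already in `fit` are excluded.
#'
#' @inheritParams score_test
#' @param method `"marginal"` or `"conditional"`.
#' @return A `SnpOrdering`: list with `order` (permutation of the
#'   non-model SNP indices) and `statistics` (matching, nonincreasing).
#' @export
order_snps <- function(ds, fit, method = c("marginal", "conditional")) {
  method <- match.arg(method)
  cand <- setdiff(seq_len(ds$p), fit$snp_indices)
  if (!length(cand))
    return(structure(list(order = integer(0), statistics = numeric(0)),
                     class = "SnpOrdering"))
  stats <- if (method == "marginal") {
    y <- ds$phenotype
    vapply(cand, function(j) ca_stat(ds$genotypes[, j], y), numeric(1))
  } else {
    suppressWarnings(score_stats(ds, fit, cand))
  }
  o <- order(-stats, cand)
  structure(list(order = cand[o], statistics = stats[o]), class = "SnpOrdering")
}

#' Benjamini-Hochberg step-up rule
#'
#' Rejects the `i*` smallest p-values, where `i*` is the largest `i`
#' with \eqn{p_{(i)} \le i q / m}; controls the FDR at level `q` for
#' independent or positively dependent tests.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q target FDR level.
#' @return Integer vector of rejected indices (possibly empty).
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  which(p.adjust(pvals, method = "BH") <= q)
}

#' Single-marker scan with principal-component adjustment
#'
#' The standard single-SNP comparator: for each SNP an ordinary
#' (non-Firth) logistic regression of status on that SNP plus the top
#' `n_pcs` principal components of the column-standardized genotype
#' matrix, tested by the 1-df likelihood-ratio test against the
#' PC-only null; Benjamini-Hochberg at level `q` decides detections.
#' SNPs whose logistic fit separates (non-finite LRT) fall back to the
#' Cochran-Armitage trend p-value.
#'
#' @param ds a complete `GenotypeDataset`.
#' @param q Benjamini-Hochberg FDR level (default 0.05).
#' @param n_pcs number of genotype principal components used as
#'   covariates (default 4).
#' @return List with `selected` (rejected SNP indices), `p` (per-SNP
#'   p-values) and `table` (snp_id, statistic, p, rejected).
#' @export
single_marker_scan <- function(ds, q = 0.05, n_pcs = 4) {
  stopifnot(n_pcs >= 0, n_pcs < ds$n)
  G <- ds$genotypes
  if (anyNA(G)) stop("genotypes contain missing values; run impute_missing() first")
  y <- ds$phenotype
  if (n_pcs > 0) {
    sds <- apply(G, 2, sd)
    Gs <- scale(G[, sds > 0, drop = FALSE])
    pcs <- prcomp(Gs, center = FALSE, scale. = FALSE, rank. = n_pcs)$x
    X0 <- cbind(1, pcs)
  } else {
    X0 <- matrix(1, ds$n, 1)
  }
  fit0 <- glm.fit(X0, y, family = binomial())
  dev0 <- fit0$deviance
  lrt <- pv <- numeric(ds$p)
  for (j in seq_len(ds$p)) {
    fj <- suppressWarnings(glm.fit(cbind(X0, G[, j]), y, family = binomial()))
    lrt[j] <- dev0 - fj$deviance
    pj <- pchisq(lrt[j], df = 1, lower.tail = FALSE)
    if (!is.finite(pj) || !fj$converged || any(abs(fj$coefficients) > 15)) {
      # separation fallback: trend-test p-value
      pj <- tryCatch(cochran_armitage(ds, j)$p, error = function(e) 1)
    }
    pv[j] <- pj
  }
  sel <- benjamini_hochberg(pv, q)
  tab <- data.frame(snp_id = ds$snps$snp_id, statistic = lrt, p = pv,
                    rejected = seq_len(ds$p) %in% sel)
  list(selected = sel, p = pv, table = tab)
}
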