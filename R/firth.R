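#' Fit a Firth-penalized logistic regression model
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' \deqn{l^*(\beta) = l(\beta) + \tfrac12 \log\det I(\beta)}
#' for the logistic model of case/control status on the selected SNP
#' columns (plus intercept), where \eqn{I(\beta) = X^T W X} is the
#' Fisher information.  The penalty removes the first-order bias of the
#' maximum-likelihood estimate and keeps all coefficients finite even
#' under complete separation, which occurs routinely when scanning many
#' SNP combinations.
#'
#' Newton/IRLS iterations are run on the Firth-modified score
#' \eqn{X^T(y - \pi + h(1/2 - \pi))} with step-halving whenever a step
#' would decrease the penalized likelihood; convergence is declared when
#' the modified score's sup-norm drops below `tol`.
#'
#' @param ds a [genotype_dataset()].
#' @param snp_indices integer vector of SNP column indices to include
#'   (may be empty for the intercept-only model).
#' @param tol convergence tolerance on the modified score (default 1e-8).
#' @param max_iter iteration cap (default 50); on hitting it the fit is
#'   returned with `converged = FALSE`.
#' @param beta_init optional warm-start coefficient vector (length
#'   `k + 1`, intercept first).
#' @return An object of class `ModelFit`: list with `snp_indices`,
#'   `beta` (intercept first), `penalized_loglik`, `converged`,
#'   `iterations`, `hat_diag`, `fitted`.
#' @examples
#' ds <- genotype_dataset(matrix(rbinom(40, 2, 0.3), 20),
#'                        data.frame(snp_id = c("a", "b"), chrom = "1",
#'                                   pos_bp = 1:2, allele1 = "A", allele2 = "C"),
#'                        rep(0:1, 10))
#' fit <- firth_fit(ds, 1L)
#' fit$beta
#' @export
firth_fit <- function(ds, snp_indices = integer(0), tol = 1e-8,
                      max_iter = 50L, beta_init = NULL) {
  snp_indices <- sort(unique(as.integer(snp_indices)))
  X <- design_matrix(ds, snp_indices)
  k <- length(snp_indices)
  if (k + 1L > ds$n) stop("more parameters than observations")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(beta_init)) beta_init <- numeric(k + 1L)
  stopifnot(length(beta_init) == k + 1L)
  res <- .firth_fit_cpp(X, as.double(ds$phenotype), as.double(beta_init),
                        tol, as.integer(max_iter))
  structure(list(snp_indices = snp_indices,
                 beta = as.numeric(res$beta),
                 penalized_loglik = res$penalized_loglik,
                 converged = res$converged,
                 iterations = res$iterations,
                 hat_diag = as.numeric(res$hat_diag),
                 fitted = as.numeric(res$fitted)),
            class = "ModelFit")
}

#' Penalized log-likelihood at fixed coefficients
#'
#' Evaluates \eqn{l(\beta) + \tfrac12\log\det X^T W X} for the model in
#' `fit` at `fit$beta`, without refitting.
#'
#' @inheritParams firth_fit
#' @param fit a `ModelFit` (any finite `beta`; need not be an optimum).
#' @return The penalized log-likelihood (natural-log scale).
#' @export
penalized_loglik <- function(ds, fit) {
  stopifnot(inherits(fit, "ModelFit"), all(is.finite(fit$beta)))
  X <- design_matrix(ds, fit$snp_indices)
  .firth_pll_cpp(X, as.double(ds$phenotype), as.double(fit$beta))
}

#' @export
print.ModelFit <- function(x, ...) {
  cat(sprintf("ModelFit: %d SNP(s), penalized logLik %.4f, %s in %d iteration(s)\n",
              length(x$snp_indices), x$penalized_loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  if (length(x$snp_indices))
    cat("  SNP columns:", paste(x$snp_indices, collapse = ", "), "\n")
  invisible(x)
}

# Intercept + selected SNP columns; errors on missing genotypes because
# the fitters require a complete matrix (run impute_missing first).
design_matrix <- function(ds, snp_indices) {
  cols <- ds$genotypes[, snp_indices, drop = FALSE]
  if (anyNA(cols))
    stop("genotypes contain missing values; run impute_missing() first")
  X <- cbind(`(Intercept)` = 1, cols)
  colnames(X) <- c("(Intercept)", ds$snps$snp_id[snp_indices])
  X
}

# Null (intercept-only) Firth fit; starting point of the search.
null_fit <- function(ds, ...) firth_fit(ds, integer(0), ...)
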