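#' Model-selection criterion configuration
#'
#' Bundles the tunable constants of the two criteria used by the
#' stepwise search: the target criterion mBIC2 (constant `c`, default 4)
#' and the milder mBIC_E used in the early search rounds (prior expected
#' model size `E`, default 60, hence "mBIC_60").
#'
#' @param name `"mBIC2"` or `"mBIC_E"`.
#' @param c positive constant of mBIC2 (default 4).
#' @param E prior expected model size of mBIC_E (default 60; must be
#'   >= 1).
#' @return A `CriterionConfig` list.
#' @export
criterion_config <- function(name = c("mBIC2", "mBIC_E"), c = 4, E = 60) {
  name <- match.arg(name)
  stopifnot(c > 0, E >= 1)
  structure(list(name = name, c = c, E = E), class = "CriterionConfig")
}

#' The FDR-controlling criterion mBIC2
#'
#' \deqn{\mathrm{mBIC2} = -2\,l^* + k\,\log\!\big(n p^2 / c^2\big) - 2\log k!}
#' where \eqn{l^*} is the Firth-penalized maximum log-likelihood of the
#' `k`-SNP model, `n` the number of individuals, `p` the number of
#' candidate SNPs and `c` the criterion constant (default 4).  Smaller
#' is better.  The extra \eqn{-2\log k!} term relative to mBIC is what
#' yields FDR-type (rather than FWER-type) control of the selected
#' model, in analogy to the Benjamini-Hochberg step-up rule.
#'
#' @param loglik Firth-penalized maximum log-likelihood of the model.
#' @param n number of individuals.
#' @param p number of candidate SNPs.
#' @param k model size (number of SNPs).
#' @param cfg a [criterion_config()].
#' @return The criterion value (natural logs throughout).
#' @export
mbic2 <- function(loglik, n, p, k, cfg = criterion_config()) {
  stopifnot(k >= 0, p >= 1, n >= 1)
  if (k > p) stop("model size k exceeds number of SNPs p")
  -2 * loglik + k * log(n * p^2 / cfg$c^2) - 2 * lfactorial(k)
}

#' The milder criterion mBIC_E
#'
#' Plain mBIC with the per-SNP penalty relaxed through a prior expected
#' model size `E`:
#' \deqn{\mathrm{mBIC}_E = -2\,l^* + k\,\log\!\big(n p^2 / E^2\big).}
#' With the default `E = 60` ("mBIC_60") the penalty per SNP is milder
#' than mBIC2's, so early search rounds deliberately accept models that
#' are too large, reducing the risk of losing causal SNPs to local
#' minima before the final mBIC2 round.
#'
#' @inheritParams mbic2
#' @return The criterion value.
#' @export
mbic_e <- function(loglik, n, p, k, cfg = criterion_config("mBIC_E")) {
  stopifnot(k >= 0, p >= 1, n >= 1)
  if (k > p) stop("model size k exceeds number of SNPs p")
  -2 * loglik + k * log(n * p^2 / cfg$E^2)
}

# Penalty part of the configured criterion for a size-k model, so that
# criterion = -2 * loglik + crit_penalty(k, ...).
crit_penalty <- function(k, n, p, cfg) {
  switch(cfg$name,
         mBIC2 = k * log(n * p^2 / cfg$c^2) - 2 * lfactorial(k),
         mBIC_E = k * log(n * p^2 / cfg$E^2))
}

# Evaluate the configured criterion for a fitted model.
criterion_value <- function(fit, n, p, cfg) {
  k <- length(fit$snp_indices)
  switch(cfg$name,
         mBIC2 = mbic2(fit$penalized_loglik, n, p, k, cfg),
         mBIC_E = mbic_e(fit$penalized_loglik, n, p, k, cfg))
}
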