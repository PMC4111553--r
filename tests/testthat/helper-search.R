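# Search-test fixtures and the exhaustive-enumeration oracle.

# Exhaustive-search oracle: best mBIC2 model over all subsets of size
# <= kmax (independent of the stepwise search code path).
exhaustive_best <- function(ds, kmax, cfg = criterion_config()) {
  best <- list(indices = integer(0),
               crit = mbic2(firth_fit(ds)$penalized_loglik, ds$n, ds$p, 0, cfg))
  for (k in seq_len(kmax)) {
    for (idx in utils::combn(ds$p, k, simplify = FALSE)) {
      fit <- tryCatch(firth_fit(ds, idx), error = function(e) NULL)
      if (is.null(fit)) next
      cr <- mbic2(fit$penalized_loglik, ds$n, ds$p, k, cfg)
      if (cr < best$crit) best <- list(indices = idx, crit = cr)
    }
  }
  best
}

# A tiny dataset with planted causal SNPs (independent genotypes).
planted_dataset <- function(n, p, causal, betas, seed) {
  set.seed(seed)
  g <- vapply(runif(p, 0.2, 0.5), function(m) rbinom(n, 2, m), numeric(n))
  eta <- g[, causal, drop = FALSE] %*% betas
  mk_dataset(g, rbinom(n, 1, plogis(eta - mean(eta))))
}
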