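#' Configuration of the fast stepwise search
#'
#' @param p1 size of the forward-candidate group P1: directed forward
#'   steps walk the `p1` best-ranked candidates (default 100).
#' @param p2 size of the exchange-candidate group P2 (`p2 >= p1`);
#'   exchange steps may swap model SNPs with P2 members (default
#'   `min(p, 5000)`, capped at fit time).
#' @param window number of neighboring SNPs considered on each side of a
#'   model SNP in exchange steps, as index distance within the same
#'   chromosome (default 49).
#' @param max_backward_depth how many consecutive non-improving greedy
#'   removals the extended backward step explores before giving up
#'   (default 3).
#' @param p2_shrink_threshold model size above which `p2` is halved to
#'   guard runtime (default 25).
#' @param max_sweeps safety cap on forward/exchange/backward cycles per
#'   FSS call (default 50).
#' @param criterion a [criterion_config()].
#' @return A `SearchConfig` list.
#' @export
search_config <- function(p1 = 100, p2 = 5000, window = 49,
                          max_backward_depth = 3, p2_shrink_threshold = 25,
                          max_sweeps = 50,
                          criterion = criterion_config()) {
  stopifnot(p1 >= 1, p2 >= p1, window >= 0, max_backward_depth >= 1,
            max_sweeps >= 1)
  structure(list(p1 = p1, p2 = p2, window = window,
                 max_backward_depth = max_backward_depth,
                 p2_shrink_threshold = p2_shrink_threshold,
                 max_sweeps = max_sweeps, criterion = criterion),
            class = "SearchConfig")
}

# Refit helper with warm start from the parent model's coefficients.
# Lean path for the search hot loop: no rank pre-check (a singular
# information matrix surfaces as a C++ error, mapped to NULL = skip).
refit <- function(ds, snp_indices, parent = NULL) {
  snp_indices <- sort(unique(as.integer(snp_indices)))
  init <- numeric(length(snp_indices) + 1L)
  if (!is.null(parent)) {
    init[1] <- parent$beta[1]
    common <- match(snp_indices, parent$snp_indices)
    init[-1][!is.na(common)] <- parent$beta[-1][common[!is.na(common)]]
  }
  X <- cbind(1, ds$genotypes[, snp_indices, drop = FALSE])
  res <- tryCatch(
    .firth_fit_cpp(X, as.double(ds$phenotype), init, 1e-8, 50L),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  structure(list(snp_indices = snp_indices,
                 beta = as.numeric(res$beta),
                 penalized_loglik = res$penalized_loglik,
                 converged = res$converged,
                 iterations = res$iterations,
                 hat_diag = as.numeric(res$hat_diag),
                 fitted = as.numeric(res$fitted)),
            class = "ModelFit")
}

#' Directed forward step
#'
#' Walks the top-`p1` candidates in ordering order and adds the FIRST
#' one whose addition strictly lowers the criterion (each candidate is
#' evaluated by an exact Firth refit).  Returns the unchanged model if
#' no candidate improves.
#'
#' @param ds a complete `GenotypeDataset`.
#' @param fit current `ModelFit`.
#' @param ordering a `SnpOrdering` from [order_snps()].
#' @param cfg a [search_config()].
#' @param memo optional environment used by [fss()] to cache failed
#'   scans of an unchanged model (internal).
#' @return The (possibly enlarged) `ModelFit` with attribute
#'   `"criterion"`.
#' @export
directed_forward <- function(ds, fit, ordering, cfg, memo = NULL) {
  crit <- criterion_value(fit, ds$n, ds$p, cfg$criterion)
  cand <- setdiff(ordering$order, fit$snp_indices)
  cand <- utils::head(cand, cfg$p1)
  if (!length(cand)) {
    attr(fit, "criterion") <- crit
    return(fit)
  }
  key <- paste0("m", paste(fit$snp_indices, collapse = ","))
  # all enlarged models share size k+1: "criterion improves" is a
  # penalized-log-likelihood threshold, evaluated batched in C++
  pen_new <- crit_penalty(length(fit$snp_indices) + 1L, ds$n, ds$p,
                          cfg$criterion)
  thr <- (pen_new - crit) / 2
  if (!is.null(memo) && !is.null(memo$forward[[key]]) &&
      memo$forward[[key]] <= thr) {
    attr(fit, "criterion") <- crit
    return(fit)
  }
  # scan tolerance 1e-5: the resulting pll sits within ~1e-10 of the
  # optimum (quadratic flatness), and any accepted move is re-verified
  # below by an exact refit at the full 1e-8 tolerance
  Xbase <- cbind(1, ds$genotypes[, fit$snp_indices, drop = FALSE])
  res <- .firth_batch_cpp(Xbase, as.double(ds$phenotype),
                          ds$genotypes[, cand, drop = FALSE],
                          fit$beta, 1e-5, 50L, thr, TRUE)
  if (res$chosen > 0) {
    f2 <- refit(ds, c(fit$snp_indices, cand[res$chosen]), parent = fit)
    if (!is.null(f2)) {
      c2 <- criterion_value(f2, ds$n, ds$p, cfg$criterion)
      if (c2 < crit) {
        attr(f2, "criterion") <- c2
        return(f2)
      }
    }
  } else if (!is.null(memo)) {  # full scan failed: remember its best pll
    memo$forward[[key]] <- suppressWarnings(max(res$pll, -Inf, na.rm = TRUE))
  }
  attr(fit, "criterion") <- crit
  fit
}

#' Exchange step
#'
#' Iterates once over the model SNPs in order; for each, evaluates
#' swapping it with every P2 SNP on the same chromosome within `window`
#' positions (index distance in chromosome order).  If any swap lowers
#' the criterion the best-scoring swap is applied before moving on.  The
#' rationale: the directed forward step may have admitted a correlated
#' proxy rather than the locally optimal SNP.
#'
#' @inheritParams directed_forward
#' @param p2_set integer vector of SNP indices forming group P2
#'   (defaults to all SNPs).
#' @param memo optional cache environment (see [directed_forward()]).
#' @return `ModelFit` with attribute `"criterion"`; never worse than the
#'   input.
#' @export
exchange_step <- function(ds, fit, cfg, p2_set = seq_len(ds$p), memo = NULL) {
  crit <- criterion_value(fit, ds$n, ds$p, cfg$criterion)
  if (!length(fit$snp_indices)) {
    attr(fit, "criterion") <- crit
    return(fit)
  }
  key <- paste0("m", paste(fit$snp_indices, collapse = ","),
                "|p2:", length(p2_set))
  if (!is.null(memo) && isTRUE(memo$exchange[[key]])) {
    attr(fit, "criterion") <- crit
    return(fit)
  }
  start_indices <- fit$snp_indices
  chrom <- ds$snps$chrom
  # rank of each SNP within its chromosome (bim order = position order)
  rank_in_chrom <- stats::ave(seq_len(ds$p), chrom, FUN = seq_along)
  p2 <- logical(ds$p); p2[p2_set] <- TRUE
  for (s in fit$snp_indices) {
    if (!(s %in% fit$snp_indices)) next  # may have been swapped out already
    near <- which(chrom == chrom[s] &
                  abs(rank_in_chrom - rank_in_chrom[s]) <= cfg$window &
                  p2 & !(seq_len(ds$p) %in% fit$snp_indices))
    if (!length(near)) next
    base <- setdiff(fit$snp_indices, s)
    # swaps preserve the model size: compare penalized log-likelihoods
    # of all candidate swaps in one C++ batch, keep the best improving
    # one (ascending candidate order, so ties keep the lowest index)
    init <- fit$beta[c(1L, 1L + match(base, fit$snp_indices))]
    Xbase <- cbind(1, ds$genotypes[, base, drop = FALSE])
    res <- .firth_batch_cpp(Xbase, as.double(ds$phenotype),
                            ds$genotypes[, near, drop = FALSE],
                            init, 1e-5, 50L, Inf, FALSE)
    pll_cur <- fit$penalized_loglik
    best_j <- which(res$pll > pll_cur & res$pll >= max(res$pll, na.rm = TRUE))
    if (length(best_j)) {
      f2 <- refit(ds, c(base, near[best_j[1]]), parent = fit)
      if (!is.null(f2)) {
        c2 <- criterion_value(f2, ds$n, ds$p, cfg$criterion)
        if (c2 < crit) {
          fit <- f2
          crit <- c2
        }
      }
    }
  }
  if (!is.null(memo) && identical(fit$snp_indices, start_indices))
    memo$exchange[[key]] <- TRUE
  attr(fit, "criterion") <- crit
  fit
}

#' Extended backward elimination step
#'
#' Greedily removes the least-explanatory SNP (the removal giving the
#' best criterion).  When a removal does not improve on the best model
#' seen so far the elimination is still pursued, up to
#' `max_backward_depth` consecutive non-improving removals, so that
#' one-step local minima can be escaped.  Returns the best model seen,
#' including the starting one.
#'
#' @inheritParams directed_forward
#' @return `ModelFit` with attribute `"criterion"`; never worse than the
#'   input.
#' @export
backward_step <- function(ds, fit, cfg, memo = NULL) {
  key <- paste0("m", paste(fit$snp_indices, collapse = ","))
  if (!is.null(memo) && isTRUE(memo$backward[[key]])) {
    attr(fit, "criterion") <- criterion_value(fit, ds$n, ds$p, cfg$criterion)
    return(fit)
  }
  best <- fit
  best_crit <- criterion_value(fit, ds$n, ds$p, cfg$criterion)
  cur <- fit
  cur_crit <- best_crit
  worse_streak <- 0L
  while (length(cur$snp_indices) > 0 && worse_streak < cfg$max_backward_depth) {
    cands <- lapply(cur$snp_indices, function(s)
      refit(ds, setdiff(cur$snp_indices, s), parent = cur))
    crits <- vapply(cands, function(f)
      if (is.null(f)) Inf else criterion_value(f, ds$n, ds$p, cfg$criterion),
      numeric(1))
    i <- which.min(crits)
    if (!is.finite(crits[i])) break
    cur <- cands[[i]]
    cur_crit <- crits[i]
    if (cur_crit < best_crit) {
      best <- cur
      best_crit <- cur_crit
      worse_streak <- 0L
    } else {
      worse_streak <- worse_streak + 1L
    }
  }
  if (!is.null(memo) && identical(best$snp_indices, fit$snp_indices))
    memo$backward[[key]] <- TRUE
  attr(best, "criterion") <- best_crit
  best
}

#' Fast stepwise search (FSS)
#'
#' Starting from `init`, builds the candidate ordering (marginal trend
#' statistics or score tests conditional on `init`), forms the candidate
#' groups P1/P2, then cycles directed forward, exchange and extended
#' backward steps until a full cycle yields no criterion improvement (or
#' `max_sweeps` is hit).  Every accepted move strictly decreases the
#' criterion, so the search terminates; the returned model's criterion
#' is never above `init`'s.  The ordering is fixed for the whole call.
#'
#' @inheritParams directed_forward
#' @param init starting `ModelFit` (e.g. the intercept-only fit).
#' @param ordering_method `"marginal"` or `"conditional"` (see
#'   [order_snps()]).
#' @return The final `ModelFit`, with attributes `"criterion"` and
#'   `"trace"` (data frame of accepted steps).
#' @export
fss <- function(ds, init, ordering_method = c("marginal", "conditional"),
                cfg = search_config()) {
  ordering_method <- match.arg(ordering_method)
  ordering <- order_snps(ds, init, ordering_method)
  p2_n <- min(cfg$p2, length(ordering$order))
  p2_set <- ordering$order[seq_len(p2_n)]
  fit <- init
  memo <- new.env(parent = emptyenv())
  crit <- criterion_value(fit, ds$n, ds$p, cfg$criterion)
  trace <- list(data.frame(sweep = 0L, step = "init",
                           model_size = length(fit$snp_indices),
                           criterion = crit))
  for (sweep in seq_len(cfg$max_sweeps)) {
    crit_before <- crit
    # runtime guard: halve the exchange group for large models
    eff_p2 <- if (length(fit$snp_indices) > cfg$p2_shrink_threshold)
      p2_set[seq_len(ceiling(p2_n / 2))] else p2_set
    fit <- directed_forward(ds, fit, ordering, cfg, memo = memo)
    trace[[length(trace) + 1L]] <-
      data.frame(sweep = sweep, step = "forward",
                 model_size = length(fit$snp_indices),
                 criterion = attr(fit, "criterion"))
    fit <- exchange_step(ds, fit, cfg, p2_set = eff_p2, memo = memo)
    trace[[length(trace) + 1L]] <-
      data.frame(sweep = sweep, step = "exchange",
                 model_size = length(fit$snp_indices),
                 criterion = attr(fit, "criterion"))
    fit <- backward_step(ds, fit, cfg, memo = memo)
    trace[[length(trace) + 1L]] <-
      data.frame(sweep = sweep, step = "backward",
                 model_size = length(fit$snp_indices),
                 criterion = attr(fit, "criterion"))
    crit <- attr(fit, "criterion")
    if (crit >= crit_before - 1e-12) break
  }
  attr(fit, "criterion") <- crit
  attr(fit, "trace") <- do.call(rbind, trace)
  fit
}

#' Full three-round model search
#'
#' The complete search schedule: starting from the null model,
#' \enumerate{
#'   \item `M1 = fss(null, marginal ordering, mBIC_E)` — candidates
#'     preselected by Cochran-Armitage statistics under the milder
#'     criterion;
#'   \item `M2 = fss(M1, conditional ordering, mBIC_E)` — score tests
#'     conditional on M1 pick up SNPs whose effect is masked marginally;
#'   \item `M3 = fss(M2, conditional ordering, mBIC2)` — the final round
#'     under the target FDR-controlling criterion.
#' }
#' The returned model's type I error is controlled in terms of FDR at
#' roughly the 10% level by the mBIC2 penalty.
#'
#' @param ds a QC'd, imputed `GenotypeDataset`.
#' @param cfg a [search_config()]; its `criterion` field configures the
#'   constants `c` (mBIC2) and `E` (mBIC_E).
#' @return The final `ModelFit` with attributes `"criterion"` (its mBIC2
#'   value) and `"trace"` (all three rounds' accepted steps).
#' @examples
#' \donttest{
#' sc <- simulation_scenario(n = 300, p = 50, k_causal = 2,
#'                           effect_range = c(1.5, 1.5), block_rho = 0,
#'                           hide_fraction = 0, seed = 7)
#' ds <- simulate_dataset(sc)
#' fit <- full_search(ds)
#' fit$snp_indices
#' }
#' @export
full_search <- function(ds, cfg = search_config()) {
  cfg_e <- cfg
  cfg_e$criterion <- criterion_config("mBIC_E", c = cfg$criterion$c,
                                      E = cfg$criterion$E)
  cfg2 <- cfg
  cfg2$criterion <- criterion_config("mBIC2", c = cfg$criterion$c,
                                     E = cfg$criterion$E)
  m0 <- null_fit(ds)
  m1 <- fss(ds, m0, "marginal", cfg_e)
  m2 <- fss(ds, m1, "conditional", cfg_e)
  m3 <- fss(ds, m2, "conditional", cfg2)
  tr <- rbind(cbind(round = 1L, attr(m1, "trace")),
              cbind(round = 2L, attr(m2, "trace")),
              cbind(round = 3L, attr(m3, "trace")))
  attr(m3, "trace") <- tr
  m3
}

#' Write a search trace as a tab-separated log
#'
#' @param fit a `ModelFit` returned by [fss()] or [full_search()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  tr <- attr(fit, "trace")
  if (is.null(tr)) stop("fit carries no search trace")
  write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
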