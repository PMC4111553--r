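#' Describe a synthetic case-control GWAS scenario
#'
#' Defines the generative model the simulator draws from: blocks of
#' correlated common SNPs (a Gaussian copula with within-block latent
#' correlation `block_rho`, thresholded to Hardy-Weinberg genotype
#' probabilities), a sparse additive logistic disease model with
#' log-odds effects drawn from `effect_range`, an intercept calibrated
#' to `target_prevalence`, and optionally a fraction of causal SNPs
#' hidden before analysis so that only LD proxies remain detectable.
#'
#' @param n number of individuals.
#' @param p number of SNPs.
#' @param k_causal number of causal SNPs.
#' @param maf_range interval of per-SNP minor allele frequencies,
#'   drawn uniformly (default `c(0.05, 0.5)`; causal SNPs are common).
#' @param block_size SNPs per LD block (default 10).
#' @param block_rho latent within-block pairwise correlation in
#'   `[0, 1)`; 0 gives independent SNPs.
#' @param effect_range interval of |log-odds| effect sizes (default
#'   `c(0.3, 0.6)`, giving intermediate power at n of a few thousand).
#' @param hide_fraction fraction of causal SNPs removed before analysis
#'   (default 0.5); requires `block_rho > 0` so a proxy remains.
#' @param target_prevalence mean disease risk the intercept is
#'   calibrated to (default 0.5, balanced cases/controls).
#' @param n_chrom number of pseudo-chromosomes blocks are spread over
#'   (default 6).
#' @param seed integer seed; the full pipeline is deterministic given it.
#' @return A `SimulationScenario` list.
#' @export
simulation_scenario <- function(n, p, k_causal,
                                maf_range = c(0.05, 0.5),
                                block_size = 10, block_rho = 0,
                                effect_range = c(0.3, 0.6),
                                hide_fraction = 0.5,
                                target_prevalence = 0.5,
                                n_chrom = 6, seed = 1) {
  stopifnot(k_causal <= p, target_prevalence > 0, target_prevalence < 1,
            block_rho >= 0, block_rho < 1, hide_fraction >= 0,
            hide_fraction <= 1, maf_range[1] >= 0.01, maf_range[2] <= 0.5)
  if (hide_fraction > 0 && (block_rho == 0 || block_size < 2))
    stop("hide_fraction > 0 requires correlated blocks (block_rho > 0, block_size >= 2)")
  structure(list(n = n, p = p, k_causal = k_causal, maf_range = maf_range,
                 block_size = block_size, block_rho = block_rho,
                 effect_range = effect_range, hide_fraction = hide_fraction,
                 target_prevalence = target_prevalence, n_chrom = n_chrom,
                 seed = as.integer(seed)),
            class = "SimulationScenario")
}

#' Named scenario presets
#'
#' `"null"` is the global-null design (no causal SNPs, labels
#' independent of genotypes); `"k6"`, `"k12"` and `"k24"` carry 6, 12
#' and 24 causal SNPs equally distributed over six pseudo-chromosomes,
#' with half of them hidden behind LD proxies before analysis.  Sizes
#' (n = 1000, p = 600 SNPs in blocks of 10 with latent correlation 0.8)
#' are chosen so a full replicate study runs on a single desktop CPU.
#'
#' @param type one of `"null"`, `"k6"`, `"k12"`, `"k24"`.
#' @param seed integer seed.
#' @param ... overrides passed on to [simulation_scenario()] (e.g. `n`,
#'   `p`, `block_rho`; the argument is called `type` so that short
#'   override names cannot partially match it).
#' @return A `SimulationScenario`.
#' @export
scenario_preset <- function(type = c("null", "k6", "k12", "k24"),
                            seed = 1, ...) {
  name <- match.arg(type)
  base <- list(n = 1000, p = 600, block_size = 10, block_rho = 0.8,
               maf_range = c(0.05, 0.5), effect_range = c(0.3, 0.6),
               hide_fraction = 0.5, target_prevalence = 0.5,
               n_chrom = 6, seed = seed)
  base$k_causal <- switch(name, null = 0, k6 = 6, k12 = 12, k24 = 24)
  if (name == "null") {
    base$hide_fraction <- 0
    base$block_rho <- 0
  }
  over <- list(...)
  base[names(over)] <- over
  do.call(simulation_scenario, base)
}

#' Generate genotypes for a scenario
#'
#' Per-SNP minor allele frequencies are drawn uniformly from
#' `maf_range`; latent Gaussians with equicorrelation `block_rho` inside
#' each block (independent across blocks) are thresholded to the
#' Hardy-Weinberg genotype probabilities \eqn{((1-m)^2, 2m(1-m), m^2)}.
#' Blocks are assigned round-robin to `n_chrom` pseudo-chromosomes.
#' Deterministic given `sc$seed`.
#'
#' @param sc a [simulation_scenario()].
#' @return A `GenotypeDataset` with attributes `"causal"` (causal SNP
#'   indices), `"betas"` (their log-odds effects) and `"beta0"` (the
#'   calibrated intercept).  The phenotype is all-zero until
#'   [simulate_status()] is applied (see [simulate_dataset()] for the
#'   one-call pipeline).
#' @export
generate_genotypes <- function(sc) {
  set.seed(sc$seed)
  n <- sc$n; p <- sc$p
  maf <- runif(p, sc$maf_range[1], sc$maf_range[2])
  n_blocks <- ceiling(p / sc$block_size)
  block <- rep(seq_len(n_blocks), each = sc$block_size)[seq_len(p)]
  # equicorrelated latent Gaussians: sqrt(rho) * shared + sqrt(1-rho) * own
  Z <- matrix(rnorm(n * p), n, p)
  if (sc$block_rho > 0) {
    shared <- matrix(rnorm(n * n_blocks), n, n_blocks)
    Z <- sqrt(sc$block_rho) * shared[, block] + sqrt(1 - sc$block_rho) * Z
  }
  # HWE thresholds on the latent scale
  t0 <- qnorm((1 - maf)^2)           # below: genotype 0
  t1 <- qnorm(1 - maf^2)             # above: genotype 2
  G <- (sweep(Z, 2, t0, ">")) + (sweep(Z, 2, t1, ">"))
  storage.mode(G) <- "double"
  chrom_of_block <- rep_len(seq_len(sc$n_chrom), n_blocks)
  chrom <- as.character(chrom_of_block[block])
  # positions: 1-based, increasing within chromosome
  pos <- stats::ave(seq_len(p), chrom, FUN = function(i) seq_along(i) * 1000L)
  snps <- data.frame(snp_id = sprintf("snp%04d", seq_len(p)),
                     chrom = chrom, pos_bp = as.integer(pos),
                     allele1 = "A", allele2 = "G",
                     stringsAsFactors = FALSE)
  ds <- genotype_dataset(G, snps, integer(n))
  attr(ds, "block") <- block
  ds
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' Finds \eqn{\beta_0} such that the mean of
#' \eqn{\mathrm{expit}(\beta_0 + \sum_j \beta_j x_{ij})} over the
#' observed genotypes equals `target` (monotone root-finding; within
#' 1e-3 or better).  Keeps simulated case/control counts balanced at
#' `target = 0.5` regardless of the effect sizes.
#'
#' @param ds a `GenotypeDataset`.
#' @param causal integer indices of causal SNPs.
#' @param betas their log-odds effects (same length as `causal`).
#' @param target target mean disease risk.
#' @return The intercept \eqn{\beta_0}.
#' @export
calibrate_intercept <- function(ds, causal, betas, target = 0.5) {
  stopifnot(length(causal) == length(betas))
  if (!length(causal)) return(qlogis(target))
  eta <- as.numeric(ds$genotypes[, causal, drop = FALSE] %*% betas)
  f <- function(b0) mean(plogis(b0 + eta)) - target
  uniroot(f, c(-50, 50), tol = 1e-8)$root
}

#' Draw case/control status from the logistic disease model
#'
#' Independent Bernoulli draws with individual risks
#' \eqn{\pi_i = \mathrm{expit}(\beta_0 + \sum_j \beta_j x_{ij})}
#' (prospective sampling).
#'
#' @inheritParams calibrate_intercept
#' @param beta0 calibrated intercept.
#' @param seed integer seed for the status draws.
#' @return Integer phenotype vector (0/1) of length `n`.
#' @export
simulate_status <- function(ds, causal, betas, beta0, seed = 1) {
  eta <- beta0
  if (length(causal))
    eta <- eta + as.numeric(ds$genotypes[, causal, drop = FALSE] %*% betas)
  set.seed(seed)
  rbinom(ds$n, 1, plogis(eta))
}

#' Hide causal SNPs behind their LD proxies
#'
#' Removes `hide_fraction` of the causal columns before analysis,
#' mimicking the situation where the SNPs associated with a trait are
#' not themselves causal but only in LD with the cause.  Each hidden
#' SNP must have a remaining same-block partner (guaranteed when
#' `block_rho > 0` and blocks hold more than one SNP); the causal
#' bookkeeping keeps original indices so detections can still be scored
#' against the full causal set.
#'
#' @param ds a `GenotypeDataset` from [generate_genotypes()].
#' @param causal causal SNP indices (original space).
#' @param sc the `SimulationScenario`.
#' @return List with `ds` (analysis dataset, hidden columns removed;
#'   remaining column order preserved) and `hidden` (original indices
#'   of the removed SNPs).
#' @export
hide_causal <- function(ds, causal, sc) {
  n_hide <- round(sc$hide_fraction * length(causal))
  if (n_hide == 0) return(list(ds = ds, hidden = integer(0)))
  block <- attr(ds, "block")
  ok <- vapply(causal, function(s) {
    sc$block_rho > 0 && sum(block == block[s]) > 1
  }, logical(1))
  cand <- causal[ok]
  if (length(cand) < n_hide)
    stop("not enough causal SNPs with a correlated same-block partner to hide")
  hidden <- cand[seq_len(n_hide)]          # deterministic: first in index order
  keep <- setdiff(seq_len(ds$p), hidden)
  out <- subset_snps(ds, keep)
  attr(out, "block") <- block[keep]
  list(ds = out, hidden = hidden)
}

#' Simulate a complete analysis-ready dataset
#'
#' One-call pipeline: genotypes, causal SNP placement (one per block,
#' blocks spread evenly over the pseudo-chromosomes, and within each
#' block the commonest SNP carries the effect, since causal variants
#' are common), effect sizes with random signs, intercept calibration,
#' status draws, and causal hiding.  Fully deterministic given
#' `sc$seed`.
#'
#' @param sc a [simulation_scenario()].
#' @return The analysis `GenotypeDataset`, with attributes `"causal"`
#'   (original-space causal indices, including hidden ones), `"hidden"`,
#'   `"betas"`, `"beta0"`, and `"full_ds"` (the pre-hiding dataset, for
#'   correlation-based scoring).
#' @export
simulate_dataset <- function(sc) {
  ds <- generate_genotypes(sc)
  block <- attr(ds, "block")
  k <- sc$k_causal
  if (k > 0) {
    n_blocks <- max(block)
    if (k <= n_blocks) {
      # one causal SNP per block, blocks spread across chromosomes
      causal_blocks <- unique(round(seq(1, n_blocks, length.out = k)))
      # ensure k distinct blocks even after rounding collisions
      while (length(causal_blocks) < k)
        causal_blocks <- union(causal_blocks,
                               setdiff(seq_len(n_blocks), causal_blocks)[1])
      # within each causal block, the commonest SNP carries the effect
      # (causal variants are common; rare columns stay as background)
      causal <- vapply(sort(causal_blocks)[seq_len(k)], function(b) {
        members <- which(block == b)
        members[which.max(ds$snps$maf[members])]
      }, integer(1))
    } else {
      # more causal SNPs than blocks: spread them over distinct columns
      causal <- sort(unique(round(seq(1, sc$p, length.out = k))))
      while (length(causal) < k)
        causal <- sort(union(causal, setdiff(seq_len(sc$p), causal)[1]))
    }
    set.seed(sc$seed + 500009L)
    betas <- runif(k, sc$effect_range[1], sc$effect_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
  } else {
    causal <- integer(0)
    betas <- numeric(0)
  }
  beta0 <- calibrate_intercept(ds, causal, betas, sc$target_prevalence)
  ds$phenotype <- simulate_status(ds, causal, betas, beta0,
                                  seed = sc$seed + 900007L)
  hidden <- integer(0)
  full_ds <- ds
  if (k > 0 && sc$hide_fraction > 0) {
    h <- hide_causal(ds, causal, sc)
    ds <- h$ds
    ds$phenotype <- full_ds$phenotype
    hidden <- h$hidden
  }
  attr(ds, "causal") <- causal
  attr(ds, "hidden") <- hidden
  attr(ds, "betas") <- betas
  attr(ds, "beta0") <- beta0
  attr(ds, "full_ds") <- full_ds
  ds
}
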