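#' Evaluation configuration
#'
#' A single correlation constant `r_threshold` is used both for
#' matching detections to causal SNPs (true-positive rule) and for
#' clustering redundant detections, so the two bookkeeping rules are
#' always consistent.
#'
#' @param r_threshold correlation threshold in (0, 1), default 0.3.
#' @return An `EvaluationConfig` list.
#' @export
evaluation_config <- function(r_threshold = 0.3) {
  stopifnot(r_threshold > 0, r_threshold < 1)
  structure(list(r_threshold = r_threshold), class = "EvaluationConfig")
}

#' Greedy r-clustering of detected SNPs
#'
#' Partitions the detected SNPs, walked in genomic order, into clusters
#' guaranteed to have pairwise |correlation| > `r` between ALL members:
#' a SNP joins the current cluster only if it is correlated above the
#' threshold with every SNP already in it, otherwise it opens a new
#' cluster.
#'
#' @param detected integer vector of SNP indices.
#' @param corr symmetric correlation matrix (unit diagonal) indexed by
#'   the same space as `detected`.
#' @param r threshold.
#' @return A list of integer vectors (the clusters).
#' @export
r_cluster <- function(detected, corr, r = 0.3) {
  detected <- sort(detected)
  clusters <- list()
  cur <- integer(0)
  for (s in detected) {
    if (!length(cur) || all(abs(corr[cur, s]) > r)) {
      cur <- c(cur, s)
    } else {
      clusters[[length(clusters) + 1L]] <- cur
      cur <- s
    }
  }
  if (length(cur)) clusters[[length(clusters) + 1L]] <- cur
  clusters
}

#' Score detections against the causal truth
#'
#' A detection is causal-matched when its genotype |correlation| with
#' some causal SNP exceeds the threshold; each causal SNP counts at
#' most once toward the true positives (several detections tagging the
#' same causal SNP count as one).  Unmatched detections are false
#' positives, counted as r-clusters when `cluster_fp = TRUE` (for
#' selectors that report many redundant correlated SNPs) or singly
#' otherwise.  Power = detected causal SNPs / total causal SNPs;
#' misclassifications = false positives + missed causal SNPs;
#' FDP = false positives / max(1, true + false positives).
#'
#' @param detected detected SNP indices (original, pre-hiding space).
#' @param causal_full all causal SNP indices, including hidden ones.
#' @param corr correlation matrix over the original SNP space (Pearson,
#'   additive coding).
#' @param cfg an [evaluation_config()].
#' @param cluster_fp whether to cluster false positives.
#' @return An `EvaluationResult` list: `size`, `tp_causal`,
#'   `fp_clusters`, `power`, `fdp`, `mis`.
#' @export
score_detections <- function(detected, causal_full, corr,
                             cfg = evaluation_config(), cluster_fp = FALSE) {
  r <- cfg$r_threshold
  detected <- sort(unique(detected))
  k_total <- length(causal_full)
  if (!length(detected)) {
    return(structure(list(size = 0L, tp_causal = 0L, fp_clusters = 0L,
                          power = 0, fdp = 0, mis = k_total),
                     class = "EvaluationResult"))
  }
  if (k_total) {
    cm <- abs(corr[detected, causal_full, drop = FALSE]) > r
    cm[is.na(cm)] <- FALSE
    matched <- rowSums(cm) > 0
    tp_causal <- sum(colSums(cm[matched, , drop = FALSE]) > 0)
  } else {
    matched <- rep(FALSE, length(detected))
    tp_causal <- 0L
  }
  fp_snps <- detected[!matched]
  fp_clusters <- if (!length(fp_snps)) 0L
    else if (cluster_fp) length(r_cluster(fp_snps, corr, r))
    else length(fp_snps)
  power <- if (k_total) tp_causal / k_total else 0
  fdp <- fp_clusters / max(1, tp_causal + fp_clusters)
  mis <- fp_clusters + (k_total - tp_causal)
  structure(list(size = tp_causal + fp_clusters, tp_causal = tp_causal,
                 fp_clusters = fp_clusters, power = power, fdp = fdp,
                 mis = mis),
            class = "EvaluationResult")
}

#' Run a replicated simulation experiment
#'
#' Per replicate: generate the scenario's dataset (with its own seed),
#' hide causal SNPs, run the selector on the analysis dataset, map the
#' selection back to the original SNP space and score it against the
#' full causal set.  Detections of the criterion-based `full_search`
#' are scored unclustered (it selects one representative per region);
#' `single_marker_scan` detections have their false positives
#' r-clustered, since marginal tests report many redundant correlated
#' SNPs.  With `k_causal = 0` the mean false-positive count is the
#' per-family error-rate estimate.
#'
#' @param sc a [simulation_scenario()]; replicate `i` uses seed
#'   `sc$seed + i - 1`.
#' @param selector `"full_search"`, `"single_marker_scan"`, or a
#'   function `(ds) -> analysis-space indices`.
#' @param replicates number of replicates.
#' @param cfg an [evaluation_config()].
#' @param search_cfg a [search_config()] for the `full_search` selector.
#' @return List with `summary` (means and Monte-Carlo standard errors of
#'   Size/Power/FP/FDR/Mis) and `per_replicate` (data frame).
#' @export
run_experiment <- function(sc, selector = "full_search", replicates = 10,
                           cfg = evaluation_config(),
                           search_cfg = search_config()) {
  stopifnot(replicates >= 1)
  cluster_fp <- identical(selector, "single_marker_scan")
  select_fun <- if (is.function(selector)) selector
    else switch(selector,
      full_search = function(ds) full_search(ds, search_cfg)$snp_indices,
      single_marker_scan = function(ds) single_marker_scan(ds)$selected,
      stop("unknown selector: ", selector))
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    sci <- sc
    sci$seed <- sc$seed + i - 1L
    ds <- simulate_dataset(sci)
    causal <- attr(ds, "causal")
    full <- attr(ds, "full_ds")
    sel_local <- select_fun(ds)
    detected <- orig_index(ds)[sel_local]
    # correlations only among the columns scoring actually touches
    U <- sort(unique(c(detected, causal)))
    corr <- matrix(0, full$p, full$p)
    if (length(U))
      corr[U, U] <- suppressWarnings(cor(full$genotypes[, U, drop = FALSE]))
    res <- score_detections(detected, causal, corr, cfg,
                            cluster_fp = cluster_fp)
    rows[[i]] <- data.frame(replicate = i, seed = sci$seed,
                            size = res$size, tp = res$tp_causal,
                            fp = res$fp_clusters, power = res$power,
                            fdp = res$fdp, mis = res$mis)
  }
  per <- do.call(rbind, rows)
  mets <- c(size = "size", power = "power", fp = "fp", fdr = "fdp",
            mis = "mis")
  means <- vapply(mets, function(m) mean(per[[m]]), numeric(1))
  ses <- vapply(mets, function(m) sd(per[[m]]) / sqrt(replicates), numeric(1))
  summary <- data.frame(metric = c("Size", "Power", "FP", "FDR", "Mis"),
                        mean = as.numeric(means), se = as.numeric(ses))
  list(summary = summary, per_replicate = per)
}
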