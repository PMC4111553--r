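---
title: "Multi-marker model selection for case-control GWAS with mBIC2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-marker model selection for case-control GWAS with mBIC2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbicgwas)
```

## The problem

Single-marker tests remain the dominant analysis of genome-wide
association studies, but for complex traits they are statistically
awkward: the effect of every other causal variant is left in the
residual, which costs power, and correlated markers make the ranking of
marginal p-values unreliable.  `mbicgwas` instead selects one
*multi-SNP* logistic regression model for the case/control status,
treating GWAS analysis as a model-selection problem over all subsets of
SNPs.

For a subset $M = \{j_1, \dots, j_k\}$ of the $p$ genotyped SNPs the
disease model is

$$
\log \frac{P(y_i = 1)}{P(y_i = 0)}
  = \beta_0 + \sum_{l=1}^{k} \beta_{l}\, x_{i j_l},
$$

with $x_{ij} \in \{0, 1, 2\}$ the additive genotype coding and $n$
individuals.  Two ingredients make the subset search workable at GWAS
scale: a penalized likelihood that is finite for every subset, and a
selection criterion whose penalty is calibrated for the
multiple-testing burden of $p$ candidate regressors.

## Firth-penalized logistic regression

When a SNP combination separates cases from controls the ordinary
maximum-likelihood estimate diverges.  Because a subset search visits
enormous numbers of SNP combinations, separation is routine rather than
exotic, so all fits maximize the Jeffreys-prior penalized likelihood

$$
l^*(\beta) \;=\; l(\beta) + \tfrac12 \log\det I(\beta),
\qquad I(\beta) = X^\top W X,\; W = \mathrm{diag}\{\pi_i(1-\pi_i)\},
$$

Firth's bias-reducing correction.  Estimates are always finite; for the
intercept-only model the fitted prevalence is the closed form
$(\sum y_i + 1/2)/(n+1)$, and for a separated $2\times2$ table the
estimate equals the classical add-half log odds ratio.  These closed
forms, and agreement of the solver with a generic optimizer of
$l^*$, are pinned by the test suite.

### Numerical scheme

`firth_fit()` runs Newton iterations on the modified score
$U^*(\beta) = X^\top\!\big(y - \pi + h \circ (\tfrac12 - \pi)\big)$,
where $h$ is the hat-matrix diagonal, using the expected information as
the Hessian, with step-halving whenever a step would decrease $l^*$.
Three numerical choices matter:

* **Convergence** is declared when $\lVert U^* \rVert_\infty <$ `tol`
  (default $10^{-8}$) *or* the Newton step collapses below $10^{-10}$ —
  with an approximate Hessian the score converges only linearly in its
  last decade, while the parameters are long since at the optimum.
* **Step acceptance** tolerates a likelihood decrease of
  $10^{-10}(|l^*|+1)$, the floating-point resolution of $l^*$ itself;
  a stricter rule stalls on noise.
* **Candidate scans** inside the search fit every candidate model
  exactly but stop the score at $10^{-5}$; by the quadratic flatness of
  $l^*$ near its optimum this bounds the likelihood error by about
  $10^{-10}$, far below any criterion difference that could change a
  decision, and every accepted move is re-verified by a full-tolerance
  refit before it is applied.

$\log\det I$ is evaluated through the Cholesky factor of $X^\top W X$;
rank-deficient designs are rejected with the offending columns named.

## The selection criteria

The target criterion is **mBIC2**,

$$
\mathrm{mBIC2}(M) = -2\,l^*(\hat\beta_M)
  + k \log\!\frac{n p^2}{c^2} - 2 \log k!,
\qquad c = 4,
$$

minimized over subsets.  The $k\log(np^2/c^2)$ part is the mBIC-style
penalty whose $2k\log p$ term pays the multiple-testing price of $p$
candidates; the $-2\log k!$ relaxation lowers the bar for the $k$-th
accepted SNP in the same step-up fashion as the Benjamini–Hochberg
rule, which is what converts family-wise-type control into FDR-type
control (a design level of roughly 10%).

Early search rounds use the **milder criterion** $\mathrm{mBIC}_E$ with
a prior expected model size $E = 60$:

$$
\mathrm{mBIC}_E(M) = -2\,l^*(\hat\beta_M) + k \log\!\frac{n p^2}{E^2}.
$$

It deliberately accepts models that are too large, so that causal SNPs
are not lost to local minima before the final round.  We read the
milder criterion as plain mBIC with $E = 60$, i.e. *without* the
$-2\log k!$ term; with the term it would be uniformly milder than
mBIC2 at every size, eroding the distinction between the warm-up and
target criteria.  Both constants are exposed in `criterion_config()`.

## The fast stepwise search

Minimizing mBIC2 over subsets is a hard combinatorial problem;
`fss()` is a heuristic built from three moves, applied cyclically until
a full cycle brings no improvement:

1. **Directed forward.**  Candidates are ranked once per call — by
   marginal Cochran–Armitage trend statistics, or by Rao score tests
   conditional on the current model (no refit needed, which is what
   makes the ranking cheap).  The forward step walks the best `p1`
   (default 100) candidates in that order and adds the *first* one
   whose exact Firth refit lowers the criterion.
2. **Exchange.**  Each model SNP in turn is tentatively swapped with
   every member of the best-`p2` group (default 5000) lying within
   `window` = 49 positions on the same chromosome; the best improving
   swap is applied.  This repairs the common situation where a
   correlated proxy entered before the locally optimal SNP.  We
   interpret the neighborhood as an index window in map order, the
   simple reading consistent with a fixed per-side SNP count.
3. **Extended backward.**  The least-explanatory SNP is removed
   greedily; removals continue through up to `max_backward_depth` = 3
   consecutive non-improving eliminations, and the best model seen
   anywhere on the path (including the start) is returned, so
   one-removal local minima can be escaped.

Every accepted move strictly decreases the active criterion, so each
call terminates and its trace (returned as an attribute and exportable
with `write_trace()`) is monotone.  Ties anywhere break toward the
lower SNP index.  When the model outgrows `p2_shrink_threshold`
(default 25) the exchange group is halved as a runtime guard.

`full_search()` is the three-round schedule

* `M1 = fss(null model,  marginal ordering,    mBIC_60)`
* `M2 = fss(M1,          conditional ordering, mBIC_60)`
* `M3 = fss(M2,          conditional ordering, mBIC2)`

and returns `M3` with its mBIC2 value.  The candidate ordering is fixed
within each `fss()` call and recomputed between rounds; recomputing it
after every model change would change no accepted move class but
multiply the ordering cost.

On tiny instances (12 SNPs, 400 individuals) the suite verifies that
`fss()` attains the global minimum found by exhaustive enumeration of
all subsets up to size 3 in at least 90% of seeded replicates.

## Genotype input, QC, and the single-marker comparator

`read_plink()`/`write_plink()` handle the standard PLINK binary trio
(SNP-major `.bed`, magic bytes `6C 1B 01`; genotypes count copies of
the `.bim` A1 allele; on-disk phenotype 1/2 mapped to 0/1).  QC follows
the conventional thresholds: SNPs with MAF below 0.01 or a
Hardy–Weinberg goodness-of-fit p-value below $10^{-4}$ are removed.
The HWE test is the 1-df $\chi^2$ on pooled genotype counts — the
classical variant; an exact test would change little at these sample
sizes.  Residual missing genotypes are mean-imputed per SNP
(`impute_missing()`): deterministic, rank-friendly, and adequate for
the low missingness typical after imputation-grade preprocessing.

The comparator `single_marker_scan()` fits each SNP with ordinary
logistic regression plus the leading four principal components of the
standardized genotype matrix, takes likelihood-ratio p-values (falling
back to the trend test under separation), and applies
Benjamini–Hochberg at level 0.05.

A note on test conventions: the Cochran–Armitage statistic is
implemented in its common form, which is *algebraically identical* to
the efficient score statistic at the ML-fitted intercept-only model;
the $N/(N-1)$ factor sometimes quoted between the two belongs to the
permutation-variance variant of the trend test.  The suite asserts the
identity in both formulations.  Whether the conditional score test
should use the efficient (projected) or naive variance is not fixed by
convention; the efficient variance is the default and the naive one is
available behind a flag.

## The synthetic-data generator

Because the cohort data used in realistic evaluations of such methods
are access-controlled, the package ships a generator
(`simulation_scenario()`, `simulate_dataset()`) that reproduces the
statistical structure those experiments need:

* **Block LD.**  SNP MAFs are uniform on `maf_range`; genotypes come
  from a Gaussian copula — latent equicorrelated normals within blocks
  of `block_size` SNPs (correlation `block_rho`), thresholded at the
  Hardy–Weinberg genotype probabilities.  Blocks are assigned
  round-robin to pseudo-chromosomes.  A brute-force copula oracle in
  the tests confirms the realized genotype-scale correlation
  (attenuated relative to the latent one).
* **Sparse additive risk.**  One causal SNP per causal block, blocks
  spread evenly across chromosomes; within a block the commonest SNP
  carries the effect, since causal variants in such designs are common
  ones.  Effects are drawn from `effect_range` with random signs; the
  default `[0.3, 0.6]` on the log-odds scale gives intermediate power
  at a few thousand individuals and is fully configurable.
* **Balanced sampling.**  The intercept is calibrated by root-finding
  so the mean simulated risk equals `target_prevalence` (default 0.5),
  then statuses are independent Bernoulli draws (prospective
  sampling).
* **Hidden causal SNPs.**  `hide_causal()` removes a fraction (default
  half) of the causal columns before analysis — the "associated marker
  is not the causal one" situation — guaranteeing that each hidden SNP
  leaves a same-block LD partner behind; scoring keeps the original
  identities.

Presets `null`, `k6`, `k12`, `k24` (0, 6, 12, 24 causal SNPs over six
pseudo-chromosomes, `n = 1000`, `p = 600`, blocks of 10 at latent
correlation 0.8) mirror the canonical global-null and complex-trait
designs at sizes that keep a 50–200-replicate study on a single CPU.
What the generator does *not* emulate: population structure and
admixture, haplotype-scale LD decay, genotyping artifacts correlated
with plates or batches.  Passing tests therefore speak to the
statistical machinery, not to robustness against confounding.

## Scoring detections

`score_detections()` uses one correlation constant (default
$r = 0.3$) for both rules: a detection is a true positive when its
genotype correlation with some causal SNP exceeds $r$ (several
detections of one causal SNP count once), and false positives of
redundancy-prone selectors are counted as $r$-clusters — greedy
genomic-order clusters in which *every* pair is correlated above $r$
(`r_cluster()`, whose invariant is checked exhaustively in the tests).
Criterion-based selection is scored unclustered, since it picks one
representative per region anyway; the single-marker comparator is
scored clustered.  A replicate with no detections has FDP 0 by
convention.  Power, FDP and misclassification obey
`power = tp / k_total`, `mis = fp + (k_total - tp)`,
`fdp = fp / max(1, tp + fp)` exactly.

## When is the 10% FDR level attained?

The FDR property of mBIC2 is an asymptotic calibration, and its
practical margin can be summarized in two numbers: the per-SNP
acceptance bar $\log(np^2/c^2) - 2\log k$ and the expected maximum of
$p$ null 1-df statistics ($\approx$ the $1 - 1/p$ quantile of
$\chi^2_1$).  At genuine GWAS scale — hundreds of thousands of markers
and a few thousand samples — the bar sits roughly eight likelihood
units above the null maximum for any realistic model size, and the
selected model's FDR stays near the design level.

At miniature scales the margin can vanish: with $n = p = 1000$ and ten
causal SNPs the bar at realized model sizes $k \approx 12$–$15$ is
about 12.5–12.8, essentially equal to the null maximum (about 11.6,
and slightly higher while the model is still missing causal SNPs).  A
search that minimizes the criterion *well* then provably admits
jointly-overfit null SNPs — in our 100-replicate experiment at this
scale (the one `scripts/acceptance.R` runs) the empirical FDR comes
out near 25%, and removing any of the false positives *increases*
mBIC2, so
this is a property of the criterion at that scale, not of the search.
The same arithmetic governs the warm-up rounds: $\mathrm{mBIC}_{60}$'s
per-SNP bar $\log(np^2/60^2)$ is 12.5 at $n = p = 1000$ — essentially
*at* the null maximum — so under a global null at that scale rounds
1–2 admit a few chance SNPs in a sizable fraction of replicates, and
occasionally a co-adapted set becomes entrenched: each member's
conditional statistic, given the others, exceeds the $k$-lowered mBIC2
removal bar, beyond what the depth-3 backward step can unwind.  In our
100-replicate global-null experiment at $p = 1000$ the mean
false-positive count is therefore a few tenths per dataset (most
replicates select nothing; rare replicates run away), whereas at
$p \gtrsim 30{,}000$ the $\mathrm{mBIC}_{60}$ margin (about 24 versus
a null maximum of about 17.7) makes such runaways essentially
impossible and per-family error rates stay near 0.1.  Users working
with small candidate panels (candidate-gene studies, fine-mapping
regions) should prefer a larger constant $c$ — and a warm-up $E$ far
below $p$ — or treat the selected model's tail with caution; at
genome-wide $p$ the default calibration behaves as designed.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run, by design, at desk
scale: 100 replicates of $n = p = 1000$ for the FDR and global-null
experiments, 50 replicates of the `k6` preset for the power check, 50
twelve-SNP instances against the exhaustive oracle, and
Monte-Carlo/oracle checks of the generator at up to $2\times10^5$
latent draws.  These sizes were chosen so the whole battery completes
in well under an hour on one core while every check retains clear
statistical resolution.

## Known limitations

* Population structure is not modeled; add leading principal
  components as covariates (as the single-marker comparator does) or
  use a mixed-model tool when structure is a first-order concern.
* Quantitative traits, sex-chromosome handling, VCF input and
  reference-panel imputation are out of scope.
* The exchange neighborhood is an index window, not a base-pair
  window; with very uneven marker spacing the two differ.
* Backward elimination explores at most three consecutive
  non-improving removals; pathological criterion landscapes could in
  principle require more.
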