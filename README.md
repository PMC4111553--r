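# mbicgwas

Multi-marker model selection for case-control genome-wide association
studies (GWAS).  Instead of testing each SNP separately, `mbicgwas`
selects one multi-SNP logistic regression model for disease status by
minimizing **mBIC2**, a modification of the Bayesian information
criterion whose penalty controls the false discovery rate of the
selected SNPs, with **Firth's Jeffreys-prior penalty** keeping every
candidate fit finite under complete separation.  A three-round **fast
stepwise search** (directed forward, exchange and extended backward
steps over candidate groups ranked by trend and conditional score
tests) makes the subset minimization tractable at GWAS scale.

For a model $M$ with $k$ SNPs out of $p$ candidates on $n$ individuals,

$$
\mathrm{mBIC2}(M) = -2\,l^*(\hat\beta_M) + k\,\log\frac{n\,p^2}{c^2}
  - 2\log k!, \qquad c = 4,
$$

where $l^*(\beta) = l(\beta) + \tfrac12\log\det X^\top W X$ is the
Firth-penalized logistic log-likelihood.  The $-2\log k!$ term lowers
the bar for the $k$-th accepted SNP in the same step-up fashion as the
Benjamini–Hochberg rule, giving FDR-type rather than family-wise
control (design level roughly 10%).  Search rounds 1–2 use the milder
$\mathrm{mBIC}_{60}$ ($-2 l^* + k\log(np^2/60^2)$) to avoid losing
causal SNPs to local minima; the final round minimizes mBIC2.

The package also provides PLINK binary (`.bed/.bim/.fam`) input and
output with MAF/Hardy-Weinberg QC and mean imputation, a
single-marker + principal-components + Benjamini–Hochberg comparator,
a block-LD genotype/phenotype simulator (Gaussian copula), and scoring
utilities (power, false positives, FDR, misclassifications, with
correlation-threshold truth matching and r-clustering) for replicated
simulation studies.  It is aimed at statistical geneticists who want
criterion-based multi-marker selection with explicit error control,
and at methodologists who need a fully synthetic, reproducible test
bed for it.

## Worked example

Simulate the `k6` preset (1000 individuals, 600 SNPs in LD blocks of
10 at latent correlation 0.8, six common causal SNPs with log-odds
effects in [0.3, 0.6], half of them hidden behind LD proxies before
analysis), then run the full three-round search:

```r
library(mbicgwas)

sc  <- scenario_preset("k6", seed = 42)
ds  <- simulate_dataset(sc)
ds
#> GenotypeDataset: 1000 individuals x 597 SNPs (504 cases, 496 controls)

attr(ds, "causal")    # true causal SNPs (original indices)
#> [1]   2 128 250 358 474 594
attr(ds, "hidden")    # removed before analysis; only LD proxies remain
#> [1]   2 128 250

fit <- full_search(ds)
fit
#> ModelFit: 7 SNP(s), penalized logLik -594.6860, converged in 5 iteration(s)
#>   SNP columns: 4, 124, 162, 241, 355, 471, 591

sel <- mbicgwas:::orig_index(ds)[fit$snp_indices]
res <- score_detections(sel, attr(ds, "causal"),
                        cor(attr(ds, "full_ds")$genotypes),
                        evaluation_config(r_threshold = 0.3))
unlist(res[c("tp_causal", "fp_clusters", "power", "fdp", "mis")])
#> tp_causal fp_clusters       power         fdp         mis
#>         6           1   1.0000000   0.1428571           1
```

All six causal SNPs are recovered — the three hidden ones through
same-block LD proxies (e.g. column 5 tags hidden causal SNP 2) — at
the cost of one false positive; the realized FDP of 1/7 sits at the
criterion's design level.  The model's mBIC2 value is carried in
`attr(fit, "criterion")` and the full search trace (round, sweep,
step, model size, criterion) in `attr(fit, "trace")`.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/mbicgwas.R simulate --preset k6 --seed 42 --out /tmp/k6
Rscript inst/scripts/mbicgwas.R select   --bfile /tmp/k6 --out /tmp/k6_out
Rscript inst/scripts/mbicgwas.R evaluate --preset null --replicates 20 \
        --seed 1 --out /tmp/null_out
Rscript inst/scripts/mbicgwas.R scan     --bfile /tmp/k6 --q 0.05 --pcs 4
```

See the vignette (`vignettes/model-selection.Rmd`) for the model, the
search heuristic, the generator's assumptions, and an analysis of the
scales at which the 10% FDR calibration does and does not hold.

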