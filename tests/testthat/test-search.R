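# Fast stepwise search: individual steps, the FSS loop and the
# three-round schedule.

test_that("directed forward adds a planted strong SNP and nothing on empty input", {
  ds <- planted_dataset(400, 12, causal = 3L, betas = 1.5, seed = 1)
  cfg <- search_config(p1 = 12, p2 = 12)
  fit0 <- firth_fit(ds)
  ord <- order_snps(ds, fit0, "marginal")
  expect_equal(ord$order[1], 3L)

  fit1 <- directed_forward(ds, fit0, ord, cfg)
  expect_equal(fit1$snp_indices, 3L)
  expect_lt(attr(fit1, "criterion"),
            mbic2(fit0$penalized_loglik, ds$n, ds$p, 0, cfg$criterion))
  # direct criterion evaluation of both models agrees with the step
  expect_equal(attr(fit1, "criterion"),
               mbic2(firth_fit(ds, 3L)$penalized_loglik, ds$n, ds$p, 1,
                     cfg$criterion),
               tolerance = 1e-6)

  # empty candidate group: unchanged
  empty_ord <- structure(list(order = integer(0), statistics = numeric(0)),
                         class = "SnpOrdering")
  expect_equal(directed_forward(ds, fit1, empty_ord, cfg)$snp_indices, 3L)
})

test_that("forward step leaves pure-noise models untouched", {
  ds <- random_dataset(300, 15, seed = 5)
  cfg <- search_config(p1 = 15, p2 = 15)
  fit0 <- firth_fit(ds)
  ord <- order_snps(ds, fit0, "marginal")
  fit1 <- directed_forward(ds, fit0, ord, cfg)
  # criterion never increased
  expect_lte(attr(fit1, "criterion"),
             mbic2(fit0$penalized_loglik, ds$n, ds$p, 0, cfg$criterion) + 1e-9)
})

test_that("exchange step replaces a proxy with the correlated causal SNP", {
  set.seed(2)
  n <- 500
  latent <- rnorm(n)
  g_causal <- (latent > qnorm(0.49)) + (latent > qnorm(0.91))
  noisy <- 0.75 * latent + sqrt(1 - 0.75^2) * rnorm(n)
  g_proxy <- (noisy > qnorm(0.49)) + (noisy > qnorm(0.91))
  fill <- vapply(runif(6, 0.2, 0.4), function(m) rbinom(n, 2, m), numeric(n))
  g <- cbind(fill[, 1:3], g_proxy, g_causal, fill[, 4:6])
  y <- rbinom(n, 1, plogis(1.2 * (g_causal - mean(g_causal))))
  ds <- mk_dataset(g, y)

  cfg <- search_config(p1 = 8, p2 = 8, window = 2)
  fit_proxy <- firth_fit(ds, 4L)   # the proxy, column 4; causal is column 5
  expect_gt(firth_fit(ds, 5L)$penalized_loglik, fit_proxy$penalized_loglik)
  swapped <- exchange_step(ds, fit_proxy, cfg)
  expect_equal(swapped$snp_indices, 5L)
  expect_lte(attr(swapped, "criterion"),
             mbic2(fit_proxy$penalized_loglik, ds$n, ds$p, 1, cfg$criterion))

  # empty model: unchanged
  f0 <- firth_fit(ds)
  expect_equal(exchange_step(ds, f0, cfg)$snp_indices, integer(0))
})

test_that("exchange honors the same-chromosome index window", {
  ds <- planted_dataset(300, 10, causal = 2L, betas = 1.2, seed = 9)
  ds$snps$chrom <- rep(c("1", "2"), each = 5)
  cfg <- search_config(p1 = 10, p2 = 10, window = 1)
  fit <- firth_fit(ds, 7L)
  out <- exchange_step(ds, fit, cfg)
  # SNP 2 (other chromosome) can never be swapped in for SNP 7
  expect_true(all(out$snp_indices %in% 6:8))
})

test_that("backward step removes appended noise and never worsens", {
  ds <- planted_dataset(400, 12, causal = c(2L, 9L), betas = c(1.3, 1.1),
                        seed = 3)
  cfg <- search_config(p1 = 12, p2 = 12)
  bloated <- firth_fit(ds, c(2L, 5L, 9L))   # SNP 5 is noise
  slim <- backward_step(ds, bloated, cfg)
  expect_equal(slim$snp_indices, c(2L, 9L))
  expect_lt(attr(slim, "criterion"),
            mbic2(bloated$penalized_loglik, ds$n, ds$p, 3, cfg$criterion))
  # null model: unchanged
  f0 <- firth_fit(ds)
  expect_equal(backward_step(ds, f0, cfg)$snp_indices, integer(0))
})

test_that("backward explores beyond one non-improving removal", {
  ds <- planted_dataset(400, 12, causal = c(2L, 9L), betas = c(1.3, 1.1),
                        seed = 3)
  cfg <- search_config(p1 = 12, p2 = 12, max_backward_depth = 3)
  start <- firth_fit(ds, c(1L, 2L, 5L, 9L))
  out <- backward_step(ds, start, cfg)
  crit_start <- mbic2(start$penalized_loglik, ds$n, ds$p, 4, cfg$criterion)
  expect_lte(attr(out, "criterion"), crit_start)
  expect_true(all(c(2L, 9L) %in% out$snp_indices) || length(out$snp_indices) < 2)
})

test_that("fss attains the exhaustive optimum on a planted instance", {
  ds <- planted_dataset(400, 12, causal = 6L, betas = 1.4, seed = 4)
  cfg <- search_config(p1 = 12, p2 = 12,
                       criterion = criterion_config("mBIC2"))
  found <- fss(ds, firth_fit(ds), "marginal", cfg)
  oracle <- exhaustive_best(ds, kmax = 2)
  expect_equal(sort(found$snp_indices), sort(oracle$indices))
  expect_equal(attr(found, "criterion"), oracle$crit, tolerance = 1e-6)
})

test_that("fss is a fixed point of itself and its trace never increases", {
  ds <- planted_dataset(500, 15, causal = c(4L, 11L), betas = c(1.2, 1.0),
                        seed = 6)
  cfg <- search_config(p1 = 15, p2 = 15,
                       criterion = criterion_config("mBIC2"))
  f1 <- fss(ds, firth_fit(ds), "marginal", cfg)
  f2 <- fss(ds, f1, "marginal", cfg)
  expect_equal(f2$snp_indices, f1$snp_indices)
  expect_equal(attr(f2, "criterion"), attr(f1, "criterion"), tolerance = 1e-9)

  tr <- attr(f1, "trace")
  expect_true(all(diff(tr$criterion) <= 1e-9))
})

test_that("full_search is deterministic and round-3 honors mBIC2", {
  ds <- planted_dataset(400, 20, causal = c(3L, 14L), betas = c(1.2, 1.2),
                        seed = 8)
  cfg <- search_config(p1 = 20, p2 = 20)
  a <- full_search(ds, cfg)
  b <- full_search(ds, cfg)
  expect_identical(a$snp_indices, b$snp_indices)
  expect_equal(attr(a, "criterion"), attr(b, "criterion"))
  expect_true(all(c(3L, 14L) %in% a$snp_indices))

  tr <- attr(a, "trace")
  expect_setequal(unique(tr$round), 1:3)
  # final model's mBIC2 never above the round-2 model evaluated under mBIC2
  r2_end <- tr[tr$round == 2, ]
  expect_lte(attr(a, "criterion") - 1e-9,
             {m2 <- fss(ds, firth_fit(ds), "marginal",
                        search_config(p1 = 20, p2 = 20,
                                      criterion = criterion_config("mBIC_E")))
              m2b <- fss(ds, m2, "conditional",
                         search_config(p1 = 20, p2 = 20,
                                       criterion = criterion_config("mBIC_E")))
              mbic2(m2b$penalized_loglik, ds$n, ds$p,
                    length(m2b$snp_indices), criterion_config())})
})

test_that("write_trace emits a readable tab-separated log", {
  ds <- planted_dataset(300, 10, causal = 5L, betas = 1.3, seed = 10)
  fit <- full_search(ds, search_config(p1 = 10, p2 = 10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(fit, path)
  tr <- read.table(path, header = TRUE, sep = "\t")
  expect_named(tr, c("round", "sweep", "step", "model_size", "criterion"))
  expect_gt(nrow(tr), 0)
})
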