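# Marginal and conditional association tests, BH, and the
# single-marker comparator.

test_that("Cochran-Armitage statistic matches hand-evaluated tables", {
  # perfect balance: statistic 0
  g <- rep(c(0, 1, 2), each = 40)
  y <- rep(c(1, 0), 60)
  expect_equal(cochran_armitage(mk_dataset(matrix(g, 120), y), 1)$statistic, 0)

  # cases (0,0,10) vs controls (10,0,0): statistic 20
  g2 <- c(rep(2, 10), rep(0, 10))
  y2 <- c(rep(1, 10), rep(0, 10))
  res <- cochran_armitage(mk_dataset(matrix(g2, 20), y2), 1)
  expect_equal(res$statistic, 20, tolerance = 1e-12)
  expect_equal(res$p, pchisq(20, 1, lower.tail = FALSE))

  expect_error(cochran_armitage(mk_dataset(matrix(rep(1, 10), 10),
                                           rbinom(10, 1, .5)), 1),
               "constant")
})

test_that("trend p-values stay in [0,1] over random tables", {
  set.seed(31)
  for (i in 1:50) {
    ds <- random_dataset(40, 1, maf = runif(1, 0.1, 0.5))
    if (length(unique(ds$genotypes[, 1])) < 2) next
    p <- cochran_armitage(ds, 1)$p
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("score test vanishes for a column collinear with the design", {
  set.seed(17)
  g <- rbinom(50, 2, 0.4)
  ds <- mk_dataset(cbind(g, g), rbinom(50, 1, 0.5))
  fit <- firth_fit(ds, 1L)
  expect_warning(st <- score_test(ds, fit, 2L), "collinear")
  expect_equal(st, 0)
  expect_error(score_test(ds, fit, 1L), "already in the model")
})

test_that("score test at the ML null equals the trend statistic", {
  set.seed(23)
  checked <- 0
  for (i in 1:100) {
    n <- sample(c(30, 60, 101), 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    y <- rbinom(n, 1, runif(1, 0.3, 0.7))
    if (length(unique(g)) < 2 || length(unique(y)) < 2) next
    ds <- mk_dataset(matrix(g, n), y)
    null_ml <- structure(list(snp_indices = integer(0),
                              beta = qlogis(mean(y)),
                              fitted = rep(mean(y), n)),
                         class = "ModelFit")
    st <- score_test(ds, null_ml, 1L)
    ca <- cochran_armitage(ds, 1)$statistic
    # exact algebraic identity (factor 1); the N/(N-1) factor relates
    # the score test to the permutation-variance trend variant
    expect_equal(st, ca, tolerance = 1e-6)
    R <- sum(y)
    ca_perm <- ca * (n - 1) / n   # permutation-variance trend form
    expect_equal(st, ca_perm * n / (n - 1), tolerance = 1e-6)
    checked <- checked + 1
  }
  expect_gte(checked, 90)
})

test_that("score statistics are nonnegative quadratic forms", {
  set.seed(41)
  ds <- random_dataset(200, 30)
  fit <- firth_fit(ds, c(3L, 10L))
  stats <- suppressWarnings(
    vapply(setdiff(1:30, c(3L, 10L)),
           function(j) score_test(ds, fit, j), numeric(1)))
  expect_true(all(stats >= 0))
  # naive variance never below efficient variance: stat_naive <= stat_eff
  st_e <- score_test(ds, fit, 5L, efficient = TRUE)
  st_n <- score_test(ds, fit, 5L, efficient = FALSE)
  expect_lte(st_n, st_e + 1e-10)
})

test_that("order_snps sorts by statistic with index tie-breaks", {
  # three SNPs engineered so marginal statistics order as s2 > s3 > s1
  set.seed(51)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  g1 <- rbinom(n, 2, 0.3)
  g2 <- rbinom(n, 2, plogis(-1 + 2.0 * y))
  g3 <- rbinom(n, 2, plogis(-1 + 0.8 * y))
  ds <- mk_dataset(cbind(g1, g2, g3), y)
  fit0 <- firth_fit(ds)
  ord <- order_snps(ds, fit0, "marginal")
  expect_equal(ord$order[1], 2L)
  expect_equal(sort(ord$order), 1:3)
  expect_true(all(diff(ord$statistics) <= 0))

  # exact ties break toward the lower index: duplicate a column pattern
  ds2 <- mk_dataset(cbind(g1, g1, g2), y)
  suppressWarnings(ord2 <- order_snps(ds2, fit0, "marginal"))
  tie_pos <- which(ord2$order %in% c(1L, 2L))
  expect_equal(ord2$order[tie_pos], c(1L, 2L))

  # ordering excludes model SNPs and remains a permutation
  fit1 <- firth_fit(ds, 2L)
  ord3 <- suppressWarnings(order_snps(ds, fit1, "conditional"))
  expect_equal(sort(ord3$order), c(1L, 3L))
})

test_that("conditional ordering at the null agrees with marginal ranking", {
  set.seed(61)
  ds <- random_dataset(300, 12)
  null_ml <- structure(list(snp_indices = integer(0),
                            beta = qlogis(mean(ds$phenotype)),
                            fitted = rep(mean(ds$phenotype), ds$n)),
                       class = "ModelFit")
  m <- order_snps(ds, null_ml, "marginal")
  c_ <- order_snps(ds, null_ml, "conditional")
  # consequence of the exact score/trend identity at the ML null
  expect_equal(c_$order, m$order)
  expect_equal(c_$statistics, m$statistics, tolerance = 1e-6)
})

test_that("Benjamini-Hochberg matches direct step-up enumeration", {
  expect_equal(benjamini_hochberg(c(0.001, 0.01, 0.02, 0.9), 0.05), 1:3)
  expect_equal(benjamini_hochberg(rep(1, 6), 0.05), integer(0))
  expect_equal(benjamini_hochberg(0.04, 0.05), 1L)

  bh_direct <- function(p, q) {
    m <- length(p)
    o <- order(p)
    istar <- suppressWarnings(max(which(p[o] <= seq_len(m) * q / m)))
    if (!is.finite(istar)) integer(0) else sort(o[seq_len(istar)])
  }
  set.seed(71)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_equal(sort(benjamini_hochberg(p, q)), bh_direct(p, q))
  }
})

test_that("BH rejections grow monotonically in the level q", {
  set.seed(81)
  p <- runif(50)^2
  prev <- integer(0)
  for (q in c(0.01, 0.05, 0.1, 0.2, 0.5)) {
    cur <- benjamini_hochberg(p, q)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("single_marker_scan reduces to one logistic LRT when p = 1", {
  set.seed(91)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * g))
  ds <- mk_dataset(matrix(g, n), y)
  res <- single_marker_scan(ds, q = 0.05, n_pcs = 0)
  f0 <- glm(y ~ 1, family = binomial())
  f1 <- glm(y ~ g, family = binomial())
  p_direct <- pchisq(deviance(f0) - deviance(f1), 1, lower.tail = FALSE)
  expect_equal(res$p[1], p_direct, tolerance = 1e-8)
  expect_equal(res$selected, if (p_direct <= 0.05) 1L else integer(0))
  expect_named(res$table, c("snp_id", "statistic", "p", "rejected"))
})

test_that("single_marker_scan controls false positives on pure noise", {
  set.seed(101)
  fp <- vapply(1:60, function(i) {
    ds <- random_dataset(150, 120)
    length(single_marker_scan(ds, q = 0.05, n_pcs = 4)$selected)
  }, numeric(1))
  expect_lte(mean(fp), 0.15)
})
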