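test_that("a noiseless linear relationship is fit exactly", {
  x <- rep(c(0, 1, 2), 10)
  rec <- fit_conventional(2 * x, x)
  expect_equal(rec$beta1, 2, tolerance = 1e-12)
  expect_equal(rec$model, "conventional")
  expect_equal(rec$n, 30)
})

test_that("per-pair OLS matches the lm() oracle exactly", {
  set.seed(41)
  n <- 80
  x <- sample(0:2, n, TRUE)
  covar <- cbind(pc1 = rnorm(n), pc2 = rnorm(n))
  pn <- runif(n, 0.05, 0.6)
  y <- 0.5 + 0.3 * x - 0.2 * pn + 0.15 * pn * x +
    0.1 * covar[, 1] + rnorm(n)

  conv <- fit_conventional(y, x, covariates = covar)
  m1 <- summary(lm(y ~ x + covar))$coefficients["x", ]
  expect_equal(conv$beta1, unname(m1["Estimate"]), tolerance = 1e-12)
  expect_equal(conv$se1, unname(m1["Std. Error"]), tolerance = 1e-12)
  expect_equal(conv$p, unname(m1["Pr(>|t|)"]), tolerance = 1e-12)

  intr <- fit_interaction(y, x, purity = 1 - pn, covariates = covar)
  m2 <- summary(lm(y ~ x + covar + pn + x:pn))$coefficients
  expect_equal(intr$beta1, m2["x", "Estimate"], tolerance = 1e-12)
  expect_equal(intr$se1, m2["x", "Std. Error"], tolerance = 1e-12)
  expect_equal(intr$p, m2["x", "Pr(>|t|)"], tolerance = 1e-12)
  expect_equal(intr$beta4, m2["pn", "Estimate"], tolerance = 1e-12)
  expect_equal(intr$beta5, m2["x:pn", "Estimate"], tolerance = 1e-12)
})

test_that("the interaction model decomposes a constructed mixture exactly", {
  set.seed(42)
  n <- 60
  x <- sample(0:2, n, TRUE)
  pn <- runif(n, 0.1, 0.6)              # normal fraction
  y <- 1 + 0.4 * x * (1 - pn)           # effect only in the cancer fraction
  rec <- fit_interaction(y, x, purity = 1 - pn)
  expect_equal(rec$beta1, 0.4, tolerance = 1e-10)
  expect_equal(rec$beta5, -0.4, tolerance = 1e-10)
  expect_equal(rec$beta4, 0, tolerance = 1e-10)
})

test_that("degenerate designs raise informative errors", {
  y <- rnorm(20)
  expect_error(fit_conventional(y, rep(1, 20)), "constant")
  expect_error(fit_interaction(y, sample(0:2, 20, TRUE),
                               purity = rep(0.7, 20)),
               "normal_fraction")
  x <- sample(0:2, 20, TRUE)
  expect_error(fit_conventional(y, x, covariates = cbind(dup = x)),
               "collinear")
})

test_that("BH adjustment agrees with a step-up enumeration oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  base <- c(0.01, 0.2, 0.04, 0.8, 0.001, 0.6)
  perms <- replicate(30, sample(length(base)))
  for (k in seq_len(ncol(perms))) {
    p <- base[perms[, k]]
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  set.seed(43)
  for (m in 1:6) {
    p <- runif(m)
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  withna <- c(0.01, NA, 0.5)
  q <- bh_fdr(withna)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(c(0.01, 0.5)))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the Z-difference test matches the normal-CDF oracle", {
  rec <- zdiff_test(0.5, 0.1, 0.0, 0.1)
  expect_equal(rec$z, 0.5 / sqrt(0.02), tolerance = 1e-10)
  expect_equal(rec$z, 3.5355339, tolerance = 1e-6)
  expect_equal(rec$p, 2 * pnorm(-0.5 / sqrt(0.02)), tolerance = 1e-12)
  expect_equal(rec$p, 4.07e-4, tolerance = 1e-2)
  same <- zdiff_test(0.3, 0.05, 0.3, 0.08)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  a <- zdiff_test(0.2, 0.04, -0.1, 0.06)
  b <- zdiff_test(-0.1, 0.06, 0.2, 0.04)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(zdiff_test(0.1, 0, 0.2, 0.1), "positive")
  set.seed(44)
  v <- zdiff_test(rnorm(20), runif(20, 0.01, 1), rnorm(20),
                  runif(20, 0.01, 1))
  expect_equal(v$p, 2 * (1 - pnorm(abs(v$z))), tolerance = 1e-10)
})

test_that("scans reproduce single-pair fits and flag degenerate pairs", {
  co <- tiny_cohort(seed = 51)
  res <- quiet_scan(co, model = "interaction",
                    purity = co$purity)
  i <- 7
  single <- fit_interaction(co$expression[, i], co$genotypes[, i],
                            purity = co$purity)
  expect_equal(res$beta1[i], single$beta1, tolerance = 1e-12)
  expect_equal(res$se1[i], single$se1, tolerance = 1e-12)
  expect_equal(res$p[i], single$p, tolerance = 1e-12)
  # q is a monotone transform of p
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-15))
  # a constant variant yields a NaN record, not an error or a dropped row
  geno2 <- co$genotypes
  geno2[, 3] <- 1
  res2 <- quiet_scan(co$expression, geno2, model = "conventional")
  expect_equal(res2$status[3], "rank_deficient")
  expect_true(is.nan(res2$beta1[3]))
  expect_equal(nrow(res2), ncol(co$expression))
  expect_error(quiet_scan(co$expression[1:10, ], co$genotypes,
                          model = "conventional"),
               "samples")
})

test_that("genotype p-values are uniform when no eQTL exists", {
  co <- tiny_cohort(seed = 52, n_samples = 400, genes_per_group = 25)
  res <- quiet_scan(co, model = "conventional")
  p4 <- res$p[co$truth$group == "4"]
  expect_gt(stats::ks.test(p4, "punif")$p.value, 0.01)
  expect_lt(mean(p4 < 0.05), 0.16)
})

test_that("interaction and conventional estimates agree on a near-pure cohort", {
  cfg <- sim_config(n_samples = 500, genes_per_group = 10,
                    purity_shape1 = 3000, purity_shape2 = 10)  # purity ~ 0.997
  co <- simulate_cohort(cfg, seed = 55)
  conv <- quiet_scan(co, model = "conventional")
  intr <- quiet_scan(co, model = "interaction", purity = co$purity)
  # with essentially no normal contamination the bulk effect IS the cancer
  # effect; the extrapolation only adds estimation noise
  expect_lt(mean(abs(intr$beta1 - conv$beta1)), 0.25)
  expect_lt(abs(mean(intr$beta1 - conv$beta1)), 0.05)
  slope <- coef(lm(intr$beta1 ~ conv$beta1))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("binned effects partition the cohort and expose attenuation", {
  set.seed(56)
  n <- 600
  x <- sample(0:2, n, TRUE)
  cf <- runif(n, 0.25, 0.95)
  # strong normal-only eQTL: bulk effect scales with the normal fraction
  y <- 1 + 0.6 * x * (1 - cf) + rnorm(n, 0, 0.3)
  be <- suppressMessages(binned_effects(y, x, cf, n_bins = 5))
  expect_equal(sum(be$n_in_bin), n)
  expect_true(all(diff(be$purity_low) > 0))
  expect_true(all(be$purity_high[-5] <= be$purity_low[-1]))
  # low-purity bins carry the larger apparent effect
  expect_gt(abs(be$beta[1]), abs(be$beta[5]))
  # extrapolated cancer-cell estimate near zero, bulk estimate is not
  expect_lt(abs(attr(be, "interaction")$beta1), 0.1)
  expect_gt(abs(attr(be, "conventional")$beta1), 0.1)
  expect_error(binned_effects(y[1:15], x[1:15], cf[1:15], n_bins = 5),
               "too few")
})
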