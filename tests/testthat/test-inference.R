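test_that("pooled estimate and conventional standard error are correct", {
  d <- toy_dataset()
  p <- pooled_re(d, 0.25)
  expect_equal(p$mu_hat, 0.5, tolerance = 1e-12)
  expect_equal(p$se, 0.5, tolerance = 1e-12)

  p0 <- pooled_re(d, 0)
  expect_equal(p0$mu_hat, 0.5, tolerance = 1e-12)
  expect_equal(p0$se, 1 / sqrt(8), tolerance = 1e-12)

  dom <- pooled_re(meta_dataset(c(2, -3), c(1e-8, 1e8)), 0)
  expect_equal(dom$mu_hat, 2, tolerance = 1e-6)
})

test_that("H* matches hand arithmetic and limiting cases", {
  d <- toy_dataset()
  expect_equal(hstar(d, 0.25), 1.0, tolerance = 1e-12)
  expect_equal(hstar(meta_dataset(c(0, 0.6), c(0.25, 0.25)), 0),
               sqrt(0.72), tolerance = 1e-12)
  expect_equal(hstar(meta_dataset(c(0.2, 0.2), c(1, 2)), 0.1), 0)
})

test_that("standard random-effects interval uses normal quantiles", {
  d <- toy_dataset()
  res <- ci_standard_re(d, tau2_dl(d), alpha = 0.05)
  z <- qnorm(0.975)
  expect_equal(res$ci_lower, 0.5 - z * 0.5, tolerance = 1e-10)
  expect_equal(res$ci_upper, 0.5 + z * 0.5, tolerance = 1e-10)
  expect_true(is.na(res$df))

  # tau2 = 0 collapses to the common-effect interval exactly
  re0 <- ci_standard_re(d, 0, alpha = 0.05)
  ce <- ci_common_effect(d, alpha = 0.05)
  expect_equal(re0$ci_lower, ce$ci_lower, tolerance = 1e-14)
  expect_equal(re0$ci_upper, ce$ci_upper, tolerance = 1e-14)

  # alpha near 1 collapses the interval onto the point estimate
  near <- ci_standard_re(d, 0.25, alpha = 1 - 1e-12)
  expect_equal(near$ci_lower, 0.5, tolerance = 1e-5)
  expect_equal(near$ci_upper, 0.5, tolerance = 1e-5)
})

test_that("modified interval applies H* scaling and t quantiles", {
  d <- toy_dataset()
  res <- ci_modified(d, 0.25, alpha = 0.05)
  t1 <- qt(0.975, 1)
  expect_equal(res$se, 0.5, tolerance = 1e-12)  # H* = 1 here
  expect_equal(res$ci_lower, 0.5 - t1 * 0.5, tolerance = 1e-8)
  expect_equal(res$ci_upper, 0.5 + t1 * 0.5, tolerance = 1e-8)
  expect_equal(res$mu_hat, ci_standard_re(d, 0.25)$mu_hat)

  # wider than common-effect despite tau2 = 0 (group-13 pattern)
  d13 <- meta_dataset(c(0, 0.6), c(0.25, 0.25))
  m13 <- ci_modified(d13, 0, alpha = 0.05)
  expect_equal(ci_width(m13) / 2, t1 * sqrt(0.72) / sqrt(8),
               tolerance = 1e-10)
  expect_gt(ci_width(m13), ci_width(ci_common_effect(d13)))

  # narrower than common-effect (group-16 pattern)
  d16 <- meta_dataset(c(0, 0.1), c(0.25, 0.25))
  m16 <- ci_modified(d16, 0, alpha = 0.05)
  expect_equal(ci_width(m16) / 2, t1 * sqrt(0.02) / sqrt(8),
               tolerance = 1e-10)
  expect_lt(ci_width(m16), ci_width(ci_common_effect(d16)))
})

test_that("modified inference refuses degenerate datasets", {
  dg <- meta_dataset(c(0.3, 0.3), c(0.2, 0.4))
  expect_error(ci_modified(dg, 0), "zero standard error",
               class = "hkmeta_degenerate_error")
  expect_error(ci_modified_constrained(dg, 0),
               class = "hkmeta_degenerate_error")
})

test_that("constrained interval forces H* to at least 1", {
  d16 <- meta_dataset(c(0, 0.1), c(0.25, 0.25))
  res <- ci_modified_constrained(d16, 0, alpha = 0.05)
  expect_equal(ci_width(res) / 2, qt(0.975, 1) / sqrt(8), tolerance = 1e-10)

  # inactive when H* >= 1
  d <- meta_dataset(c(0, 1, 3), c(0.2, 0.3, 0.4))
  t2 <- tau2_dl(d)$value
  if (hstar(d, t2) >= 1) {
    expect_equal(ci_width(ci_modified_constrained(d, t2)),
                 ci_width(ci_modified(d, t2)), tolerance = 1e-14)
  }

  # never narrower than the standard random-effects interval
  set.seed(201)
  for (i in 1:200) {
    dr <- random_dataset(sample(2:10, 1), tau2 = runif(1, 0, 1))
    t2r <- tau2_dl(dr)$value
    expect_gte(ci_width(ci_modified_constrained(dr, t2r)),
               ci_width(ci_standard_re(dr, t2r)) - 1e-12)
  }
})

test_that("common-effect interval matches hand arithmetic", {
  d <- toy_dataset()
  ce <- ci_common_effect(d, alpha = 0.05)
  expect_equal(ce$mu_hat, 0.5, tolerance = 1e-12)
  expect_equal(ci_width(ce) / 2, qnorm(0.975) / sqrt(8), tolerance = 1e-10)

  # equal variances: the estimate is the unweighted mean
  dev <- meta_dataset(c(0.2, 0.9, 1.3), rep(0.4, 3))
  expect_equal(ci_common_effect(dev)$mu_hat, mean(dev$y), tolerance = 1e-12)

  # RE interval is always at least as wide as the CE interval
  set.seed(202)
  for (i in 1:200) {
    dr <- random_dataset(sample(2:10, 1), tau2 = runif(1, 0, 1))
    expect_gte(ci_width(ci_standard_re(dr, tau2_dl(dr)$value)),
               ci_width(ci_common_effect(dr)) - 1e-12)
  }
})

test_that("modified intervals agree with metafor's Knapp-Hartung option", {
  skip_if_not_installed("metafor")
  set.seed(203)
  for (i in 1:20) {
    d <- random_dataset(sample(2:10, 1), tau2 = runif(1, 0, 1.5))
    fit <- suppressWarnings(
      metafor::rma(yi = d$y, vi = d$v, method = "DL", test = "knha"))
    res <- ci_modified(d, tau2_dl(d), alpha = 0.05)
    expect_equal(res$mu_hat, as.numeric(fit$beta), tolerance = 1e-8)
    expect_equal(res$se, fit$se, tolerance = 1e-8)
    expect_equal(res$ci_lower, fit$ci.lb, tolerance = 1e-6)
    expect_equal(res$ci_upper, fit$ci.ub, tolerance = 1e-6)
  }
})

test_that("two-study H*^2 equals the product form w1 w2 (y1-y2)^2 / (w1+w2)", {
  set.seed(204)
  for (i in 1:200) {
    d <- random_dataset(2, tau2 = runif(1, 0, 1))
    t2 <- runif(1, 0, 2)
    w <- 1 / (d$v + t2)
    expect_equal(hstar(d, t2)^2,
                 w[1] * w[2] * (d$y[1] - d$y[2])^2 / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("the CI excludes zero exactly when p < alpha, per method", {
  set.seed(205)
  for (i in 1:100) {
    d <- random_dataset(sample(2:8, 1), tau2 = runif(1, 0, 1))
    t2 <- tau2_dl(d)$value
    alpha <- runif(1, 0.01, 0.2)
    for (res in list(ci_standard_re(d, t2, alpha),
                     ci_modified(d, t2, alpha),
                     ci_common_effect(d, alpha))) {
      excludes <- res$ci_lower > 0 || res$ci_upper < 0
      expect_identical(excludes, res$p_value < alpha)
    }
  }
})
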