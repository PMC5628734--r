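test_that("generalized_q matches hand-computed values and is monotone", {
  d <- toy_dataset()
  # w_i = 2 at tau2 = 0.25, weighted mean 0.5: Q = 2*.25 + 2*.25 = 1
  expect_equal(generalized_q(d, 0.25), 1.0, tolerance = 1e-12)

  d3 <- meta_dataset(c(0, 1, 2), c(0.5, 1.0, 0.25))
  # fixed-effect weights (2, 1, 4), weighted mean 9/7: Q = 266/49
  expect_equal(generalized_q(d3, 0), 266 / 49, tolerance = 1e-12)

  expect_equal(generalized_q(meta_dataset(c(1, 1, 1), 1:3), 0.7), 0)

  # non-increasing in tau2, on random datasets over a grid
  set.seed(101)
  for (i in 1:20) {
    d <- random_dataset(sample(2:10, 1))
    q <- vapply(seq(0, 5, by = 0.25), function(t2) generalized_q(d, t2),
                numeric(1))
    expect_true(all(diff(q) <= 1e-12))
  }
})

test_that("DerSimonian-Laird estimator reproduces the moment formula", {
  d3 <- meta_dataset(c(0, 1, 2), c(0.5, 1.0, 0.25))
  est <- tau2_dl(d3)
  expect_equal(est$value, (266 / 49 - 2) / (7 - 21 / 7), tolerance = 1e-10)
  expect_false(est$truncated)

  d <- meta_dataset(c(0, 0.1), c(0.25, 0.25))
  est2 <- tau2_dl(d)
  expect_equal(est2$value, 0)
  expect_true(est2$truncated)
  expect_equal(est2$pre_truncation, -0.245, tolerance = 1e-12)

  est3 <- tau2_dl(meta_dataset(c(0.4, 0.4, 0.4), c(1, 2, 3)))
  expect_equal(est3$value, 0)
  expect_true(est3$truncated)
})

test_that("REML estimator honours the equal-variance and n=2 identities", {
  dev <- meta_dataset(c(0, 0.5, 1.0), c(0.1, 0.1, 0.1))
  est <- tau2_reml(dev)
  expect_equal(est$value, 0.15, tolerance = 1e-9)
  expect_true(est$converged)

  d2 <- toy_dataset()
  expect_equal(tau2_reml(d2)$value, 0.25, tolerance = 1e-9)
  expect_equal(tau2_reml(d2)$value, tau2_dl(d2)$value, tolerance = 1e-9)

  expect_equal(tau2_reml(meta_dataset(c(1, 1, 1), c(1, 2, 3)))$value, 0)
})

test_that("REML agrees with metafor on random datasets", {
  skip_if_not_installed("metafor")
  set.seed(102)
  for (i in 1:20) {
    d <- random_dataset(sample(3:12, 1), tau2 = runif(1, 0, 2))
    fit <- suppressWarnings(
      metafor::rma(yi = d$y, vi = d$v, method = "REML",
                   control = list(threshold = 1e-12)))
    expect_equal(tau2_reml(d)$value, fit$tau2, tolerance = 1e-7)
  }
})

test_that("Paule-Mandel estimator solves H*^2 = 1 or truncates", {
  d2 <- toy_dataset()
  expect_equal(tau2_pm(d2)$value, 0.25, tolerance = 1e-10)

  trunc <- tau2_pm(meta_dataset(c(0, 0.1), c(0.25, 0.25)))
  expect_equal(trunc$value, 0)
  expect_true(trunc$truncated)
  expect_lt(hstar(meta_dataset(c(0, 0.1), c(0.25, 0.25)), 0), 1)

  d3 <- meta_dataset(c(0, 1, 2), c(0.5, 1.0, 0.25))
  est <- tau2_pm(d3)
  expect_gt(est$value, 0)
  expect_equal(hstar(d3, est$value)^2, 1, tolerance = 1e-10)
})

test_that("PM agrees with metafor on random datasets", {
  skip_if_not_installed("metafor")
  set.seed(103)
  for (i in 1:20) {
    d <- random_dataset(sample(3:12, 1), tau2 = runif(1, 0.2, 2))
    fit <- suppressWarnings(
      metafor::rma(yi = d$y, vi = d$v, method = "PM",
                   control = list(tol = 1e-12)))
    expect_equal(tau2_pm(d)$value, fit$tau2, tolerance = 1e-8)
  }
})

test_that("two-study closed form matches all three estimators", {
  d <- toy_dataset()
  expect_equal(tau2_closed_form_n2(d), 0.25, tolerance = 1e-12)
  expect_equal(tau2_closed_form_n2(meta_dataset(c(0, 0.1), c(0.25, 0.25))),
               -0.245, tolerance = 1e-12)
  expect_lt(tau2_closed_form_n2(meta_dataset(c(0.7, 0.7), c(0.2, 0.3))), 0)
  expect_error(tau2_closed_form_n2(meta_dataset(c(0, 1, 2), c(1, 1, 1))),
               class = "hkmeta_validation_error")

  set.seed(104)
  for (i in 1:200) {
    d <- random_dataset(2, tau2 = runif(1, 0, 1.5))
    expected <- max(0, tau2_closed_form_n2(d))
    expect_equal(tau2_dl(d)$value, expected, tolerance = 1e-8)
    expect_equal(tau2_reml(d)$value, expected, tolerance = 1e-8)
    expect_equal(tau2_pm(d)$value, expected, tolerance = 1e-8)
  }
})

test_that("equal-variance closed form matches all three estimators", {
  dev <- meta_dataset(c(0, 0.5, 1.0), c(0.1, 0.1, 0.1))
  cf <- equal_variance_closed_form(dev)
  expect_equal(cf$s2, 0.25, tolerance = 1e-12)
  expect_equal(cf$tau2, 0.15, tolerance = 1e-12)

  cf2 <- equal_variance_closed_form(meta_dataset(c(0, 0.1), c(0.25, 0.25)))
  expect_equal(cf2$s2, 0.005, tolerance = 1e-12)
  expect_equal(cf2$tau2, 0)

  expect_equal(equal_variance_closed_form(
    meta_dataset(c(2, 2, 2), c(0.3, 0.3, 0.3)))$tau2, 0)
  expect_error(equal_variance_closed_form(meta_dataset(c(0, 1), c(1, 2))),
               class = "hkmeta_validation_error")

  set.seed(105)
  for (i in 1:200) {
    d <- random_equal_variance_dataset(sample(2:12, 1),
                                       tau2 = runif(1, 0, 2))
    expected <- equal_variance_closed_form(d)$tau2
    expect_equal(tau2_dl(d)$value, expected, tolerance = 1e-6)
    expect_equal(tau2_reml(d)$value, expected, tolerance = 1e-6)
    expect_equal(tau2_pm(d)$value, expected, tolerance = 1e-6)
  }
})

test_that("DL truncation implies H*(0) < 1", {
  set.seed(106)
  found <- 0L
  for (i in 1:500) {
    d <- random_dataset(sample(2:8, 1), tau2 = 0)
    est <- tau2_dl(d)
    if (est$truncated) {
      found <- found + 1L
      expect_lt(hstar(d, 0), 1)
    }
  }
  expect_gt(found, 50L)  # the case must actually be exercised
})

test_that("estimators recover the true between-study variance on average", {
  set.seed(107)
  n_rep <- 300L
  truth <- 1.0
  means <- sapply(c("dl", "reml", "pm"), function(e) {
    mean(vapply(seq_len(n_rep), function(i) {
      d <- random_dataset(40, tau2 = truth)
      estimate_tau2(d, e)$value
    }, numeric(1)))
  })
  # MC-SE of each mean is roughly sqrt(2/n) * tau2 / sqrt(n_rep) ~ 0.013
  for (m in means) expect_lt(abs(m - truth), 0.06)
})
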