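# Between-study variance estimation: DerSimonian-Laird, REML, Paule-Mandel,
# and the closed-form special cases (two studies; equal within-study variances).

new_tau2_estimate <- function(value, estimator, truncated, converged = TRUE,
                              iterations = 0L, pre_truncation = NA_real_) {
  structure(list(value = value, estimator = estimator, truncated = truncated,
                 converged = converged, iterations = as.integer(iterations),
                 pre_truncation = pre_truncation),
            class = "tau2_estimate")
}

#' @export
print.tau2_estimate <- function(x, ...) {
  cat(sprintf("tau2 estimate (%s): %.6g%s%s\n", x$estimator, x$value,
              if (x$truncated) " [truncated to 0]" else "",
              if (!x$converged) " [NOT converged]" else ""))
  invisible(x)
}

as_tau2_value <- function(tau2) {
  if (inherits(tau2, "tau2_estimate")) tau2$value else as.numeric(tau2)
}

#' Generalized Q statistic
#'
#' Computes `Q(tau2) = sum(w_i * (y_i - mu_hat)^2)` with weights
#' `w_i = 1/(v_i + tau2)` and `mu_hat` the weighted mean. At `tau2 = 0` this
#' is Cochran's Q; divided by `n - 1` it is the squared generalized
#' heterogeneity statistic H*^2 (see [hstar()]). `Q` is continuous and
#' non-increasing in `tau2`, which makes the Paule-Mandel root unique.
#'
#' @param dataset a [meta_dataset()].
#' @param tau2 nonnegative between-study variance at which to evaluate.
#' @return the nonnegative statistic value.
#' @export
generalized_q <- function(dataset, tau2) {
  w <- 1 / (dataset$v + tau2)
  mu <- sum(w * dataset$y) / sum(w)
  sum(w * (dataset$y - mu)^2)
}

#' DerSimonian-Laird estimator of the between-study variance
#'
#' Moment estimator `(Q(0) - (n - 1)) / (S1 - S2/S1)` with fixed-effect
#' weights `u_i = 1/v_i`, `S1 = sum(u_i)`, `S2 = sum(u_i^2)`, truncated at
#' zero. The pre-truncation value is retained in the result.
#'
#' @param dataset a [meta_dataset()].
#' @return a `tau2_estimate` with fields `value`, `estimator`, `truncated`,
#'   `converged`, `iterations`, `pre_truncation`.
#' @export
tau2_dl <- function(dataset) {
  u <- 1 / dataset$v
  q0 <- generalized_q(dataset, 0)
  denom <- sum(u) - sum(u^2) / sum(u)
  pre <- (q0 - (dataset$n - 1)) / denom
  new_tau2_estimate(value = max(0, pre), estimator = "dl",
                    truncated = pre < 0, pre_truncation = pre)
}

#' REML estimator of the between-study variance
#'
#' Maximizes the restricted log-likelihood of the random-effects model over
#' `tau2 >= 0` by Fisher-scoring fixed-point iteration
#' `tau2 <- sum(w^2 ((y - mu)^2 - v)) / sum(w^2) + 1/sum(w)`, truncated at
#' zero each step, started from the (truncated) DerSimonian-Laird value.
#' Non-convergence is not an error: the best iterate is returned with
#' `converged = FALSE` so that callers can apply the usual exclusion rule.
#'
#' @param dataset a [meta_dataset()].
#' @param tol convergence tolerance on the change in `tau2` per iteration.
#' @param max_iter maximum number of iterations.
#' @return a `tau2_estimate`.
#' @export
tau2_reml <- function(dataset, tol = 1e-10, max_iter = 100L) {
  if (tol <= 0) hk_validation_error("tol must be positive")
  y <- dataset$y
  v <- dataset$v
  t2 <- max(0, tau2_dl(dataset)$value)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    t2_new <- sum(w^2 * ((y - mu)^2 - v)) / sum(w^2) + 1 / sum(w)
    t2_new <- max(0, t2_new)
    if (abs(t2_new - t2) < tol) {
      t2 <- t2_new
      converged <- TRUE
      break
    }
    t2 <- t2_new
  }
  new_tau2_estimate(value = t2, estimator = "reml",
                    truncated = t2 == 0, converged = converged,
                    iterations = iter, pre_truncation = NA_real_)
}

#' Paule-Mandel estimator of the between-study variance
#'
#' Defined as the value of `tau2` at which the generalized heterogeneity
#' statistic satisfies `H*^2 = 1`, i.e. the root of
#' `Q(tau2) = n - 1`. Because `Q` is non-increasing in `tau2` the root is
#' unique; it is bracketed by doubling an upper bound and solved with
#' [stats::uniroot()], then polished with Newton steps. If already
#' `Q(0) <= n - 1` there is no positive root and the estimate is truncated
#' to zero, in which case `H* < 1` by construction.
#'
#' @param dataset a [meta_dataset()].
#' @param tol absolute tolerance on the root.
#' @return a `tau2_estimate`.
#' @export
tau2_pm <- function(dataset, tol = 1e-10) {
  if (tol <= 0) hk_validation_error("tol must be positive")
  n <- dataset$n
  target <- n - 1
  f <- function(t2) generalized_q(dataset, t2) - target
  if (f(0) <= 0) {
    return(new_tau2_estimate(value = 0, estimator = "pm", truncated = TRUE,
                             pre_truncation = NaN))
  }
  upper <- max(stats::var(dataset$y), mean(dataset$v), tol)
  tries <- 0L
  while (f(upper) >= 0) {
    upper <- upper * 2
    tries <- tries + 1L
    if (tries > 200L)
      hk_stop(sprintf(
        "Paule-Mandel bracket expansion failed; achieved bracket [0, %g]",
        upper), "hkmeta_numerical_error")
  }
  root <- stats::uniroot(f, lower = 0, upper = upper, tol = tol,
                         maxiter = 1000L)
  t2 <- root$root
  # Newton polish using dQ/dtau2 = -sum(w^2 (y - mu)^2) (envelope theorem)
  for (i in 1:3) {
    w <- 1 / (dataset$v + t2)
    mu <- sum(w * dataset$y) / sum(w)
    qv <- sum(w * (dataset$y - mu)^2)
    dq <- -sum(w^2 * (dataset$y - mu)^2)
    step <- (qv - target) / dq
    t2_new <- t2 - step
    if (!is.finite(t2_new) || t2_new < 0) break
    t2 <- t2_new
  }
  new_tau2_estimate(value = t2, estimator = "pm", truncated = FALSE,
                    iterations = root$iter, pre_truncation = t2)
}

#' Estimate the between-study variance
#'
#' Dispatcher over the three supported estimators.
#'
#' @param dataset a [meta_dataset()].
#' @param estimator `"dl"`, `"reml"` or `"pm"`.
#' @param ... passed to the specific estimator ([tau2_reml()] accepts `tol`
#'   and `max_iter`; [tau2_pm()] accepts `tol`).
#' @return a `tau2_estimate`.
#' @export
estimate_tau2 <- function(dataset, estimator = c("dl", "reml", "pm"), ...) {
  estimator <- match.arg(estimator)
  switch(estimator,
         dl = tau2_dl(dataset),
         reml = tau2_reml(dataset, ...),
         pm = tau2_pm(dataset, ...))
}

#' Closed-form between-study variance for two studies
#'
#' For `n = 2` the DerSimonian-Laird, REML and Paule-Mandel estimators all
#' coincide and, before truncation, equal
#' `((y2 - y1)^2 - v1 - v2) / 2` (Rukhin's identity). The value returned is
#' the pre-truncation quantity; `max(0, .)` equals all three estimators.
#'
#' @param dataset a [meta_dataset()] with exactly two studies.
#' @return the (possibly negative) pre-truncation closed-form value.
#' @export
tau2_closed_form_n2 <- function(dataset) {
  if (dataset$n != 2)
    hk_validation_error("closed form requires exactly n = 2 studies")
  ((dataset$y[2] - dataset$y[1])^2 - dataset$v[1] - dataset$v[2]) / 2
}

#' Closed-form between-study variance for equal within-study variances
#'
#' When all studies share the same within-study variance `sigma2`, the three
#' estimators coincide and satisfy `sigma2 + tau2_hat = s2` before
#' truncation, where `s2` is the sample variance of the estimates (divisor
#' `n - 1`). The pooled estimate is then the unweighted mean.
#'
#' @param dataset a [meta_dataset()] with all `v` equal.
#' @return a list with `s2`, `ybar`, `sigma2` and the truncated estimate
#'   `tau2`.
#' @export
equal_variance_closed_form <- function(dataset) {
  if (any(dataset$v != dataset$v[1]))
    hk_validation_error("closed form requires equal within-study variances")
  s2 <- stats::var(dataset$y)
  sigma2 <- dataset$v[1]
  list(s2 = s2, ybar = mean(dataset$y), sigma2 = sigma2,
       tau2 = max(0, s2 - sigma2))
}
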