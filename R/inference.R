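# Pooled-effect estimation and the confidence-interval constructions:
# standard random-effects (normal), Hartung-Knapp modified (t), the
# constrained-H* variant, and the common-effect analysis.

new_inference_result <- function(method, mu_hat, se, df, alpha,
                                 hstar = NA_real_, tau2_used = NA_real_) {
  if (is.null(df) || is.na(df)) {
    q <- stats::qnorm(1 - alpha / 2)
    p <- 2 * stats::pnorm(-abs(mu_hat / se))
    df <- NA_integer_
  } else {
    q <- stats::qt(1 - alpha / 2, df)
    p <- 2 * stats::pt(-abs(mu_hat / se), df)
  }
  structure(list(method = method, mu_hat = mu_hat, se = se,
                 df = df, alpha = alpha,
                 ci_lower = mu_hat - q * se, ci_upper = mu_hat + q * se,
                 p_value = p, hstar = hstar, tau2_used = tau2_used),
            class = "hk_inference")
}

#' @export
print.hk_inference <- function(x, ...) {
  dist <- if (is.na(x$df)) "z" else sprintf("t(%d)", x$df)
  cat(sprintf("%s: estimate %.4f, SE %.4f [%s], %d%% CI (%.4f, %.4f), p = %.4g\n",
              x$method, x$mu_hat, x$se, dist, round(100 * (1 - x$alpha)),
              x$ci_lower, x$ci_upper, x$p_value))
  invisible(x)
}

#' Confidence interval width
#'
#' @param result an inference result (from [ci_standard_re()] and friends).
#' @return `ci_upper - ci_lower`.
#' @export
ci_width <- function(result) result$ci_upper - result$ci_lower

#' Pooled random-effects estimate and conventional standard error
#'
#' Inverse-variance weighted mean with weights `w_i = 1/(v_i + tau2)` and
#' standard error `1/sqrt(sum(w_i))`. With `tau2 = 0` these are the
#' common-effect estimate and standard error.
#'
#' @param dataset a [meta_dataset()].
#' @param tau2 between-study variance (a number or a `tau2_estimate`).
#' @return list with `mu_hat` and `se`.
#' @export
pooled_re <- function(dataset, tau2) {
  tau2 <- as_tau2_value(tau2)
  w <- 1 / (dataset$v + tau2)
  list(mu_hat = sum(w * dataset$y) / sum(w), se = 1 / sqrt(sum(w)))
}

#' Generalized heterogeneity statistic H*
#'
#' `H* = sqrt(Q(tau2) / (n - 1))` where `Q` is [generalized_q()]. At
#' `tau2 = 0` this equals the Higgins-Thompson H statistic. The modified
#' method scales the conventional standard error by H*; H* = 0 occurs only
#' for datasets whose estimates are all identical (see
#' [detect_degenerate()]).
#'
#' @inheritParams pooled_re
#' @return the nonnegative scaling factor.
#' @export
hstar <- function(dataset, tau2) {
  tau2 <- as_tau2_value(tau2)
  sqrt(generalized_q(dataset, tau2) / (dataset$n - 1))
}

#' Standard random-effects confidence interval
#'
#' Normal-theory interval `mu_hat +/- z_(1-alpha/2) / sqrt(sum(w_i))` for the
#' average effect, treating the estimated between-study variance as known.
#' With `tau2 = 0` the analysis collapses to the common-effect analysis.
#'
#' @param dataset a [meta_dataset()].
#' @param tau2_estimate a `tau2_estimate` or a nonnegative number.
#' @param alpha two-sided significance level in (0, 1); default 0.05.
#' @return an `hk_inference` with method `"RE_Z"`.
#' @export
ci_standard_re <- function(dataset, tau2_estimate, alpha = 0.05) {
  tau2 <- as_tau2_value(tau2_estimate)
  p <- pooled_re(dataset, tau2)
  new_inference_result("RE_Z", p$mu_hat, p$se, df = NULL, alpha = alpha,
                       hstar = hstar(dataset, tau2), tau2_used = tau2)
}

#' Hartung-Knapp modified confidence interval
#'
#' Uses the scaled standard error `H* / sqrt(sum(w_i))` and quantiles from a
#' t distribution with `n - 1` degrees of freedom:
#' `mu_hat +/- t_(n-1, alpha/2) * H* / sqrt(sum(w_i))`. The point estimate is
#' identical to the standard random-effects one. Degenerate datasets
#' (all estimates exactly equal, hence H* = 0 and a zero standard error) are
#' refused.
#'
#' @inheritParams ci_standard_re
#' @return an `hk_inference` with method `"MOD_T"`.
#' @export
ci_modified <- function(dataset, tau2_estimate, alpha = 0.05) {
  tau2 <- as_tau2_value(tau2_estimate)
  h <- hstar(dataset, tau2)
  if (h == 0)
    hk_stop(paste("modified inference undefined: identical estimates give",
                  "H* = 0 and a zero standard error"),
            "hkmeta_degenerate_error")
  p <- pooled_re(dataset, tau2)
  new_inference_result("MOD_T", p$mu_hat, h * p$se, df = dataset$n - 1L,
                       alpha = alpha, hstar = h, tau2_used = tau2)
}

#' Constrained Hartung-Knapp confidence interval (H* >= 1)
#'
#' As [ci_modified()] but with the scaling factor replaced by `max(H*, 1)`.
#' Because the t quantile exceeds the normal quantile, the resulting interval
#' is always at least as wide as the standard random-effects interval.
#'
#' @inheritParams ci_standard_re
#' @return an `hk_inference` with method `"MOD_CONSTRAINED_T"`.
#' @export
ci_modified_constrained <- function(dataset, tau2_estimate, alpha = 0.05) {
  tau2 <- as_tau2_value(tau2_estimate)
  h <- hstar(dataset, tau2)
  if (h == 0)
    hk_stop(paste("modified inference undefined: identical estimates give",
                  "H* = 0 and a zero standard error"),
            "hkmeta_degenerate_error")
  p <- pooled_re(dataset, tau2)
  new_inference_result("MOD_CONSTRAINED_T", p$mu_hat, max(h, 1) * p$se,
                       df = dataset$n - 1L, alpha = alpha, hstar = h,
                       tau2_used = tau2)
}

#' Common-effect confidence interval
#'
#' Fixed-effect analysis: weights `1/v_i`, standard error
#' `1/sqrt(sum(1/v_i))`, normal quantiles. The point estimate generally
#' differs from the random-effects one when `tau2 > 0`.
#'
#' @param dataset a [meta_dataset()].
#' @param alpha two-sided significance level in (0, 1).
#' @return an `hk_inference` with method `"CE_Z"`.
#' @export
ci_common_effect <- function(dataset, alpha = 0.05) {
  p <- pooled_re(dataset, 0)
  new_inference_result("CE_Z", p$mu_hat, p$se, df = NULL, alpha = alpha,
                       hstar = hstar(dataset, 0), tau2_used = 0)
}
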