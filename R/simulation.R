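# Synthetic meta-analysis generation under the random-effects model
# Y_i ~ N(mu, sigma_i^2 + tau^2), plus survey, audit and coverage harnesses.

#' Variance laws for simulated within-study variances
#'
#' `variance_law_uniform(min, max)` draws each `sigma_i^2` uniformly;
#' `variance_law_equal(sigma2)` gives every study the same variance (the
#' "equal study size" special case in which all three estimators coincide).
#'
#' @param min,max bounds of the uniform law, `0 < min <= max`.
#' @return an `hk_variance_law`.
#' @export
variance_law_uniform <- function(min = 0.1, max = 1.0) {
  if (min <= 0 || max < min)
    hk_validation_error("uniform variance law needs 0 < min <= max")
  structure(list(type = "uniform", min = min, max = max),
            class = "hk_variance_law")
}

#' @rdname variance_law_uniform
#' @param sigma2 common within-study variance, positive.
#' @export
variance_law_equal <- function(sigma2) {
  if (sigma2 <= 0) hk_validation_error("sigma2 must be positive")
  structure(list(type = "equal", sigma2 = sigma2), class = "hk_variance_law")
}

draw_variances <- function(law, n) {
  switch(law$type,
         uniform = stats::runif(n, law$min, law$max),
         equal = rep(law$sigma2, n),
         hk_validation_error("unknown variance law"))
}

mean_variance <- function(law) {
  switch(law$type,
         uniform = (law$min + law$max) / 2,
         equal = law$sigma2)
}

#' Simulation configuration
#'
#' Describes the generating random-effects model. `n` and `tau2` may be
#' vectors, in which case each simulated meta-analysis draws its study count
#' and its true between-study variance uniformly from the given values --
#' this is how the default survey mixes sizes and heterogeneity levels.
#'
#' @param mu true average effect.
#' @param tau2 true between-study variance(s), all nonnegative.
#' @param n study count(s), all at least 2.
#' @param variance_law an `hk_variance_law`; default uniform on (0.1, 1).
#' @param n_reps number of replicates for harnesses that loop.
#' @param seed master integer seed; every replicate derives its own
#'   substream from `(seed, draw_index)` so that any replicate can be
#'   replayed in isolation.
#' @param alpha two-sided significance level used by harnesses.
#' @return an `hk_sim_config`.
#' @export
simulation_config <- function(mu = 0, tau2 = 0.25, n = 5,
                              variance_law = variance_law_uniform(),
                              n_reps = 1000L, seed = 1L, alpha = 0.05) {
  if (any(tau2 < 0)) hk_validation_error("tau2 must be nonnegative")
  if (any(n < 2)) hk_validation_error("n must be at least 2")
  if (alpha <= 0 || alpha >= 1) hk_validation_error("alpha must be in (0, 1)")
  if (!inherits(variance_law, "hk_variance_law"))
    hk_validation_error("variance_law must be built with variance_law_*()")
  structure(list(mu = mu, tau2 = as.numeric(tau2), n = as.integer(n),
                 variance_law = variance_law, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), alpha = alpha),
            class = "hk_sim_config")
}

#' Default taxonomy-survey configuration
#'
#' Mixes study counts 2, 3, 5, 10 and 20 with between-study variances of 0,
#' 0.25, 1 and 4 times the mean within-study variance of the uniform(0.1, 1)
#' law (i.e. multiples of 0.55), spanning homogeneous to strongly
#' heterogeneous meta-analyses.
#'
#' @param seed master integer seed.
#' @param n_reps number of simulated meta-analyses; default 50000.
#' @return an `hk_sim_config`.
#' @export
default_survey_config <- function(seed = 1L, n_reps = 50000L) {
  law <- variance_law_uniform(0.1, 1.0)
  simulation_config(mu = 0,
                    tau2 = c(0, 0.25, 1, 4) * mean_variance(law),
                    n = c(2L, 3L, 5L, 10L, 20L),
                    variance_law = law, n_reps = n_reps, seed = seed)
}

replicate_seed <- function(seed, draw_index) {
  as.integer((as.double(seed) * 1000003 + as.double(draw_index)) %% 2147483647)
}

#' Simulate one meta-analysis dataset
#'
#' Draws `sigma_i^2` from the configured variance law, true study effects
#' `theta_i ~ N(mu, tau2)`, and observed estimates `y_i ~ N(theta_i,
#' sigma_i^2)`. Reproducible: the same `(seed, draw_index)` always yields
#' the same dataset. When `config$n` or `config$tau2` are vectors one value
#' is drawn per replicate; the realized values are attached as attributes
#' `true_n` and `true_tau2`.
#'
#' @param config an [simulation_config()].
#' @param draw_index positive integer replicate index.
#' @return a [meta_dataset()].
#' @export
simulate_dataset <- function(config, draw_index = 1L) {
  set.seed(replicate_seed(config$seed, draw_index))
  n <- if (length(config$n) > 1L) sample(config$n, 1L) else config$n
  tau2 <- if (length(config$tau2) > 1L) sample(config$tau2, 1L)
          else config$tau2
  v <- draw_variances(config$variance_law, n)
  theta <- stats::rnorm(n, config$mu, sqrt(tau2))
  y <- stats::rnorm(n, theta, sqrt(v))
  d <- new_meta_dataset(y, v)
  attr(d, "true_n") <- n
  attr(d, "true_tau2") <- tau2
  d
}

# classify one dataset with one estimator and realize all six conventions;
# shares the exact decision logic used by analyze()
classify_all <- function(dataset, estimator, alpha = 0.05) {
  record <- binary_outcomes(dataset, estimator, alpha)
  tau2 <- record$tau2
  mod <- ci_modified(dataset, tau2, alpha)
  re <- ci_standard_re(dataset, tau2, alpha)
  ce <- ci_common_effect(dataset, alpha)
  constrained <- ci_modified_constrained(dataset, tau2, alpha)
  rc <- realize_conventions(record$tau2_positive, record$hstar,
                            mod, re, ce, constrained, record$group)
  list(record = record, labels = rc$labels,
       widths = c(mod = ci_width(mod), re = ci_width(re), ce = ci_width(ce),
                  constrained = ci_width(constrained)))
}

#' Taxonomy-group frequency survey
#'
#' Simulates `config$n_reps` meta-analyses and classifies each with every
#' requested estimator, tallying taxonomy groups. Mirrors the empirical
#' exclusion rules: degenerate datasets (identical estimates) are excluded
#' for all estimators, and datasets where REML fails to converge are
#' excluded for REML only. Exclusions are counted, never silently dropped.
#'
#' @param config an [simulation_config()].
#' @param estimators subset of `c("dl", "reml", "pm")`.
#' @param keep_details if `TRUE`, retain per-replicate groups, realized
#'   convention labels and truncation flags (needed by
#'   [impossible_group_audit()] forensics and oracle checks).
#' @return an `hk_survey` with a `counts` matrix (estimator x group 1..16),
#'   exclusion tallies and, optionally, `details`.
#' @export
group_frequency_survey <- function(config, estimators = c("dl", "reml", "pm"),
                                   keep_details = FALSE) {
  estimators <- match.arg(estimators, c("dl", "reml", "pm"),
                          several.ok = TRUE)
  n_reps <- config$n_reps
  counts <- matrix(0L, nrow = length(estimators), ncol = 16L,
                   dimnames = list(estimators, as.character(1:16)))
  excl_degenerate <- 0L
  excl_reml <- 0L
  details <- NULL
  if (keep_details) {
    groups <- matrix(NA_integer_, n_reps, length(estimators),
                     dimnames = list(NULL, estimators))
    labels <- array(NA_character_, c(n_reps, length(estimators), 6L),
                    dimnames = list(NULL, estimators, CONVENTIONS))
    truncated <- matrix(NA, n_reps, length(estimators),
                        dimnames = list(NULL, estimators))
    hstars <- matrix(NA_real_, n_reps, length(estimators),
                     dimnames = list(NULL, estimators))
    true_n <- integer(n_reps)
  }
  for (i in seq_len(n_reps)) {
    d <- simulate_dataset(config, i)
    if (keep_details) true_n[i] <- attr(d, "true_n")
    if (detect_degenerate(d) == "identical_estimates") {
      excl_degenerate <- excl_degenerate + 1L
      next
    }
    for (e in estimators) {
      est <- estimate_tau2(d, e)
      if (e == "reml" && !est$converged) {
        excl_reml <- excl_reml + 1L
        next
      }
      cl <- classify_all_est(d, e, est, config$alpha)
      g <- cl$record$group
      counts[e, g] <- counts[e, g] + 1L
      if (keep_details) {
        groups[i, e] <- g
        labels[i, e, ] <- cl$labels
        truncated[i, e] <- est$truncated
        hstars[i, e] <- cl$record$hstar
      }
    }
  }
  if (keep_details)
    details <- list(groups = groups, labels = labels, truncated = truncated,
                    hstars = hstars, true_n = true_n)
  structure(list(counts = counts, estimators = estimators,
                 exclusions = list(degenerate = excl_degenerate,
                                   reml_nonconverged = excl_reml),
                 n_reps = n_reps, config = config, details = details),
            class = "hk_survey")
}

# classify with a precomputed estimate (survey hot path)
classify_all_est <- function(dataset, estimator, est, alpha) {
  record <- binary_outcomes(dataset, estimator, alpha, tau2_estimate = est)
  tau2 <- record$tau2
  mod <- ci_modified(dataset, tau2, alpha)
  re <- ci_standard_re(dataset, tau2, alpha)
  ce <- ci_common_effect(dataset, alpha)
  constrained <- ci_modified_constrained(dataset, tau2, alpha)
  rc <- realize_conventions(record$tau2_positive, record$hstar,
                            mod, re, ce, constrained, record$group)
  list(record = record, labels = rc$labels)
}

#' @export
print.hk_survey <- function(x, ...) {
  cat(sprintf("taxonomy survey: %d replicates (seed %d)\n", x$n_reps,
              x$config$seed))
  nonzero <- which(colSums(x$counts) > 0)
  print(x$counts[, nonzero, drop = FALSE])
  cat(sprintf("exclusions: %d degenerate, %d REML non-convergent\n",
              x$exclusions$degenerate, x$exclusions$reml_nonconverged))
  invisible(x)
}

#' Audit a survey for impossible taxonomy groups
#'
#' Checks that the nine logically impossible groups (2, 3, 4, 6, 10, 11, 12,
#' 14, 15) have zero counts for every estimator and that each estimator's
#' additional exclusions ([estimator_exclusions()]) also have zero counts.
#' A violation indicates a bug in the classifier or the inference code; when
#' the survey was run with `keep_details = TRUE`, the offending replicate
#' indices are reported so the dataset can be replayed via
#' [simulate_dataset()].
#'
#' @param survey an `hk_survey`.
#' @return an `hk_audit`: `clean` flag and a data frame of violations.
#' @export
impossible_group_audit <- function(survey) {
  impossible_always <- setdiff(1:16, OBSERVABLE_GROUPS)
  viol <- list()
  for (e in survey$estimators) {
    bad <- sort(unique(c(impossible_always, estimator_exclusions(e))))
    for (g in bad) {
      cnt <- survey$counts[e, as.character(g)]
      if (cnt > 0) {
        idx <- NA_integer_
        if (!is.null(survey$details))
          idx <- which(survey$details$groups[, e] == g)[1L]
        viol[[length(viol) + 1L]] <-
          data.frame(estimator = e, group = g, count = cnt,
                     first_draw_index = idx)
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol)
                else data.frame(estimator = character(0), group = integer(0),
                                count = integer(0),
                                first_draw_index = integer(0))
  structure(list(clean = nrow(violations) == 0L, violations = violations,
                 seed = survey$config$seed),
            class = "hk_audit")
}

#' @export
print.hk_audit <- function(x, ...) {
  if (x$clean) cat("impossibility audit: clean\n")
  else {
    cat("impossibility audit: VIOLATIONS (implementation bug)\n")
    print(x$violations)
  }
  invisible(x)
}

#' Confidence-interval coverage study
#'
#' Simulates meta-analyses from `config` and, for each convention, records
#' whether the presented interval covers the true `mu` and how wide it is.
#' All conventions are evaluated on the same simulated datasets, so
#' differences are paired. Degenerate datasets (and REML non-convergence,
#' if applicable) are excluded and counted.
#'
#' @param config an [simulation_config()]; `n_reps` of at least 10^4 keeps
#'   the Monte-Carlo standard error of a 95% coverage estimate below 0.005.
#' @param conventions subset of the six convention names.
#' @param estimator the between-study variance estimator to use.
#' @return an `hk_coverage`: data frame with per-convention `coverage`,
#'   `mean_width`, `mc_se` and the replicate count used.
#' @export
coverage_study <- function(config, conventions = c("never", "always",
                                                   "constrain"),
                           estimator = c("dl", "reml", "pm")) {
  conventions <- match.arg(conventions, CONVENTIONS, several.ok = TRUE)
  estimator <- match.arg(estimator)
  n_reps <- config$n_reps
  covered <- matrix(0L, n_reps, length(conventions),
                    dimnames = list(NULL, conventions))
  widths <- matrix(NA_real_, n_reps, length(conventions),
                   dimnames = list(NULL, conventions))
  used <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    d <- simulate_dataset(config, i)
    if (detect_degenerate(d) == "identical_estimates") next
    est <- estimate_tau2(d, estimator)
    if (estimator == "reml" && !est$converged) next
    cl <- classify_all_est2(d, est, config$alpha)
    used[i] <- TRUE
    for (cv in conventions) {
      res <- cl$presented[[cv]]
      covered[i, cv] <- (res$ci_lower <= config$mu &&
                         config$mu <= res$ci_upper)
      widths[i, cv] <- ci_width(res)
    }
  }
  n_used <- sum(used)
  cov <- colSums(covered[used, , drop = FALSE]) / n_used
  out <- data.frame(convention = conventions,
                    coverage = as.numeric(cov),
                    mean_width = as.numeric(colMeans(widths[used, ,
                                                            drop = FALSE])),
                    mc_se = sqrt(cov * (1 - cov) / n_used),
                    n_used = n_used, row.names = NULL)
  structure(list(table = out, alpha = config$alpha,
                 n_excluded = n_reps - n_used, config = config,
                 estimator = estimator),
            class = "hk_coverage")
}

# presented results for all conventions, given a precomputed estimate
classify_all_est2 <- function(dataset, est, alpha) {
  tau2 <- est$value
  h <- hstar(dataset, tau2)
  mod <- ci_modified(dataset, tau2, alpha)
  re <- ci_standard_re(dataset, tau2, alpha)
  ce <- ci_common_effect(dataset, alpha)
  constrained <- ci_modified_constrained(dataset, tau2, alpha)
  rc <- realize_conventions(tau2 > 0, h, mod, re, ce, constrained)
  rc
}

#' @export
print.hk_coverage <- function(x, ...) {
  cat(sprintf("coverage study at nominal %d%% (%s estimator, %d replicates used, %d excluded)\n",
              round(100 * (1 - x$alpha)), x$estimator, x$table$n_used[1],
              x$n_excluded))
  print(x$table, digits = 4)
  invisible(x)
}
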