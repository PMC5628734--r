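# The 16-candidate / 7-observable taxonomy of meta-analysis datasets, defined
# by four binary outcomes: (1) tau2_hat > 0, (2) H* > 1, (3) the modified CI
# is wider than the standard random-effects CI, (4) the modified CI is wider
# than the common-effect CI.

#' Map the four binary outcomes to a taxonomy group number
#'
#' Groups 1-8 have `tau2 > 0`, 9-16 have `tau2 = 0`; within each block of 8,
#' groups 1-4 (resp. 9-12) have `H* > 1`; groups 1-2, 5-6, 9-10, 13-14 have
#' a modified CI wider than the standard one; odd groups have a modified CI
#' wider than the common-effect one. The map is a bijection between the 16
#' outcome combinations and 1..16.
#'
#' @param tau2_positive,hstar_gt_1,mod_wider_than_re,mod_wider_than_ce
#'   logicals.
#' @return integer group in 1..16.
#' @export
group_from_outcomes <- function(tau2_positive, hstar_gt_1,
                                mod_wider_than_re, mod_wider_than_ce) {
  (if (tau2_positive) 0L else 8L) +
    (if (hstar_gt_1) 0L else 4L) +
    (if (mod_wider_than_re) 0L else 2L) +
    (if (mod_wider_than_ce) 1L else 2L)
}

#' Recover the four binary outcomes of a taxonomy group
#'
#' Inverse of [group_from_outcomes()].
#'
#' @param group integer in 1..16.
#' @return named logical vector with elements `tau2_positive`, `hstar_gt_1`,
#'   `mod_wider_than_re`, `mod_wider_than_ce`.
#' @export
outcomes_for_group <- function(group) {
  group <- as.integer(group)
  if (group < 1L || group > 16L)
    hk_validation_error("group must be in 1..16")
  g0 <- group - 1L
  c(tau2_positive = g0 %/% 8L == 0L,
    hstar_gt_1 = (g0 %% 8L) %/% 4L == 0L,
    mod_wider_than_re = (g0 %% 4L) %/% 2L == 0L,
    mod_wider_than_ce = g0 %% 2L == 0L)
}

new_taxonomy_record <- function(tau2_positive, hstar_gt_1, mod_wider_than_re,
                                mod_wider_than_ce, group, estimator, alpha,
                                hstar, tau2) {
  structure(list(tau2_positive = tau2_positive, hstar_gt_1 = hstar_gt_1,
                 mod_wider_than_re = mod_wider_than_re,
                 mod_wider_than_ce = mod_wider_than_ce,
                 group = group, observable = group %in% OBSERVABLE_GROUPS,
                 estimator = estimator, alpha = alpha, hstar = hstar,
                 tau2 = tau2),
            class = "taxonomy_record")
}

#' @export
print.taxonomy_record <- function(x, ...) {
  yn <- function(b) if (b) "yes" else "no"
  cat(sprintf(paste0("taxonomy group %d (%s, alpha = %g)%s\n",
                     "  tau2 > 0: %s | H* > 1: %s | Mod > RE: %s | Mod > CE: %s\n",
                     "  tau2 = %.6g, H* = %.4f\n"),
              x$group, x$estimator, x$alpha,
              if (x$observable) "" else " [IMPOSSIBLE - implementation bug]",
              yn(x$tau2_positive), yn(x$hstar_gt_1),
              yn(x$mod_wider_than_re), yn(x$mod_wider_than_ce)))
  invisible(x)
}

#' Classify a dataset into the taxonomy
#'
#' Computes the chosen estimator's between-study variance, the scaling factor
#' H* at that value, and the widths of the modified, standard random-effects
#' and common-effect confidence intervals, then assigns the taxonomy group.
#' Width comparisons are strict; the `H* > 1` outcome treats values within
#' `1e-8` of 1 as not greater than 1 (the Paule-Mandel estimator produces
#' H* = 1 by construction only up to root-finding accuracy). When the
#' Paule-Mandel estimate is positive the dataset is labelled group 1, since
#' the distinction between groups 1 and 5 is then meaningless.
#'
#' @param dataset a [meta_dataset()]; must not be degenerate.
#' @param estimator `"dl"`, `"reml"` or `"pm"`.
#' @param alpha two-sided significance level; default 0.05.
#' @param tau2_estimate optional precomputed `tau2_estimate` matching
#'   `estimator` (saves recomputation in surveys).
#' @return a `taxonomy_record`.
#' @export
binary_outcomes <- function(dataset, estimator = c("dl", "reml", "pm"),
                            alpha = 0.05, tau2_estimate = NULL) {
  estimator <- match.arg(estimator)
  if (detect_degenerate(dataset) == "identical_estimates")
    hk_stop("cannot classify a degenerate dataset (identical estimates, H* = 0)",
            "hkmeta_degenerate_error")
  est <- if (is.null(tau2_estimate)) estimate_tau2(dataset, estimator)
         else tau2_estimate
  if (estimator == "reml" && !est$converged)
    hk_stop("REML estimator failed to converge; dataset excluded from classification",
            "hkmeta_convergence_error")
  tau2 <- est$value
  h <- hstar(dataset, tau2)
  mod <- ci_modified(dataset, tau2, alpha)
  re <- ci_standard_re(dataset, tau2, alpha)
  ce <- ci_common_effect(dataset, alpha)
  o1 <- tau2 > 0
  o2 <- h > 1 + HSTAR_ONE_TOL
  o3 <- ci_width(mod) > ci_width(re)
  o4 <- ci_width(mod) > ci_width(ce)
  group <- group_from_outcomes(o1, o2, o3, o4)
  if (estimator == "pm" && o1) group <- 1L
  new_taxonomy_record(o1, o2, o3, o4, group, estimator, alpha, h, tau2)
}

#' Is a taxonomy group observable?
#'
#' Nine of the 16 candidate groups cannot occur: 2, 6, 10, 14 would need a
#' modified CI wider than the standard one yet not wider than the
#' common-effect one; 3, 4, 11, 12 would need `H* > 1` with a modified CI not
#' wider than the standard one; 15 would need, at `tau2 = 0`, a modified CI
#' not wider than the standard one yet wider than the common-effect one.
#' An impossible group occurring in a survey indicates an implementation bug.
#'
#' @param record a `taxonomy_record` or an integer group number.
#' @return `TRUE` iff the group is one of 1, 5, 7, 8, 9, 13, 16.
#' @export
assert_observable <- function(record) {
  group <- if (inherits(record, "taxonomy_record")) record$group
           else as.integer(record)
  group %in% OBSERVABLE_GROUPS
}

#' Groups additionally impossible for a given estimator
#'
#' DerSimonian-Laird cannot produce group 9 (it would need `tau2 = 0` with
#' `H* > 1`, impossible under truncation). Paule-Mandel merges group 5 into
#' group 1 and cannot produce groups 7, 8 (positive roots force H* = 1, so
#' the modified CI is the widest) or 9 (truncation implies H* < 1). REML
#' admits all seven observable groups.
#'
#' @param estimator `"dl"`, `"reml"` or `"pm"`.
#' @return integer vector of excluded group numbers (possibly empty).
#' @export
estimator_exclusions <- function(estimator = c("dl", "reml", "pm")) {
  estimator <- match.arg(estimator)
  switch(estimator,
         dl = 9L,
         reml = integer(0),
         pm = c(5L, 7L, 8L, 9L))
}

#' Reduce a taxonomy record to the 3-group taxonomy
#'
#' For two-study datasets, equal within-study variance datasets, and the
#' Paule-Mandel estimator generally, the taxonomy collapses to three groups:
#' "1 or 5" (positive between-study variance, H* = 1), 13 and 16. Any other
#' group arising under one of these contexts signals an implementation
#' fault.
#'
#' @param record a `taxonomy_record`.
#' @param context `"n2"`, `"equal_variance"` or `"pm"`.
#' @return one of `"GROUP_1_OR_5"`, `"GROUP_13"`, `"GROUP_16"`.
#' @export
reduced_group <- function(record, context = c("n2", "equal_variance", "pm")) {
  context <- match.arg(context)
  g <- record$group
  if (g %in% c(1L, 5L)) return("GROUP_1_OR_5")
  if (g == 13L) return("GROUP_13")
  if (g == 16L) return("GROUP_16")
  hk_stop(sprintf("group %d cannot occur in the %s reduced taxonomy", g,
                  context), "hkmeta_taxonomy_error")
}
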