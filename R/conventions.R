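# The six conventions for choosing which analysis to present: never / always
# use the modified method, constrain H* >= 1, and three hybrids. The realized
# label (Mod/RE/CE with t or Z quantiles) is determined by the data, and the
# 7 x 6 grid of expected labels serves as the end-to-end oracle.

# expected presentation for each (observable group, convention); rows follow
# the observable groups 1, 5, 7, 8, 9, 13, 16
TABLE1_LABELS <- matrix(
  c("RE(Z)", "Mod(t)", "Mod(t)", "Mod(t)", "Mod(t)", "Mod(t)",
    "RE(Z)", "Mod(t)", "RE(t)",  "Mod(t)", "Mod(t)", "Mod(t)",
    "RE(Z)", "Mod(t)", "RE(t)",  "Mod(t)", "RE(Z)",  "Mod(t)",
    "RE(Z)", "Mod(t)", "RE(t)",  "Mod(t)", "RE(Z)",  "CE(Z)",
    "CE(Z)", "Mod(t)", "Mod(t)", "CE(Z)",  "Mod(t)", "Mod(t)",
    "CE(Z)", "Mod(t)", "CE(t)",  "CE(Z)",  "Mod(t)", "Mod(t)",
    "CE(Z)", "Mod(t)", "CE(t)",  "CE(Z)",  "CE(Z)",  "CE(Z)"),
  nrow = 7, byrow = TRUE,
  dimnames = list(as.character(OBSERVABLE_GROUPS), CONVENTIONS))

#' Expected analysis label for a taxonomy group under a convention
#'
#' Hard-coded dispatch grid over the seven observable groups and six
#' conventions. "Mod", "RE" and "CE" name the standard error used (modified,
#' conventional random-effects, common-effect); "(t)" and "(Z)" name the
#' reference distribution. Used as the oracle against the label [analyze()]
#' realizes from the data.
#'
#' @param group an observable group number (1, 5, 7, 8, 9, 13 or 16).
#' @param convention one of `"never"`, `"always"`, `"constrain"`,
#'   `"hybrid1"`, `"hybrid2"`, `"hybrid3"`.
#' @return the label string, e.g. `"Mod(t)"`.
#' @export
expected_label <- function(group, convention) {
  convention <- match.arg(convention, CONVENTIONS)
  if (!group %in% OBSERVABLE_GROUPS)
    hk_validation_error(sprintf("group %d is not observable", group))
  TABLE1_LABELS[as.character(group), convention]
}

# Realize all six conventions from one set of inference results.
# Returns list(labels = named character, presented = named list of results).
# `group` disambiguates the constrain label when H* = 1 (within tolerance):
# the modified and conventional standard errors then coincide, and the
# dispatch grid names the analysis Mod(t) in group 1 (where the Paule-Mandel
# merge places positive estimates) but RE(t) in group 5.
realize_conventions <- function(tau2_positive, h, mod, re, ce, constrained,
                                group = NA_integer_) {
  w_mod <- ci_width(mod)
  w_re <- ci_width(re)
  w_ce <- ci_width(ce)
  re_label <- if (tau2_positive) "RE(Z)" else "CE(Z)"
  labels <- character(6)
  presented <- vector("list", 6)
  names(labels) <- names(presented) <- CONVENTIONS

  labels["never"] <- re_label
  presented[["never"]] <- re

  labels["always"] <- "Mod(t)"
  presented[["always"]] <- mod

  labels["constrain"] <-
    if (h > 1 + HSTAR_ONE_TOL ||
        (abs(h - 1) <= HSTAR_ONE_TOL && isTRUE(group == 1L))) "Mod(t)"
    else if (tau2_positive) "RE(t)" else "CE(t)"
  presented[["constrain"]] <- constrained

  if (tau2_positive) {
    labels["hybrid1"] <- "Mod(t)"
    presented[["hybrid1"]] <- mod
  } else {
    labels["hybrid1"] <- "CE(Z)"
    presented[["hybrid1"]] <- ce
  }

  # "more conservative" = wider interval; exact ties present the modified
  # analysis (they guard against Mod being too short, which a tie is not)
  if (w_mod >= w_re) {
    labels["hybrid2"] <- "Mod(t)"
    presented[["hybrid2"]] <- mod
  } else {
    labels["hybrid2"] <- re_label
    presented[["hybrid2"]] <- re
  }

  if (w_mod >= w_ce) {
    labels["hybrid3"] <- "Mod(t)"
    presented[["hybrid3"]] <- mod
  } else {
    labels["hybrid3"] <- "CE(Z)"
    presented[["hybrid3"]] <- ce
  }

  list(labels = labels, presented = presented)
}

#' Analyze a dataset under a presentation convention
#'
#' Runs the full pipeline: estimates the between-study variance, computes the
#' modified, standard random-effects, constrained-modified and common-effect
#' confidence intervals, classifies the dataset into its taxonomy group, and
#' presents the analysis selected by the convention:
#'
#' * `never` - the standard random-effects interval (collapsing to the
#'   common-effect analysis when the variance estimate is zero);
#' * `always` - the modified interval;
#' * `constrain` - the modified interval with `H*` constrained to be at
#'   least 1;
#' * `hybrid1` - the modified interval iff the variance estimate is
#'   positive, else the common-effect interval;
#' * `hybrid2` - the wider of the modified and standard random-effects
#'   intervals;
#' * `hybrid3` - the wider of the modified and common-effect intervals
#'   ("more conservative" means wider interval, not larger p-value).
#'
#' @param dataset a [meta_dataset()].
#' @param convention one of the six convention names (see above).
#' @param estimator `"dl"`, `"reml"` or `"pm"`.
#' @param alpha two-sided significance level; default 0.05.
#' @param tau2_estimate optional precomputed `tau2_estimate`.
#' @return an `hk_convention_result`: the presented inference, its label, the
#'   taxonomy record, and all computed alternatives for sensitivity analysis.
#' @export
analyze <- function(dataset, convention = c("hybrid2", "never", "always",
                                            "constrain", "hybrid1", "hybrid3"),
                    estimator = c("dl", "reml", "pm"), alpha = 0.05,
                    tau2_estimate = NULL) {
  convention <- match.arg(convention)
  estimator <- match.arg(estimator)
  record <- binary_outcomes(dataset, estimator, alpha, tau2_estimate)
  tau2 <- record$tau2
  mod <- ci_modified(dataset, tau2, alpha)
  re <- ci_standard_re(dataset, tau2, alpha)
  ce <- ci_common_effect(dataset, alpha)
  constrained <- ci_modified_constrained(dataset, tau2, alpha)
  rc <- realize_conventions(record$tau2_positive, record$hstar,
                            mod, re, ce, constrained, record$group)
  structure(list(convention = convention,
                 presented = rc$presented[[convention]],
                 label = unname(rc$labels[convention]),
                 group = record$group,
                 record = record,
                 alternatives = list(mod = mod, re = re, ce = ce,
                                     mod_constrained = constrained),
                 all_labels = rc$labels),
            class = "hk_convention_result")
}

#' @export
print.hk_convention_result <- function(x, ...) {
  cat(sprintf("Convention '%s' on a group-%d dataset (%s estimator)\n",
              x$convention, x$group, x$record$estimator))
  cat(sprintf("Presented analysis [%s]:\n  ", x$label))
  print(x$presented)
  cat("Sensitivity analyses:\n")
  for (nm in names(x$alternatives)) {
    cat("  ")
    print(x$alternatives[[nm]])
  }
  invisible(x)
}
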