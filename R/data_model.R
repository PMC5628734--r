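# Study-level data structures, readers and validation.

hk_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "hkmeta_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

hk_validation_error <- function(msg) hk_stop(msg, "hkmeta_validation_error")

#' Construct a meta-analysis dataset
#'
#' A `meta_dataset` holds the study-level inputs of a random-effects
#' meta-analysis: per-study effect estimates `y` (on any scale, e.g. log odds
#' ratios) and their within-study variances `v`, which are treated as fixed
#' and known in all subsequent analysis.
#'
#' @param y numeric vector of effect estimates, all finite.
#' @param v numeric vector of within-study variances, strictly positive and
#'   finite, same length as `y`.
#' @param labels optional character vector of study identifiers; defaults to
#'   `"study_1"`, `"study_2"`, ...
#' @return an object of class `meta_dataset` with elements `labels`, `y`,
#'   `v` and the study count `n`.
#' @examples
#' d <- meta_dataset(y = c(0, 1), v = c(0.25, 0.25))
#' d$n
#' @export
meta_dataset <- function(y, v, labels = NULL) {
  y <- as.numeric(y)
  v <- as.numeric(v)
  if (is.null(labels)) labels <- paste0("study_", seq_along(y))
  labels <- as.character(labels)
  d <- new_meta_dataset(y, v, labels)
  validate_meta_dataset(d)
  d
}

# internal fast-path constructor: no validation (hot loops in simulation)
new_meta_dataset <- function(y, v, labels = paste0("study_", seq_along(y))) {
  structure(list(labels = labels, y = y, v = v, n = length(y)),
            class = "meta_dataset")
}

validate_meta_dataset <- function(d) {
  if (length(d$y) != length(d$v) || length(d$y) != length(d$labels))
    hk_validation_error("y, v and labels must have equal length")
  if (d$n < 2)
    hk_validation_error("n < 2: a meta-analysis requires at least 2 studies")
  if (anyNA(d$y) || any(!is.finite(d$y)))
    hk_validation_error("all effect estimates y must be finite")
  if (anyNA(d$v) || any(!is.finite(d$v)) || any(d$v <= 0))
    hk_validation_error("all within-study variances v must be positive and finite")
  invisible(d)
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf("meta_dataset: %d studies\n", x$n))
  print(data.frame(study = x$labels, yi = x$y, vi = x$v,
                   row.names = NULL), ...)
  invisible(x)
}

#' Read per-study effect estimates from a CSV file
#'
#' Expects a comma-separated file with a header and columns `study`, `yi` and
#' either `vi` (within-study variance) or `sei` (standard error). In standard
#' error mode the variance is computed as `sei^2`. Row order is preserved.
#'
#' @param path path to the CSV file.
#' @param variance_column_mode `"variance"` (column `vi`), `"standard_error"`
#'   (column `sei`), or `"auto"` (default) to infer from the header.
#' @return a [meta_dataset()].
#' @export
read_effects <- function(path,
                         variance_column_mode = c("auto", "variance",
                                                  "standard_error")) {
  variance_column_mode <- match.arg(variance_column_mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"study" %in% names(df) || !"yi" %in% names(df))
    hk_validation_error("missing columns: effects CSV needs 'study' and 'yi'")
  if (variance_column_mode == "auto") {
    variance_column_mode <-
      if ("vi" %in% names(df)) "variance"
      else if ("sei" %in% names(df)) "standard_error"
      else hk_validation_error("missing columns: need a 'vi' or 'sei' column")
  }
  vcol <- if (variance_column_mode == "variance") "vi" else "sei"
  if (!vcol %in% names(df))
    hk_validation_error(sprintf("missing columns: expected column '%s'", vcol))
  yi <- suppressWarnings(as.numeric(df$yi))
  vv <- suppressWarnings(as.numeric(df[[vcol]]))
  if (anyNA(yi) || anyNA(vv))
    hk_validation_error("non-numeric cells in 'yi' or variance/SE column")
  if (nrow(df) < 2)
    hk_validation_error("n < 2: a meta-analysis requires at least 2 studies")
  v <- if (variance_column_mode == "standard_error") vv^2 else vv
  if (any(v <= 0))
    hk_validation_error("non-positive variance in input")
  meta_dataset(y = yi, v = v, labels = df$study)
}

#' Write a meta-analysis dataset to CSV
#'
#' Writes columns `study,yi,vi` with 17 significant digits so that
#' re-reading with [read_effects()] reproduces `y` and `v` bit-exactly.
#'
#' @param dataset a [meta_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(dataset, path) {
  validate_meta_dataset(dataset)
  lines <- c("study,yi,vi",
             sprintf("%s,%.17g,%.17g", dataset$labels, dataset$y, dataset$v))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-study 2x2 count tables from a CSV file
#'
#' Expects columns `study`, `events_trt`, `total_trt`, `events_ctl`,
#' `total_ctl` (nonnegative integer counts, events not exceeding totals,
#' totals at least 1).
#'
#' @param path path to the CSV file.
#' @return a data frame of validated count tables suitable for
#'   [counts_to_log_or()].
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("study", "events_trt", "total_trt", "events_ctl", "total_ctl")
  if (!all(needed %in% names(df)))
    hk_validation_error(paste("missing columns: counts CSV needs",
                              paste(needed, collapse = ", ")))
  num <- df[needed[-1]]
  num[] <- lapply(num, function(x) suppressWarnings(as.numeric(x)))
  if (anyNA(num))
    hk_validation_error("non-numeric cells in count columns")
  df[needed[-1]] <- num
  validate_count_tables(df)
  df
}

validate_count_tables <- function(df) {
  with(df, {
    if (any(c(events_trt, total_trt, events_ctl, total_ctl) < 0))
      hk_validation_error("counts must be nonnegative")
    if (any(total_trt < 1) || any(total_ctl < 1))
      hk_validation_error("arm totals must be at least 1")
    if (any(events_trt > total_trt) || any(events_ctl > total_ctl))
      hk_validation_error("events exceed arm total")
  })
  invisible(df)
}

#' Convert 2x2 count tables to log odds ratios
#'
#' Each table contributes `yi = log((a*d)/(b*c))` with `a` = treatment events,
#' `b` = treatment non-events, `c` = control events, `d` = control non-events,
#' and within-study variance `vi = 1/a + 1/b + 1/c + 1/d`. The continuity
#' correction is added to all four cells of a table if and only if any cell of
#' that table is zero; zero-free tables are left untouched.
#'
#' @param tables a data frame as returned by [read_counts()] (columns
#'   `events_trt`, `total_trt`, `events_ctl`, `total_ctl`, optionally `study`).
#' @param correction positive continuity correction, default 0.5.
#' @return a [meta_dataset()] of log odds ratios.
#' @export
counts_to_log_or <- function(tables, correction = 0.5) {
  if (correction <= 0) hk_validation_error("correction must be positive")
  validate_count_tables(tables)
  a <- tables$events_trt
  b <- tables$total_trt - tables$events_trt
  cc <- tables$events_ctl
  d <- tables$total_ctl - tables$events_ctl
  zero <- (a == 0) | (b == 0) | (cc == 0) | (d == 0)
  a <- a + correction * zero
  b <- b + correction * zero
  cc <- cc + correction * zero
  d <- d + correction * zero
  y <- log(a * d / (b * cc))
  v <- 1 / a + 1 / b + 1 / cc + 1 / d
  labels <- if ("study" %in% names(tables)) as.character(tables$study)
            else paste0("study_", seq_along(y))
  meta_dataset(y = y, v = v, labels = labels)
}

#' Detect degenerate datasets with identical effect estimates
#'
#' A dataset in which every study reports exactly the same estimate has
#' H* = 0, so the modified method's standard error is zero and modified
#' inference is undefined. Detection uses exact floating-point equality:
#' near-ties pass through (they yield tiny but nonzero H*).
#'
#' @param dataset a [meta_dataset()].
#' @return `"identical_estimates"` if all `y` are exactly equal, else `"ok"`.
#' @export
detect_degenerate <- function(dataset) {
  if (all(dataset$y == dataset$y[1L])) "identical_estimates" else "ok"
}
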