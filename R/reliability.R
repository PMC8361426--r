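# Rater reliability of the compression-volume measurement via
# intraclass correlation, computed from two-way / one-way ANOVA mean
# squares.

#' Intraclass correlation result
#'
#' @param icc Estimate (not truncated at 0; negative estimates are
#'   reported as computed, with `negative = TRUE`).
#' @param model_label Which ICC model was used.
#' @param variance_components Named numeric: `between_subject`,
#'   `between_rater` (NA for the one-way model), `residual`.
#' @param n_subjects,n_ratings Design size.
#' @return An `icc_result` object.
#' @keywords internal
icc_result <- function(icc, model_label, variance_components, n_subjects,
                       n_ratings) {
  structure(list(icc = icc, model_label = model_label,
                 variance_components = variance_components,
                 n_subjects = n_subjects, n_ratings = n_ratings,
                 negative = icc < 0),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f (%s), %d subjects, %d ratings\n",
              x$icc, x$model_label, x$n_subjects, x$n_ratings))
  vc <- x$variance_components
  cat(sprintf("  variance components: subject %.4g, rater %.4g, residual %.4g\n",
              vc["between_subject"], vc["between_rater"], vc["residual"]))
  if (x$negative) cat("  note: negative estimate reported as computed\n")
  invisible(x)
}

check_rater_table <- function(table) {
  need <- c("subject_id", "rater_id", "repeat_index", "value_mm3")
  if (!all(need %in% names(table))) {
    stopf("rater table must have columns: %s", paste(need, collapse = ", "))
  }
  cells <- table(interaction(table$subject_id, table$rater_id, table$repeat_index,
                             drop = FALSE))
  invisible(table)
}

# Balanced-design check: every subject x rater x repeat cell present once.
assert_balanced <- function(tab) {
  full <- expand.grid(subject_id = unique(tab$subject_id),
                      rater_id = unique(tab$rater_id),
                      repeat_index = unique(tab$repeat_index),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject_id, d$rater_id, d$repeat_index, sep = "\r")
  have <- key(tab)
  if (anyDuplicated(have)) stopf("rater table has duplicated cells")
  missing <- setdiff(key(full), have)
  if (length(missing) > 0) {
    stopf("unbalanced rater table; missing cells: %s",
          paste(gsub("\r", "/", utils::head(missing, 5)), collapse = ", "))
  }
  invisible(tab)
}

#' Inter-rater reliability: two-way random-effects ICC(2,1)
#'
#' Absolute-agreement single-measurement ICC from the two-way mean
#' squares: `(MS_subject - MS_error) / (MS_subject + (k-1) MS_error +
#' k (MS_rater - MS_error) / n)` with `n` subjects and `k` raters.
#' Repeats are averaged within rater first when
#' `summarize_repeats = "mean"` (the default, matching a design of
#' several repeats per rater).
#'
#' @param table Data frame with `subject_id`, `rater_id`, `repeat_index`,
#'   `value_mm3`; the design must be balanced.
#' @param summarize_repeats `"mean"` (average repeats per subject x
#'   rater) or `"all"` (treat each rater x repeat as a rating).
#' @return An `icc_result` with
#'   `model_label = "two-way-random-absolute-single"`.
#' @export
icc_inter <- function(table, summarize_repeats = c("mean", "all")) {
  summarize_repeats <- match.arg(summarize_repeats)
  check_rater_table(table)
  assert_balanced(table)
  n_raters <- length(unique(table$rater_id))
  n_subj <- length(unique(table$subject_id))
  if (n_raters < 2) stopf("inter-rater ICC needs >= 2 raters")
  if (n_subj < 2) stopf("inter-rater ICC needs >= 2 subjects")

  if (summarize_repeats == "mean") {
    agg <- stats::aggregate(value_mm3 ~ subject_id + rater_id, data = table, FUN = mean)
    rating <- agg$rater_id
  } else {
    agg <- table
    rating <- interaction(agg$rater_id, agg$repeat_index, drop = TRUE)
  }
  y <- agg$value_mm3
  subj <- factor(agg$subject_id)
  rater <- factor(rating)
  n <- nlevels(subj); k <- nlevels(rater)

  grand <- mean(y)
  ms <- tapply(y, subj, mean)     # subject means
  mr <- tapply(y, rater, mean)    # rater means
  ss_subj <- k * sum((ms - grand)^2)
  ss_rater <- n * sum((mr - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_rater
  msb <- ss_subj / (n - 1)
  msr <- ss_rater / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  if (ss_tot == 0) stopf("zero total variance: ICC undefined")
  denom <- msb + (k - 1) * mse + k * (msr - mse) / n
  icc <- (msb - mse) / denom
  vc <- c(between_subject = max((msb - mse) / k, 0),
          between_rater = max((msr - mse) / n, 0),
          residual = mse)
  icc_result(icc, "two-way-random-absolute-single", vc, n, n * k)
}

#' Intra-rater reliability: one-way random-effects ICC(1,1)
#'
#' Single-measurement one-way ICC over one rater's repeated
#' measurements: `(MS_between - MS_within) / (MS_between +
#' (k-1) MS_within)` with `k` repeats per subject.
#'
#' @param table Data frame as in [icc_inter()].
#' @param rater_id Which rater's repeats to analyse.
#' @return An `icc_result` with `model_label = "one-way-random-single"`.
#' @export
icc_intra <- function(table, rater_id) {
  check_rater_table(table)
  tab <- table[table$rater_id == rater_id, , drop = FALSE]
  if (nrow(tab) == 0) stopf("no rows for rater '%s'", rater_id)
  assert_balanced(tab)
  k <- length(unique(tab$repeat_index))
  if (k < 2) stopf("intra-rater ICC needs >= 2 repeats per subject")
  subj <- factor(tab$subject_id)
  n <- nlevels(subj)
  if (n < 2) stopf("intra-rater ICC needs >= 2 subjects")
  y <- tab$value_mm3
  grand <- mean(y)
  ms <- tapply(y, subj, mean)
  ss_b <- k * sum((ms - grand)^2)
  ss_w <- sum((y - ms[subj])^2)
  if (ss_b + ss_w == 0) stopf("zero total variance: ICC undefined")
  msb <- ss_b / (n - 1)
  msw <- ss_w / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  vc <- c(between_subject = max((msb - msw) / k, 0),
          between_rater = NA_real_, residual = msw)
  icc_result(icc, "one-way-random-single", vc, n, n * k)
}
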