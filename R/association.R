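# Cohort-level statistics: mJOA validation, summary statistics and the
# Pearson correlation battery between compression severity, activation
# metrics and clinical scores.

# mJOA subscale maxima (upper motor / lower motor / upper sensory /
# bladder) on the 18-point disability scale.
mjoa_maxima <- c(mjoa_upper_motor = 5, mjoa_lower_motor = 7,
                 mjoa_upper_sensory = 3, mjoa_bladder = 3)

#' Load the transcribed patient cohort table
#'
#' The demographic and clinical characteristics of the 23-patient cohort
#' (case, age, sex, site of impairment, symptom duration, and the four
#' mJOA subscores with their total), shipped as a plain-text CSV fixture.
#'
#' @return Data frame with one row per patient.
#' @export
load_cohort_table <- function() {
  path <- system.file("extdata", "dcm_cohort.csv", package = "cordmotor",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Validate mJOA consistency of a cohort table
#'
#' Flags any record whose mJOA total does not equal the sum of the four
#' subscores, or whose subscore exceeds its scale maximum (upper motor 5,
#' lower motor 7, upper sensory 3, bladder 3; total max 18).
#'
#' @param records Cohort data frame with the four `mjoa_*` subscore
#'   columns and `mjoa_total`.
#' @return List: `n_records`, `n_valid`, and `violations` (data frame
#'   with `case_id` and `problem`).
#' @export
validate_cohort <- function(records) {
  probs <- list()
  for (col in names(mjoa_maxima)) {
    bad <- which(records[[col]] < 0 | records[[col]] > mjoa_maxima[[col]])
    for (i in bad) {
      probs[[length(probs) + 1]] <- data.frame(
        case_id = records$case_id[i],
        problem = sprintf("%s = %g exceeds [0, %d]", col, records[[col]][i],
                          mjoa_maxima[[col]]))
    }
  }
  sums <- rowSums(records[, names(mjoa_maxima)])
  bad <- which(records$mjoa_total != sums)
  for (i in bad) {
    probs[[length(probs) + 1]] <- data.frame(
      case_id = records$case_id[i],
      problem = sprintf("mjoa_total = %g but subscores sum to %g",
                        records$mjoa_total[i], sums[i]))
  }
  violations <- if (length(probs) > 0) do.call(rbind, probs) else
    data.frame(case_id = integer(), problem = character())
  list(n_records = nrow(records),
       n_valid = nrow(records) - length(unique(violations$case_id)),
       violations = violations)
}

#' Per-variable summary statistics of a cohort
#'
#' Sample mean, sample SD (n - 1 denominator) and range per numeric
#' variable, with a `digits` column controlling display rounding.
#'
#' @param records Cohort data frame.
#' @param variables Character vector of numeric columns to summarize.
#' @param digits Named integer vector of display digits per variable
#'   (default 1).
#' @return Data frame: `variable`, `mean`, `sd`, `min`, `max`, and the
#'   display-rounded `mean_display`, `sd_display`.
#' @export
cohort_summary <- function(records, variables = c("age", "mjoa_total"),
                           digits = NULL) {
  rows <- lapply(variables, function(v) {
    x <- records[[v]]
    if (is.null(x)) stopf("unknown cohort variable '%s'", v)
    if (length(x) < 2) stopf("summary needs at least 2 records")
    dg <- if (!is.null(digits) && v %in% names(digits)) digits[[v]] else 1L
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x),
               mean_display = round(mean(x), dg), sd_display = round(stats::sd(x), dg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation between two cohort variables
#'
#' Product-moment correlation with a two-sided p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Pairwise-complete observations are used and the effective `n`
#' reported.
#'
#' @param x,y Numeric vectors.
#' @param variable_x,variable_y Labels carried into the result.
#' @return One-row data frame: `x`, `y`, `r`, `p`, `n`.
#' @export
pearson_association <- function(x, y, variable_x = "x", variable_y = "y") {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("Pearson correlation needs n >= 3 complete pairs (have %d)", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation undefined: '%s' or '%s' is constant", variable_x, variable_y)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(x = variable_x, y = variable_y,
             r = unname(ct$estimate), p = ct$p.value, n = n,
             stringsAsFactors = FALSE)
}

#' Default variable pairs of the correlation battery
#'
#' Compression volume against every activation metric (percent BOLD and
#' VOA per ROI per hand), mJOA total against compression volume and the
#' cortical percent-BOLD metrics, and symptom duration against every
#' activation metric.
#'
#' @param cohort Cohort data frame (activation columns are discovered by
#'   their `pb_` / `voa_` prefixes).
#' @return Two-column data frame of variable pairs.
#' @export
default_battery_pairs <- function(cohort) {
  act <- grep("^(pb|voa)_", names(cohort), value = TRUE)
  cortical_pb <- grep("^pb_(M1|S1|SMA|PMC)_", names(cohort), value = TRUE)
  pairs <- rbind(
    if (length(act)) data.frame(x = "compression_volume", y = act),
    data.frame(x = "mjoa_total", y = "compression_volume"),
    if (length(cortical_pb)) data.frame(x = "mjoa_total", y = cortical_pb),
    if (length(act)) data.frame(x = "duration_months", y = act)
  )
  pairs[pairs$x %in% names(cohort) & pairs$y %in% names(cohort), , drop = FALSE]
}

#' Run the Pearson correlation battery over a cohort
#'
#' One correlation per requested variable pair, with pairwise-complete
#' cases and per-pair `n`. No multiplicity correction is applied to the
#' reported p-values (per-pair inference); a Benjamini-Hochberg adjusted
#' column `p_bh` is emitted alongside for the reader's judgement.
#'
#' @param cohort Cohort data frame.
#' @param pairs Data frame with columns `x`, `y`; defaults to
#'   [default_battery_pairs()].
#' @return Data frame: `x`, `y`, `r`, `p`, `n`, `p_bh`.
#' @export
correlation_battery <- function(cohort, pairs = NULL) {
  if (is.null(pairs)) pairs <- default_battery_pairs(cohort)
  unknown <- setdiff(unique(c(pairs$x, pairs$y)), names(cohort))
  if (length(unknown) > 0) stopf("unknown cohort variables: %s",
                                 paste(unknown, collapse = ", "))
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    xi <- cohort[[pairs$x[i]]]; yi <- cohort[[pairs$y[i]]]
    ok <- stats::complete.cases(xi, yi)
    if (sum(ok) < 3 || stats::sd(xi[ok]) == 0 || stats::sd(yi[ok]) == 0) {
      # degenerate pair (too few cases or a constant variable): keep the
      # row, flagged, so the battery shape stays predictable
      return(data.frame(x = pairs$x[i], y = pairs$y[i], r = NA_real_,
                        p = NA_real_, n = sum(ok), flag = "degenerate",
                        stringsAsFactors = FALSE))
    }
    cbind(pearson_association(xi, yi, pairs$x[i], pairs$y[i]), flag = "")
  }))
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Display rounding of a battery result
#'
#' Convention used for reporting: `r` to 2 decimal places, `p` to 2
#' significant figures; full precision is kept in the input.
#'
#' @param battery Result of [correlation_battery()].
#' @return The battery with `r_display` and `p_display` columns added.
#' @export
format_battery <- function(battery) {
  battery$r_display <- round(battery$r, 2)
  battery$p_display <- signif(battery$p, 2)
  battery
}
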