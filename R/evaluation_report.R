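#' Percentage of submissions adjudicated invalid
#'
#' `100 * n_invalid / n_total` with half-up rounding at presentation
#' precision (internal values are full precision). With 289 invalid of 478
#' submissions this prints 60.4; with 627 of 1900, 33.0.
#'
#' @param decisions Decision tibble (needs a `status` column).
#' @param digits Decimal places for half-up rounding (default 1).
#' @return A single number (percentage).
#' @export
proportion_invalid <- function(decisions, digits = 1) {
  n <- nrow(decisions)
  if (n == 0) abort("proportion_invalid needs at least one decision")
  round_half_up(100 * sum(decisions$status == "invalid") / n, digits)
}

#' Detector performance against ground-truth labels
#'
#' Standard 2x2 confusion counts with spam as the positive class: a true
#' positive is a spam-labelled submission adjudicated invalid. Review-status
#' submissions count as *not* invalid by default (conservative — in the
#' field they go to human adjudication); `review_as_invalid = TRUE` switches
#' to the strict reading.
#'
#' @param decisions Decision tibble.
#' @param labels Ground-truth tibble (`submission_id`, `label`); any label
#'   other than `"valid"` is spam.
#' @param review_as_invalid Count review-status submissions as invalid.
#' @return An `evaluation_summary` list: `n_total`, `n_valid_status`,
#'   `n_review`, `n_invalid`, `percent_invalid`, `confusion` (TP, FP, TN,
#'   FN), `sensitivity`, `specificity`, `ppv`.
#' @export
confusion_metrics <- function(decisions, labels, review_as_invalid = FALSE) {
  idx <- match(decisions$submission_id, labels$submission_id)
  if (anyNA(idx)) {
    abort(sprintf(
      "No ground-truth label for submission(s): %s",
      paste(decisions$submission_id[is.na(idx)], collapse = ", ")
    ))
  }
  truth_spam <- labels$label[idx] != "valid"
  pred_invalid <- decisions$status == "invalid" |
    (review_as_invalid & decisions$status == "review")
  tp <- sum(truth_spam & pred_invalid)
  fp <- sum(!truth_spam & pred_invalid)
  tn <- sum(!truth_spam & !pred_invalid)
  fn <- sum(truth_spam & !pred_invalid)
  structure(list(
    n_total = nrow(decisions),
    n_valid_status = sum(decisions$status == "valid"),
    n_review = sum(decisions$status == "review"),
    n_invalid = sum(decisions$status == "invalid"),
    percent_invalid = proportion_invalid(decisions),
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  ), class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("<evaluation_summary>\n")
  cat(sprintf("  %d submissions: %d valid / %d review / %d invalid (%.1f%% invalid)\n",
              x$n_total, x$n_valid_status, x$n_review, x$n_invalid, x$percent_invalid))
  cat(sprintf("  confusion (spam positive): TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"], x$confusion["FN"]))
  cat(sprintf("  sensitivity %.4f, specificity %.4f, ppv %.4f\n",
              x$sensitivity, x$specificity, x$ppv))
  invisible(x)
}

#' Calendar length of a study window
#'
#' @param start_date,end_date Dates (or date strings); `end_date` must not
#'   precede `start_date`.
#' @return Integer day count `end - start` (same date gives 0).
#' @export
#' @examples
#' study_window_days("2015-10-21", "2016-01-01")  # 72
study_window_days <- function(start_date, end_date) {
  s <- as.Date(start_date)
  e <- as.Date(end_date)
  if (is.na(s) || is.na(e)) abort("Unparseable date")
  if (e < s) abort("end_date precedes start_date")
  as.integer(e - s)
}

#' Demographic summary of a cohort
#'
#' Sample mean and standard deviation (n-1 denominator) of respondent age,
#' and the fraction reporting their cancer successfully treated among
#' non-missing cancer statuses. With a single record the SD is reported as
#' missing.
#'
#' @param records Submissions tibble with `age_years` (and optionally
#'   `cancer_status`).
#' @return One-row tibble: `n`, `n_age`, `mean_age`, `sd_age`,
#'   `treated_fraction`.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0) abort("summarize_cohort needs at least one record")
  age <- records$age_years[!is.na(records$age_years)]
  if (length(age) == 0) abort("summarize_cohort needs at least one non-missing age")
  status <- records$cancer_status
  known <- status[!is.na(status) & status != "missing"]
  tibble(
    n = nrow(records),
    n_age = length(age),
    mean_age = mean(age),
    sd_age = if (length(age) > 1) sd(age) else NA_real_,
    treated_fraction = if (length(known) > 0) {
      mean(known == "successfully_treated")
    } else {
      NA_real_
    }
  )
}

#' Write the audit report
#'
#' A deterministic human-readable account of a validation batch: cohort
#' summary tables, the status breakdown, a per-record case-study narrative
#' for every flagged submission (each strike with its evidence string), and
#' the drift timeline when a drift report is supplied. Writes
#' `<path>.md` and a machine-readable `<path>.json`; regenerating from
#' identical inputs is byte-identical.
#'
#' @param records Submissions tibble.
#' @param decisions Decision tibble corresponding to `records`.
#' @param path Output stem (no extension).
#' @param drift Optional `drift_report` to include as a timeline.
#' @return Invisibly, the two file paths written.
#' @export
write_audit_report <- function(records, decisions, path, drift = NULL) {
  stats_tbl <- summarize_cohort(records)
  lines <- c(
    "# Survey validation audit report", "",
    "## Cohort", "",
    sprintf("- submissions: %d", stats_tbl$n),
    sprintf("- mean age: %.2f years (SD %s, n=%d with age)",
            stats_tbl$mean_age,
            ifelse(is.na(stats_tbl$sd_age), "NA", sprintf("%.2f", stats_tbl$sd_age)),
            stats_tbl$n_age),
    sprintf("- successfully treated: %s",
            ifelse(is.na(stats_tbl$treated_fraction), "NA",
                   sprintf("%.1f%%", 100 * stats_tbl$treated_fraction))),
    "",
    "## Adjudication", "",
    sprintf("- valid: %d", sum(decisions$status == "valid")),
    sprintf("- review: %d", sum(decisions$status == "review")),
    sprintf("- invalid: %d (%.1f%%)", sum(decisions$status == "invalid"),
            proportion_invalid(decisions)),
    "",
    "## Case studies (flagged submissions)", ""
  )
  flagged <- decisions[decisions$strike_count > 0 | decisions$status != "valid", ,
                       drop = FALSE]
  if (nrow(flagged) == 0) {
    lines <- c(lines, "_No flagged submissions._", "")
  } else {
    for (i in seq_len(nrow(flagged))) {
      d <- flagged[i, ]
      lines <- c(lines, sprintf("### %s — %s (%d strike%s)",
                                d$submission_id, d$status, d$strike_count,
                                ifelse(d$strike_count == 1, "", "s")))
      s <- d$strikes[[1]]
      if ("incomplete" %in% d$reason_codes[[1]]) {
        lines <- c(lines, "- [incomplete] submission is partial; invalid by rule")
      }
      if (!is.null(s) && nrow(s) > 0) {
        lines <- c(lines, sprintf("- [%s/%s] %s", s$category, s$rule_id, s$evidence))
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(drift)) {
    lines <- c(lines, "## Drift timeline", "")
    if (nrow(drift$alerts) == 0) {
      lines <- c(lines, "_No drift alerts._", "")
    } else {
      lines <- c(lines, sprintf(
        "- %s: hit rate %.2f -> %.2f at window %d",
        drift$alerts$rule_id, drift$alerts$previous_rate,
        drift$alerts$current_rate, drift$alerts$window_index
      ), "")
    }
  }
  md_path <- paste0(path, ".md")
  json_path <- paste0(path, ".json")
  writeLines(lines, md_path)
  payload <- list(
    cohort = as.list(stats_tbl),
    adjudication = list(
      valid = sum(decisions$status == "valid"),
      review = sum(decisions$status == "review"),
      invalid = sum(decisions$status == "invalid"),
      percent_invalid = proportion_invalid(decisions)
    ),
    cases = lapply(seq_len(nrow(flagged)), function(i) {
      s <- flagged$strikes[[i]]
      list(
        submission_id = flagged$submission_id[i],
        status = flagged$status[i],
        strike_count = flagged$strike_count[i],
        reason_codes = as.list(flagged$reason_codes[[i]]),
        evidence = if (is.null(s)) list() else as.list(s$evidence)
      )
    })
  )
  if (!is.null(drift)) {
    payload$drift_alerts <- lapply(seq_len(nrow(drift$alerts)), function(i) {
      as.list(drift$alerts[i, ])
    })
  }
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(md_path, json_path))
}
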