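#' Adjudicate one submission under the k-strikes rule
#'
#' A partial submission is invalid regardless of strikes (reason code
#' `incomplete`); otherwise a complete submission is invalid at
#' `strike_threshold_k` or more strikes, queued for manual review at one to
#' k-1 strikes, and valid at zero. No single indicator can invalidate a
#' complete submission (the config enforces k >= 2).
#'
#' @param record One submission (one-row tibble or named list).
#' @param strikes Strike tibble for this submission (columns `rule_id`,
#'   `category`, `evidence`).
#' @param config A validated `rule_config`.
#' @return A one-row decision tibble: `submission_id`, `status`
#'   (`valid`/`review`/`invalid`), `strike_count`, `reason_codes`
#'   (list-column), `strikes` (list-column), `config_id`, `end_timestamp`.
#' @export
adjudicate <- function(record, strikes, config = default_rule_config()) {
  record <- as_record(record)
  n <- nrow(strikes)
  partial <- !identical(record$completion_status, "complete")
  status <- if (partial) "invalid"
  else if (n >= config$strike_threshold_k) "invalid"
  else if (n >= 1) "review"
  else "valid"
  reasons <- strikes$rule_id
  if (partial) reasons <- c("incomplete", reasons)
  tibble(
    submission_id = record$submission_id,
    status = status,
    strike_count = as.integer(n),
    reason_codes = list(reasons),
    strikes = list(strikes),
    config_id = config$config_id,
    end_timestamp = record$end_timestamp %||% NA_character_
  )
}

config_for_date <- function(config_history, date) {
  for (cfg in config_history) {
    w <- cfg$effective_window
    lo <- if (is.na(w[1])) as.Date("0001-01-01") else as.Date(w[1])
    hi <- if (is.na(w[2])) as.Date("9999-12-31") else as.Date(w[2])
    if (!is.na(date) && date >= lo && date <= hi) return(cfg)
  }
  NULL
}

check_history <- function(config_history) {
  if (inherits(config_history, "rule_config")) config_history <- list(config_history)
  lapply(config_history, validate_rule_config)
  if (length(config_history) > 1) {
    win <- t(vapply(config_history, function(c) {
      w <- c$effective_window
      c(if (is.na(w[1])) -Inf else as.numeric(as.Date(w[1])),
        if (is.na(w[2])) Inf else as.numeric(as.Date(w[2])))
    }, numeric(2)))
    ord <- order(win[, 1])
    win <- win[ord, , drop = FALSE]
    for (i in seq_len(nrow(win) - 1)) {
      if (win[i + 1, 1] <= win[i, 2]) {
        abort("rule_config effective windows overlap; eras must be disjoint")
      }
    }
  }
  config_history
}

#' Run the full validation protocol over a batch of submissions
#'
#' Builds the dataset-level deduplication context once over all submissions,
#' then adjudicates each record under the configuration whose effective
#' window contains the record's end date (its local calendar date of
#' completion — a record becomes adjudicable when it completes). With a
#' multi-era history, the context's thresholds come from the final era's
#' config; each era's `enabled_rules` still controls which strikes are
#' admitted for its records. Deterministic given identical inputs.
#'
#' @param records Submissions tibble.
#' @param config_history A `rule_config` or list of them with disjoint
#'   effective windows covering all submission dates.
#' @param geo Optional `geo_table` for the IP/zip consistency rule.
#' @return Decision tibble, one row per record, in input order.
#' @export
run_protocol <- function(records, config_history = default_rule_config(),
                         geo = NULL) {
  config_history <- check_history(config_history)
  if (nrow(records) == 0) {
    return(adjudicate(list(submission_id = "x", completion_status = "complete"),
                      empty_strikes(), config_history[[1]])[0, ])
  }
  context_cfg <- config_history[[length(config_history)]]
  ctx <- build_dedup_context(records, context_cfg)
  ctx_strikes <- dedup_strikes(ctx)
  cohort_median <- median(records$duration_minutes, na.rm = TRUE)

  end_dates <- ts_local_date(records$end_timestamp)
  decisions <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- as_record(records[i, ])
    cfg <- config_for_date(config_history, end_dates[i])
    if (is.null(cfg)) {
      abort(sprintf(
        "Submission %s (end date %s) falls outside every config's effective window",
        rec$submission_id, as.character(end_dates[i])
      ))
    }
    s_ded <- ctx_strikes[ctx_strikes$submission_id == rec$submission_id &
                           ctx_strikes$rule_id %in% cfg$enabled_rules,
                         c("rule_id", "category", "evidence")]
    s_rec <- plausibility_strikes(rec, cfg, geo, cohort_median)
    decisions[[i]] <- adjudicate(rec, dplyr::bind_rows(s_ded, s_rec), cfg)
  }
  dplyr::bind_rows(decisions)
}

#' Re-adjudicate every submission under one uniform final configuration
#'
#' After recruitment ends, rules changed mid-study are re-applied uniformly:
#' every record is re-adjudicated under `final_config` alone and paired with
#' its era decision. Idempotent — running the pass twice gives identical
#' output.
#'
#' @param records Submissions tibble.
#' @param final_config The uniform `rule_config` to apply retrospectively.
#' @param geo Optional `geo_table`.
#' @param era_decisions Decision tibble from the era-by-era [run_protocol()]
#'   run; its statuses populate `era_status`.
#' @return Tibble with `submission_id`, `era_status`, `retrospective_status`.
#' @export
retrospective_pass <- function(records, final_config, geo = NULL,
                               era_decisions = NULL) {
  final_config <- validate_rule_config(final_config)
  uniform <- final_config
  uniform$effective_window <- c(NA_character_, NA_character_)
  retro <- run_protocol(records, uniform, geo)
  era_status <- if (is.null(era_decisions)) {
    rep(NA_character_, nrow(records))
  } else {
    era_decisions$status[match(records$submission_id, era_decisions$submission_id)]
  }
  tibble(
    submission_id = records$submission_id,
    era_status = era_status,
    retrospective_status = retro$status
  )
}

#' Monitor per-rule drift across the study period
#'
#' Splits the decisions into consecutive windows of `drift_window_days`
#' (calendar days of the end timestamp) and computes, per window and per
#' rule, the hit rate among flagged submissions: submissions carrying that
#' rule's strike divided by submissions with at least one strike. Computing
#' among flagged submissions keeps drift in spam *style* visible even as
#' spam volume varies. An alert is raised whenever a rule's rate jumps by
#' more than `drift_delta` between consecutive non-empty windows — the
#' signature of spam evolving past one family of rules while another keeps
#' firing.
#'
#' @param decisions Decision tibble from [run_protocol()] (needs the
#'   `strikes` list-column and `end_timestamp`).
#' @param config A `rule_config` (`drift_window_days`, `drift_delta`).
#' @return A `drift_report`: `windows` tibble (`window_index`,
#'   `window_start`, `rule_id`, `hit_rate`, `n_flagged`) and `alerts` tibble
#'   (`rule_id`, `window_index`, `previous_rate`, `current_rate`). Fewer
#'   than two non-empty windows yields an empty report.
#' @export
monitor_drift <- function(decisions, config = default_rule_config()) {
  empty <- structure(list(
    windows = tibble(window_index = integer(0), window_start = as.Date(character(0)),
                     rule_id = character(0), hit_rate = numeric(0), n_flagged = integer(0)),
    alerts = tibble(rule_id = character(0), window_index = integer(0),
                    previous_rate = numeric(0), current_rate = numeric(0))
  ), class = "drift_report")
  flagged <- decisions[decisions$strike_count >= 1, , drop = FALSE]
  if (nrow(flagged) == 0) return(empty)
  dates <- ts_local_date(flagged$end_timestamp)
  ok <- !is.na(dates)
  flagged <- flagged[ok, , drop = FALSE]
  dates <- dates[ok]
  if (nrow(flagged) == 0) return(empty)

  origin <- min(dates)
  widx <- as.integer(floor(as.numeric(dates - origin) / config$drift_window_days))
  nonempty <- sort(unique(widx))
  if (length(nonempty) < 2) return(empty)

  all_rules <- rule_registry()$rule_id
  win_rows <- list()
  for (w in nonempty) {
    sub <- flagged[widx == w, , drop = FALSE]
    fired <- lapply(sub$strikes, function(s) unique(s$rule_id))
    rates <- vapply(all_rules, function(r) {
      mean(vapply(fired, function(f) r %in% f, logical(1)))
    }, numeric(1))
    win_rows[[length(win_rows) + 1]] <- tibble(
      window_index = w,
      window_start = origin + w * config$drift_window_days,
      rule_id = all_rules,
      hit_rate = unname(rates),
      n_flagged = nrow(sub)
    )
  }
  windows <- dplyr::bind_rows(win_rows)

  alert_rows <- list()
  for (k in seq_along(nonempty)[-1]) {
    prev <- windows[windows$window_index == nonempty[k - 1], ]
    cur <- windows[windows$window_index == nonempty[k], ]
    jump <- abs(cur$hit_rate - prev$hit_rate) > config$drift_delta
    if (any(jump)) {
      alert_rows[[length(alert_rows) + 1]] <- tibble(
        rule_id = cur$rule_id[jump],
        window_index = nonempty[k],
        previous_rate = prev$hit_rate[jump],
        current_rate = cur$hit_rate[jump]
      )
    }
  }
  structure(list(
    windows = windows,
    alerts = if (length(alert_rows) == 0) empty$alerts else dplyr::bind_rows(alert_rows)
  ), class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  nw <- length(unique(x$windows$window_index))
  cat("<drift_report>", nw, "window(s),", nrow(x$alerts), "alert(s)\n")
  if (nrow(x$alerts) > 0) {
    for (i in seq_len(nrow(x$alerts))) {
      cat(sprintf("  %s: %.2f -> %.2f at window %d\n",
                  x$alerts$rule_id[i], x$alerts$previous_rate[i],
                  x$alerts$current_rate[i], x$alerts$window_index[i]))
    }
  }
  invisible(x)
}

#' Extract the manual review queue
#'
#' Submissions with between one and k-1 strikes are never auto-invalidated;
#' they are queued for human adjudication (the study's human-in-the-loop
#' step). This helper filters them out of a decision table.
#'
#' @param decisions Decision tibble.
#' @return The rows with `status == "review"`.
#' @export
review_queue <- function(decisions) {
  decisions[decisions$status == "review", , drop = FALSE]
}
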