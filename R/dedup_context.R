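#' Run-length character-class signature of an email handle
#'
#' Maps each character of the handle (the part before `@`) to a class —
#' letters `L`, digits `D`, anything else `O` — and encodes the run lengths,
#' so `abc123` becomes `"L3D3"` and `john.smith` becomes `"L4O1L5"`. Handles
#' that follow one generation convention collapse to one signature while
#' ordinary personalised handles spread over many.
#'
#' @param email Email address(es); `NA` yields `NA`.
#' @return Character vector of signatures.
#' @export
#' @examples
#' email_signature(c("abc123@me.com", "john.smith@gmail.com"))
email_signature <- function(email) {
  handle <- sub("@.*$", "", email)
  vapply(handle, function(h) {
    if (is.na(h) || !nzchar(h)) return(NA_character_)
    chars <- strsplit(h, "")[[1]]
    cls <- ifelse(grepl("[A-Za-z]", chars), "L", ifelse(grepl("[0-9]", chars), "D", "O"))
    r <- rle(cls)
    paste0(r$values, r$lengths, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

email_host <- function(email) {
  host <- tolower(sub("^[^@]*@", "", email))
  host <- sub("^\\.+", "", host)  # tolerate stray leading dot in the domain
  ifelse(is.na(email) | !grepl("@", email), NA_character_, host)
}

#' Find groups of submissions sharing an IP address
#'
#' @param records Submissions tibble.
#' @param config A `rule_config`; when `ip_prefix_grouping` is `TRUE`,
#'   grouping is by /24 prefix instead of the exact address (default off).
#' @return List of character vectors of submission ids, one per IP shared by
#'   at least two records; singletons excluded. Records with missing IPs are
#'   ignored for this signal.
#' @export
find_duplicate_ips <- function(records, config = default_rule_config()) {
  ok <- !is.na(records$ip_address) & nzchar(records$ip_address)
  key <- records$ip_address[ok]
  if (isTRUE(config$ip_prefix_grouping)) key <- ip24_prefix(key)
  groups <- split(records$submission_id[ok], key)
  unname(lapply(groups[lengths(groups) >= 2], sort))
}

#' Flag submissions whose email handles follow a shared convention
#'
#' Clusters addresses by `(host domain, handle signature)` — see
#' [email_signature()] — and flags every member of a cluster of at least
#' `email_cluster_min` submissions. Captures generated address batches such as
#' `abc123@me.com`, `qrs789@me.com`, `xyz456@me.com`.
#'
#' @inheritParams find_duplicate_ips
#' @return Sorted character vector of flagged submission ids.
#' @export
score_email_convention <- function(records, config = default_rule_config()) {
  host <- email_host(records$email_address)
  sig <- email_signature(records$email_address)
  ok <- !is.na(host) & !is.na(sig)
  key <- paste0(host[ok], "/", sig[ok])
  groups <- split(records$submission_id[ok], key)
  flagged <- unlist(groups[lengths(groups) >= config$email_cluster_min],
                    use.names = FALSE)
  sort(unique(c(flagged, character(0))))
}

#' Flag chains of submissions that start seconds after another ends
#'
#' A pair of submissions is adjacent when one's start time minus the other's
#' end time lies in `(0, adjacency_gap_seconds]`; both members of every
#' adjacent pair are flagged, and chains (A ends, B starts, B ends, C starts)
#' propagate through shared members. Equivalent to the all-ordered-pairs gap
#' check.
#'
#' @inheritParams find_duplicate_ips
#' @return Sorted character vector of flagged submission ids.
#' @export
find_temporal_adjacency <- function(records, config = default_rule_config()) {
  ok <- ts_is_valid(records$start_timestamp) & ts_is_valid(records$end_timestamp)
  ids <- records$submission_id[ok]
  if (length(ids) < 2) return(character(0))
  starts <- ts_epoch(records$start_timestamp[ok])
  ends <- ts_epoch(records$end_timestamp[ok])
  gap <- config$adjacency_gap_seconds

  ord <- order(ends)
  ends_sorted <- ends[ord]
  flagged <- logical(length(ids))
  # For each record j, every earlier-ending record i with
  # start_j - end_i in (0, gap] flags both i and j.
  lo <- findInterval(starts - gap, ends_sorted, left.open = TRUE)  # ends < start - gap
  hi <- findInterval(starts, ends_sorted, left.open = TRUE)  # ends < start
  has_pred <- hi > lo
  flagged[has_pred] <- TRUE
  for (j in which(has_pred)) {
    flagged[ord[(lo[j] + 1):hi[j]]] <- TRUE
  }
  sort(ids[flagged])
}

#' Flag submissions completed in the early hours of the morning
#'
#' Uses the submission's local wall-clock end time (the timestamp as written,
#' with its own UTC offset) against the half-open window
#' `[odd_hour_window[1], odd_hour_window[2])`, by default 00:00-05:00.
#'
#' @inheritParams find_duplicate_ips
#' @return Sorted character vector of flagged submission ids.
#' @export
detect_odd_hour <- function(records, config = default_rule_config()) {
  ok <- ts_is_valid(records$end_timestamp)
  mins <- ts_local_minutes(records$end_timestamp[ok])
  lo <- parse_clock(config$odd_hour_window[1])
  hi <- parse_clock(config$odd_hour_window[2])
  inside <- if (lo <= hi) mins >= lo & mins < hi else mins >= lo | mins < hi
  sort(records$submission_id[ok][inside])
}

#' Find groups sharing an identical improbable value
#'
#' For a field where identical values across respondents are improbable
#' (default: date of birth), returns groups of at least `shared_anomaly_min`
#' submissions sharing one identical non-missing value — e.g. a batch of
#' records all claiming birth date 1901-01-01.
#'
#' @inheritParams find_duplicate_ips
#' @param field_id Name of the submissions column to examine.
#' @return List of character vectors of submission ids.
#' @export
detect_shared_anomaly <- function(records, field_id = "birth_date",
                                  config = default_rule_config()) {
  if (!field_id %in% names(records)) {
    abort(sprintf("Unknown field for shared-anomaly detection: %s", field_id))
  }
  v <- records[[field_id]]
  ok <- !is.na(v) & nzchar(as.character(v))
  groups <- split(records$submission_id[ok], as.character(v[ok]))
  unname(lapply(groups[lengths(groups) >= config$shared_anomaly_min], sort))
}

#' Build the dataset-level deduplication context
#'
#' Computes every signal that needs all submissions at once: duplicate-IP
#' groups, email-convention clusters, temporal-adjacency chains, odd-hour
#' completions, and shared-anomaly groups (on `anomaly_fields`, default the
#' birth date).
#'
#' @inheritParams find_duplicate_ips
#' @param anomaly_fields Fields to scan for shared improbable values.
#' @return A `dedup_context` object.
#' @export
build_dedup_context <- function(records, config = default_rule_config(),
                                anomaly_fields = "birth_date") {
  anomaly <- lapply(setNames(anomaly_fields, anomaly_fields), function(f) {
    detect_shared_anomaly(records, f, config)
  })
  structure(
    list(
      ip_groups = find_duplicate_ips(records, config),
      email_flagged = score_email_convention(records, config),
      adjacency_flagged = find_temporal_adjacency(records, config),
      odd_hour_ids = detect_odd_hour(records, config),
      shared_anomaly_groups = anomaly
    ),
    class = "dedup_context"
  )
}

#' @export
print.dedup_context <- function(x, ...) {
  cat("<dedup_context>\n")
  cat("  duplicate-IP groups:   ", length(x$ip_groups), "\n")
  cat("  email-convention ids:  ", length(x$email_flagged), "\n")
  cat("  adjacency-chain ids:   ", length(x$adjacency_flagged), "\n")
  cat("  odd-hour ids:          ", length(x$odd_hour_ids), "\n")
  cat("  shared-anomaly fields: ", paste(names(x$shared_anomaly_groups), collapse = ", "), "\n")
  invisible(x)
}

# Strikes contributed by the dataset-level signals, one tibble for the whole
# batch (submission_id, rule_id, category, evidence).
dedup_strikes <- function(context) {
  rows <- list()
  for (g in context$ip_groups) {
    rows[[length(rows) + 1]] <- tibble(
      submission_id = g, rule_id = "duplicate_ip", category = "dedup",
      evidence = sprintf("ip_address shared by %d submissions (%s)",
                         length(g), paste(g, collapse = ", "))
    )
  }
  if (length(context$email_flagged) > 0) {
    rows[[length(rows) + 1]] <- tibble(
      submission_id = context$email_flagged, rule_id = "email_convention",
      category = "dedup",
      evidence = "email_address handle follows a shared host/signature convention"
    )
  }
  if (length(context$adjacency_flagged) > 0) {
    rows[[length(rows) + 1]] <- tibble(
      submission_id = context$adjacency_flagged, rule_id = "temporal_adjacency",
      category = "dedup",
      evidence = "start_timestamp within the adjacency gap of another submission's end"
    )
  }
  if (length(context$odd_hour_ids) > 0) {
    rows[[length(rows) + 1]] <- tibble(
      submission_id = context$odd_hour_ids, rule_id = "odd_hour",
      category = "dedup",
      evidence = "end_timestamp falls in the odd-hour window (local clock)"
    )
  }
  for (f in names(context$shared_anomaly_groups)) {
    for (g in context$shared_anomaly_groups[[f]]) {
      rows[[length(rows) + 1]] <- tibble(
        submission_id = g, rule_id = "shared_anomaly", category = "dedup",
        evidence = sprintf("%s value identical across %d submissions", f, length(g))
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(submission_id = character(0), rule_id = character(0),
                  category = character(0), evidence = character(0)))
  }
  out <- dplyr::bind_rows(rows)
  # one strike per (submission, rule): a record in two duplicate-IP groups
  # still carries a single duplicate-IP strike
  dplyr::distinct(out, .data$submission_id, .data$rule_id, .keep_all = TRUE)
}
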