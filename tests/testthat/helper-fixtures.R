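# Fixture builders and brute-force oracles used across the suite.

# A benign, complete, internally consistent submission; override any field.
# Timestamps sit in region AL of the bundled synthetic geo table
# (ip 10.1.0.x <-> zip3 010..013).
make_record <- function(submission_id = "R1", ...) {
  rec <- tibble::tibble(
    submission_id = submission_id,
    channel_id = "A",
    screener_age_ok = TRUE, screener_residence_ok = TRUE,
    screener_gbm_ok = TRUE, screener_treatment_ok = TRUE,
    prior_completion_denied = TRUE, consent_given = TRUE,
    start_timestamp = "2015-11-03T13:10:00-06:00",
    end_timestamp = "2015-11-03T14:00:00-06:00",
    duration_minutes = 50,
    ip_address = "10.1.0.5",
    email_address = "gerald.hopkins@gmail.example",
    zip_code = "01012",
    birth_date = "1952-03-14",
    age_years = 63L,
    age_at_diagnosis = 55L,
    psa_at_diagnosis = 6.5,
    gleason_total = 6L,
    treatment_history = list(tibble::tibble(treatment = "prostatectomy",
                                            provider = "urologist")),
    disclosure_to_provider = TRUE,
    rehab_recommendations = list(character(0)),
    discrimination_attributes = list(character(0)),
    cancer_status = "successfully_treated",
    grid_responses = list(list(sexual_function = c(1, 3, 2, 5, 4, 2, 3, 1),
                               mental_health = c(2, 4, 1, 3, 5, 3, 2, 4))),
    verification_items = list(list(v1 = c(2, 2))),
    text_responses = list(list(t1 = "Recovery took longer than I expected",
                               t2 = "My surgeon explained everything clearly")),
    completion_status = "complete",
    ballot_box_cookie_present = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) {
    v <- dots[[nm]]
    rec[[nm]] <- if (is.list(rec[[nm]]) && !is.list(v)) list(v) else
      if (is.list(rec[[nm]])) list(v) else v
  }
  # keep duration consistent with timestamps unless explicitly overridden
  if (!"duration_minutes" %in% names(dots) &&
      any(c("start_timestamp", "end_timestamp") %in% names(dots))) {
    rec$duration_minutes <-
      (surveyguard:::ts_epoch(rec$end_timestamp) -
         surveyguard:::ts_epoch(rec$start_timestamp)) / 60
  }
  rec
}

make_records <- function(...) dplyr::bind_rows(...)

# Distinct benign records: unique IPs and birth dates, and email handles
# whose run-length signatures are all distinct (letter-run lengths encode i),
# so no dedup signal fires on the batch itself. Supports n <= 48.
benign_batch <- function(n, day0 = 1) {
  stopifnot(n <= 48)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    day <- sprintf("2015-11-%02d", day0 + (i - 1) %% 20)
    handle <- paste0(substr("abcdefg", 1, i %% 7 + 1), ".",
                     substr("stuvwxyz", 1, i %/% 7 + 1))
    make_record(
      submission_id = sprintf("B%03d", i),
      ip_address = sprintf("10.1.0.%d", i %% 250 + 1),
      email_address = paste0(handle, "@gmail.example"),
      birth_date = sprintf("19%02d-%02d-%02d", 40 + i %% 30,
                           i %% 12 + 1, i %% 28 + 1),
      start_timestamp = sprintf("%sT13:10:00-06:00", day),
      end_timestamp = sprintf("%sT14:00:00-06:00", day)
    )
  }))
}

# ---- brute-force oracles (all-pairs comparisons) ---------------------------

oracle_duplicate_ips <- function(records) {
  ids <- records$submission_id
  ip <- records$ip_address
  keep <- !is.na(ip) & nzchar(ip)
  groups <- list()
  used <- rep(FALSE, length(ids))
  for (i in which(keep)) {
    if (used[i]) next
    members <- i
    for (j in which(keep)) {
      if (j != i && ip[j] == ip[i]) members <- c(members, j)
    }
    if (length(members) >= 2) {
      groups[[length(groups) + 1]] <- sort(ids[members])
      used[members] <- TRUE
    }
  }
  groups
}

oracle_adjacency <- function(records, gap) {
  ids <- records$submission_id
  s <- surveyguard:::ts_epoch(records$start_timestamp)
  e <- surveyguard:::ts_epoch(records$end_timestamp)
  flagged <- character(0)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      d <- s[j] - e[i]
      if (d > 0 && d <= gap) flagged <- c(flagged, ids[i], ids[j])
    }
  }
  sort(unique(flagged))
}

oracle_shared_anomaly <- function(records, field, min_size) {
  v <- as.character(records[[field]])
  ids <- records$submission_id
  keep <- !is.na(v) & nzchar(v)
  groups <- list()
  for (val in unique(v[keep])) {
    members <- ids[keep & v == val]
    if (length(members) >= min_size) groups[[length(groups) + 1]] <- sort(members)
  }
  groups
}

label_of <- function(cohort, ids) {
  cohort$labels$label[match(ids, cohort$labels$submission_id)]
}
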