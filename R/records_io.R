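#' Default rule configuration
#'
#' Returns the default screening protocol: every threshold and switch used by
#' the indicator rules and the k-strikes adjudication. Defaults encode a
#' validation protocol for a 45-60 minute instrument: submissions faster than
#' 30 minutes are speeding; a diagnosis age under 40, PSA above 20 ng/mL or a
#' Gleason total above 6 are clinically improbable; and no single indicator can
#' invalidate a submission (`strike_threshold_k` must be at least 2 — three
#' strikes by default).
#'
#' @param ... Named overrides for any configuration field.
#' @return A `rule_config` object (a validated named list).
#' @export
#' @examples
#' cfg <- default_rule_config(strike_threshold_k = 2)
#' cfg$duration_min_minutes
default_rule_config <- function(...) {
  cfg <- list(
    config_id = "default",
    effective_window = c(NA_character_, NA_character_),  # open-ended era
    duration_min_minutes = 30,
    relative_speed_enabled = FALSE,
    relative_speed_fraction = 1 / 3,
    age_dx_min = 40,
    psa_max = 20,
    gleason_max = 6,
    forbidden_transitions = list(
      c("prostatectomy", "watchful_waiting"),
      c("prostatectomy", "active_surveillance"),
      c("prostatectomy", "diet"),
      c("radiation", "diet")
    ),
    provider_compat = list(
      prostatectomy = "urologist",
      radiation = "radiation_oncologist",
      chemotherapy = "oncologist",
      hormone = "oncologist",
      active_surveillance = c("urologist", "oncologist"),
      watchful_waiting = c("urologist", "oncologist"),
      diet = c("none", "self", "urologist", "oncologist")
    ),
    disclosure_required_rehab = c("dilator", "dildo", "butt_plug"),
    peripheral_discrimination = c("weight", "height", "appearance"),
    core_discrimination = c("race", "sexual_orientation"),
    grid_min_items = 5,
    differentiation_threshold = 0.2,
    nonresponse_threshold = 0.2,
    gibberish_vowel_fraction = 0.5,
    email_cluster_min = 3,
    adjacency_gap_seconds = 60,
    odd_hour_window = c("00:00", "05:00"),
    shared_anomaly_min = 3,
    strike_threshold_k = 3,
    drift_window_days = 7,
    drift_delta = 0.3,
    ip_prefix_grouping = FALSE,
    enabled_rules = rule_registry()$rule_id
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unknown rule_config key(s): %s. Allowed keys: %s",
      paste(unknown, collapse = ", "), paste(names(cfg), collapse = ", ")
    ))
  }
  cfg[names(overrides)] <- overrides
  cfg$effective_window <- as.character(cfg$effective_window)
  validate_rule_config(structure(cfg, class = "rule_config"))
}

#' Validate a rule configuration
#'
#' Checks every invariant of the protocol configuration, most importantly that
#' `strike_threshold_k >= 2`: the protocol forbids treating any single
#' indicator as sufficient grounds to call a submission invalid.
#'
#' @param config A `rule_config` object.
#' @return The config, invisibly usable, after validation.
#' @export
validate_rule_config <- function(config) {
  k <- config$strike_threshold_k
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 2) {
    abort(paste(
      "strike_threshold_k must be >= 2: no single indicator is deemed",
      "sufficient to call a submission invalid."
    ))
  }
  num_fields <- c(
    "duration_min_minutes", "relative_speed_fraction", "age_dx_min",
    "psa_max", "gleason_max", "grid_min_items", "differentiation_threshold",
    "nonresponse_threshold", "gibberish_vowel_fraction", "email_cluster_min",
    "adjacency_gap_seconds", "shared_anomaly_min", "drift_window_days",
    "drift_delta"
  )
  for (f in num_fields) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(sprintf("rule_config field '%s' must be a finite number", f))
    }
  }
  if (config$email_cluster_min < 2) {
    abort("email_cluster_min must be >= 2")
  }
  win <- config$odd_hour_window
  if (length(win) != 2 || !all(grepl("^\\d{2}:\\d{2}$", win))) {
    abort("odd_hour_window must be two HH:MM clock times")
  }
  config
}

#' Load a rule configuration from JSON or YAML
#'
#' Absent keys are filled with [default_rule_config()] values; unknown keys are
#' an error (listing the allowed keys); `strike_threshold_k = 1` is rejected.
#' An absent path, or an empty file, yields the defaults.
#'
#' @param path Path to a `.json`, `.yml`/`.yaml` file, or `NULL`.
#' @return A validated `rule_config`.
#' @export
load_rule_config <- function(path = NULL) {
  if (is.null(path)) {
    return(default_rule_config())
  }
  if (!file.exists(path)) {
    abort(sprintf("Rule config file not found: %s", path))
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw) || length(raw) == 0) {
    return(default_rule_config())
  }
  # forbidden_transitions may arrive as a matrix/list of 2-vectors from JSON
  if (!is.null(raw$forbidden_transitions)) {
    ft <- raw$forbidden_transitions
    if (is.matrix(ft)) ft <- lapply(seq_len(nrow(ft)), function(i) ft[i, ])
    raw$forbidden_transitions <- lapply(ft, as.character)
  }
  do.call(default_rule_config, raw)
}

#' Write a rule configuration to JSON
#'
#' Round-trips through [load_rule_config()]: loading a serialised default
#' config reproduces the defaults (defaulting is idempotent).
#'
#' @param config A `rule_config`.
#' @param path Output path (JSON).
#' @export
write_rule_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---- geo lookup table -------------------------------------------------------

#' Read an offline geo lookup table
#'
#' The table maps /24 IPv4 prefixes (`kind = "ip24"`) and 3-digit zip prefixes
#' (`kind = "zip3"`) to region codes drawn from one shared vocabulary. Lookups
#' are total: an absent key resolves to `"unknown"`.
#'
#' @param path CSV with columns `kind`, `key`, `region`.
#' @return A `geo_table` object.
#' @export
read_geo_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("kind", "key", "region")
  if (!all(need %in% names(df))) {
    abort(sprintf("Geo table must have columns %s", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(df$kind), c("ip24", "zip3"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown geo table kind(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      ip24 = setNames(df$region[df$kind == "ip24"], df$key[df$kind == "ip24"]),
      zip3 = setNames(df$region[df$kind == "zip3"], df$key[df$kind == "zip3"])
    ),
    class = "geo_table"
  )
}

#' Bundled synthetic geo table
#'
#' A fictional mapping of /24 IP prefixes and zip3 prefixes to US state codes,
#' shipped with the package so no live geolocation service is ever consulted.
#' The synthetic cohort generator draws valid respondents consistently with
#' this table and naive spam inconsistently with it.
#'
#' @return A `geo_table` object.
#' @export
default_geo_table <- function() {
  read_geo_table(system.file("extdata", "geo_regions_synthetic.csv",
                             package = "surveyguard", mustWork = TRUE))
}

ip24_prefix <- function(ip) {
  sub("^((\\d{1,3})\\.(\\d{1,3})\\.(\\d{1,3}))\\.\\d{1,3}$", "\\1", ip)
}

#' Resolve the region of an IP address or zip code
#'
#' @param geo A `geo_table`.
#' @param ip Dotted-quad IPv4 address(es); matched on the /24 prefix.
#' @param zip 5-digit zip code(s); matched on the first 3 digits.
#' @return Character vector of region codes; `"unknown"` when unresolvable.
#' @export
geo_region_ip <- function(geo, ip) {
  key <- ifelse(is.na(ip), NA_character_, ip24_prefix(ip))
  out <- unname(geo$ip24[key])
  ifelse(is.na(out), "unknown", out)
}

#' @rdname geo_region_ip
#' @export
geo_region_zip <- function(geo, zip) {
  key <- ifelse(is.na(zip) | !grepl("^\\d{5}$", zip), NA_character_, substr(zip, 1, 3))
  out <- unname(geo$zip3[key])
  ifelse(is.na(out), "unknown", out)
}

# ---- submissions ------------------------------------------------------------

submission_columns <- function() {
  c(
    "submission_id", "channel_id",
    "screener_age_ok", "screener_residence_ok", "screener_gbm_ok",
    "screener_treatment_ok", "prior_completion_denied", "consent_given",
    "start_timestamp", "end_timestamp", "duration_minutes",
    "ip_address", "email_address", "zip_code", "birth_date",
    "age_years", "age_at_diagnosis", "psa_at_diagnosis", "gleason_total",
    "treatment_history", "disclosure_to_provider", "rehab_recommendations",
    "discrimination_attributes", "cancer_status",
    "grid_responses", "verification_items", "text_responses",
    "completion_status", "ballot_box_cookie_present"
  )
}

required_columns <- function() {
  c("submission_id", "channel_id", "ip_address",
    "start_timestamp", "end_timestamp", "completion_status")
}

#' Read a submissions table
#'
#' Parses one survey attempt per row into the package's submission schema.
#' Malformed rows (unparseable timestamps, end before start, out-of-range
#' clinical values, bad zip codes) are quarantined — reported with row number
#' and the violated invariant, never silently dropped — so one bad row cannot
#' block a validation batch. Duration is recomputed from the timestamps
#' whenever both are present (single source of truth); a supplied duration
#' column is only used when a timestamp is missing.
#'
#' @param path CSV file, comma-separated, UTF-8, header row required. List
#'   fields use `|` separators (see [write_submissions()]).
#' @param mapping Optional named character vector mapping schema fields to
#'   source column names, e.g. `c(ip_address = "V4")`. Every required field
#'   must resolve to a column present in the file.
#' @param reject_path Optional CSV path for quarantined rows.
#' @return A tibble of submissions with list-columns for structured fields and
#'   an attribute `"rejects"` (tibble: row, submission_id, reason).
#' @export
read_submissions <- function(path, mapping = NULL, reject_path = NULL) {
  if (!file.exists(path)) abort(sprintf("Submissions file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  cols <- submission_columns()
  src <- setNames(cols, cols)
  if (!is.null(mapping)) {
    unknown <- setdiff(names(mapping), cols)
    if (length(unknown) > 0) {
      abort(sprintf("Mapping names unknown field(s): %s", paste(unknown, collapse = ", ")))
    }
    src[names(mapping)] <- mapping
  }
  missing_req <- required_columns()[!src[required_columns()] %in% names(raw)]
  if (length(missing_req) > 0) {
    abort(sprintf(
      "Missing required column(s) in %s: %s",
      path, paste(missing_req, collapse = ", ")
    ))
  }
  get_col <- function(field) {
    if (src[[field]] %in% names(raw)) raw[[src[[field]]]] else rep(NA_character_, nrow(raw))
  }
  df <- tibble(row = seq_len(nrow(raw)))
  for (f in cols) df[[f]] <- get_col(f)
  parse_submission_frame(df, reject_path = reject_path)
}

# Typed parsing + invariant checks over a character frame with a `row` column.
parse_submission_frame <- function(df, reject_path = NULL) {
  as_num <- function(x) suppressWarnings(as.numeric(x))
  as_int <- function(x) suppressWarnings(as.integer(x))
  as_lgl <- function(x) {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
    out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
    out
  }

  reasons <- rep(NA_character_, nrow(df))
  note <- function(bad, msg) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- msg
  }

  note(is.na(df$submission_id) | !nzchar(df$submission_id), "missing submission_id")
  note(!ts_is_valid(df$start_timestamp) & !is.na(df$start_timestamp),
       "unparseable start_timestamp")
  note(!ts_is_valid(df$end_timestamp) & !is.na(df$end_timestamp),
       "unparseable end_timestamp")
  note(is.na(df$start_timestamp) | is.na(df$end_timestamp),
       "missing start or end timestamp")

  ok_ts <- ts_is_valid(df$start_timestamp) & ts_is_valid(df$end_timestamp)
  elapsed <- rep(NA_real_, nrow(df))
  elapsed[ok_ts] <- (ts_epoch(df$end_timestamp[ok_ts]) -
                       ts_epoch(df$start_timestamp[ok_ts])) / 60
  note(ok_ts & elapsed < 0, "end_timestamp earlier than start_timestamp")

  gleason <- as_int(df$gleason_total)
  note(!is.na(gleason) & (gleason < 2 | gleason > 10), "gleason_total outside [2, 10]")
  psa <- as_num(df$psa_at_diagnosis)
  note(!is.na(psa) & psa < 0, "negative psa_at_diagnosis")
  note(!is.na(df$zip_code) & nzchar(df$zip_code) & !grepl("^\\d{5}$", df$zip_code),
       "zip_code is not 5 digits")

  dup <- duplicated(df$submission_id) & !is.na(df$submission_id)
  note(dup, "duplicate submission_id")

  rejects <- tibble(
    row = df$row[!is.na(reasons)],
    submission_id = df$submission_id[!is.na(reasons)],
    reason = reasons[!is.na(reasons)]
  )
  keep <- is.na(reasons)
  df <- df[keep, ]
  elapsed <- elapsed[keep]

  supplied <- as_num(df$duration_minutes)
  duration <- ifelse(!is.na(elapsed), elapsed, supplied)

  out <- tibble(
    submission_id = df$submission_id,
    channel_id = ifelse(is.na(df$channel_id), "A", df$channel_id),
    screener_age_ok = as_lgl(df$screener_age_ok),
    screener_residence_ok = as_lgl(df$screener_residence_ok),
    screener_gbm_ok = as_lgl(df$screener_gbm_ok),
    screener_treatment_ok = as_lgl(df$screener_treatment_ok),
    prior_completion_denied = as_lgl(df$prior_completion_denied),
    consent_given = as_lgl(df$consent_given),
    start_timestamp = df$start_timestamp,
    end_timestamp = df$end_timestamp,
    duration_minutes = duration,
    ip_address = df$ip_address,
    email_address = df$email_address,
    zip_code = df$zip_code,
    birth_date = df$birth_date,
    age_years = as_int(df$age_years),
    age_at_diagnosis = as_int(df$age_at_diagnosis),
    psa_at_diagnosis = as_num(df$psa_at_diagnosis),
    gleason_total = as_int(df$gleason_total),
    treatment_history = parse_pairs(df$treatment_history),
    disclosure_to_provider = as_lgl(df$disclosure_to_provider),
    rehab_recommendations = parse_codes(df$rehab_recommendations),
    discrimination_attributes = parse_codes(df$discrimination_attributes),
    cancer_status = ifelse(is.na(df$cancer_status) | !nzchar(df$cancer_status),
                           "missing", df$cancer_status),
    grid_responses = parse_grids(df$grid_responses),
    verification_items = parse_verification(df$verification_items),
    text_responses = parse_text(df$text_responses),
    completion_status = ifelse(is.na(df$completion_status), "partial",
                               df$completion_status),
    ballot_box_cookie_present = as_lgl(df$ballot_box_cookie_present)
  )
  if (!is.null(reject_path) && nrow(rejects) > 0) {
    readr::write_csv(rejects, reject_path, progress = FALSE)
  }
  attr(out, "rejects") <- rejects
  out
}

#' Write a submissions table
#'
#' Inverse of [read_submissions()]: list-columns are serialised with `|`
#' separators so that `read_submissions(write_submissions(x))` reproduces
#' every field bit-exactly.
#'
#' @param records Submissions tibble.
#' @param path Output CSV path.
#' @export
write_submissions <- function(records, path) {
  flat <- records
  flat$treatment_history <- ser_pairs(records$treatment_history)
  flat$rehab_recommendations <- ser_codes(records$rehab_recommendations)
  flat$discrimination_attributes <- ser_codes(records$discrimination_attributes)
  flat$grid_responses <- ser_grids(records$grid_responses)
  flat$verification_items <- ser_verification(records$verification_items)
  flat$text_responses <- ser_text(records$text_responses)
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

# ---- decision table ---------------------------------------------------------

#' Write a decision table
#'
#' One row per adjudicated submission; triggered rules are serialised as a
#' `|`-delimited reason-code list. Reading the file back with
#' [read_decision_table()] reproduces statuses and strike counts exactly.
#'
#' @param decisions Decision tibble from [run_protocol()] or [adjudicate()].
#' @param path Output CSV path.
#' @export
write_decision_table <- function(decisions, path) {
  flat <- tibble(
    submission_id = decisions$submission_id,
    status = decisions$status,
    strike_count = decisions$strike_count,
    reason_codes = ser_codes(decisions$reason_codes),
    evidence = vapply(decisions$strikes, function(s) {
      if (is.null(s) || nrow(s) == 0) "" else paste(s$evidence, collapse = "|")
    }, character(1)),
    config_id = decisions$config_id,
    end_timestamp = decisions$end_timestamp
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read a decision table written by [write_decision_table()]
#'
#' @param path CSV path.
#' @return Decision tibble (without the full strike evidence structure; reason
#'   codes, statuses and counts round-trip exactly).
#' @export
read_decision_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    submission_id = readr::col_character(),
    status = readr::col_character(),
    strike_count = readr::col_integer(),
    reason_codes = readr::col_character(),
    evidence = readr::col_character(),
    config_id = readr::col_character(),
    end_timestamp = readr::col_character()
  ), progress = FALSE)
  tibble(
    submission_id = df$submission_id,
    status = df$status,
    strike_count = df$strike_count,
    reason_codes = parse_codes(df$reason_codes),
    evidence = parse_codes(df$evidence),
    config_id = df$config_id,
    end_timestamp = df$end_timestamp
  )
}
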