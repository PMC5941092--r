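#' Registry of suspicion-indicator rules
#'
#' Every rule the protocol can fire, with its category (`dedup`, `metadata`,
#' `clinical`, `style`) and, for the per-record indicators, the classic
#' suspicious-survey characteristic it operationalises (`indicator`). The
#' per-record rules cover exactly the eight characteristics of the
#' Baker/Downes-Le Guin taxonomy: short completion times, all items selected
#' in a multiple response, bogus/low-probability answers, internal
#' inconsistencies, straight-lining in grids, high item nonresponse, failed
#' verification items, and gibberish or duplicated text. Dataset-level
#' deduplication signals carry `indicator = NA` (they are deduplication, not
#' response-style, evidence).
#'
#' @return A tibble with columns `rule_id`, `category`, `indicator`,
#'   `description`.
#' @export
#' @examples
#' unique(na.omit(rule_registry()$indicator))
rule_registry <- function() {
  tribble_like <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    tibble(rule_id = m[, 1], category = m[, 2],
           indicator = ifelse(m[, 3] == "", NA_character_, m[, 3]),
           description = m[, 4])
  }
  tribble_like(
    "duplicate_ip",        "dedup",    "",
    "IP address shared with another submission",
    "email_convention",    "dedup",    "",
    "email handle follows a shared host/signature convention",
    "temporal_adjacency",  "dedup",    "",
    "submission began within seconds of another submission's end",
    "odd_hour",            "dedup",    "",
    "completed in the early hours of the morning (local time)",
    "shared_anomaly",      "dedup",    "",
    "identical improbable value shared across submissions",

    "completion_time",     "metadata", "short_completion_time",
    "unusually short completion time versus the plausible interview length",
    "geo_mismatch",        "metadata", "internal_inconsistency",
    "IP-derived region does not match the zip-code region",

    "age_at_diagnosis",    "clinical", "low_probability_answer",
    "improbably young age at prostate-cancer diagnosis",
    "psa_implausible",     "clinical", "low_probability_answer",
    "PSA at diagnosis above the plausible maximum",
    "gleason_implausible", "clinical", "low_probability_answer",
    "Gleason total above the plausible maximum",
    "clinical_missing",    "clinical", "low_probability_answer",
    "all core clinical items 'forgotten' on a complete survey",
    "treatment_sequence",  "clinical", "internal_inconsistency",
    "clinically impossible ordering of treatments",
    "provider_mismatch",   "clinical", "internal_inconsistency",
    "treatment delivered by an incompatible provider type",
    "rehab_disclosure",    "clinical", "internal_inconsistency",
    "orientation-specific rehabilitation without provider disclosure",
    "discrimination_profile", "clinical", "low_probability_answer",
    "peripheral discrimination attributes without any core attribute",

    "straight_lining",     "style",    "straight_lining",
    "low differentiation across a grid's items",
    "nonresponse",         "style",    "item_nonresponse",
    "high fraction of missing items",
    "text_quality",        "style",    "gibberish_or_duplicated_text",
    "blank, gibberish, or duplicated free-text responses",
    "all_options",         "style",    "all_items_multiple_response",
    "every option selected in the multiple-response block",
    "verification_failure", "style",   "verification_item_failure",
    "instructed verification item answered incorrectly"
  )
}

# Accept either a plain named list or a one-row tibble (list-columns are
# unwrapped so that record$grid_responses is the named list itself).
as_record <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- lapply(record, function(col) if (is.list(col)) col[[1]] else col)
  }
  record
}

strike_row <- function(rule_id, category, evidence) {
  tibble(rule_id = rule_id, category = category, evidence = evidence)
}

empty_strikes <- function() {
  tibble(rule_id = character(0), category = character(0), evidence = character(0))
}

#' Speeding check for one submission
#'
#' Strikes when the completion duration is under the absolute floor
#' (`duration_min_minutes`, default 30), or — when `relative_speed_enabled` —
#' under `relative_speed_fraction` of the cohort median duration. The
#' boundary is strict: exactly 30 minutes does not strike.
#'
#' @param record One submission (a one-row tibble or named list).
#' @param cohort_median_minutes Median completion time of the batch, used
#'   only by the relative test.
#' @param config A `rule_config`.
#' @return Strike tibble with zero or one row.
#' @export
check_completion_time <- function(record, cohort_median_minutes = NA_real_,
                                  config = default_rule_config()) {
  record <- as_record(record)
  d <- record$duration_minutes
  if (is.null(d) || is.na(d)) return(empty_strikes())
  if (d < config$duration_min_minutes) {
    return(strike_row("completion_time", "metadata",
                      sprintf("duration %.1f min below the %.0f min floor",
                              d, config$duration_min_minutes)))
  }
  if (isTRUE(config$relative_speed_enabled) && !is.na(cohort_median_minutes) &&
      d < config$relative_speed_fraction * cohort_median_minutes) {
    return(strike_row("completion_time", "metadata",
                      sprintf("duration %.1f min below %.2f of the cohort median (%.1f min)",
                              d, config$relative_speed_fraction, cohort_median_minutes)))
  }
  empty_strikes()
}

#' IP-versus-zip geographic consistency check
#'
#' Resolves the region of the submission's /24 IP prefix and of its 3-digit
#' zip prefix through an offline lookup table; strikes only when both resolve
#' and disagree. An unresolvable side yields no strike (absence of evidence).
#'
#' @inheritParams check_completion_time
#' @param geo A `geo_table`.
#' @return Strike tibble with zero or one row.
#' @export
check_geo_consistency <- function(record, geo) {
  record <- as_record(record)
  r_ip <- geo_region_ip(geo, record$ip_address)
  r_zip <- geo_region_zip(geo, record$zip_code)
  if (r_ip != "unknown" && r_zip != "unknown" && r_ip != r_zip) {
    return(strike_row("geo_mismatch", "metadata",
                      sprintf("ip_address region %s != zip_code region %s", r_ip, r_zip)))
  }
  empty_strikes()
}

#' Clinical-plausibility checks for one submission
#'
#' Emits at most one strike per sub-rule: (a) diagnosis age under
#' `age_dx_min`; (b) PSA at diagnosis above `psa_max`; (c) Gleason total
#' above `gleason_max`; (d) all core clinical items missing ("forgotten") on
#' a complete survey; (e) any forbidden ordered treatment transition (one
#' strike regardless of how many); (f) a treatment delivered by an
#' incompatible provider type; (g) orientation-specific rehabilitation
#' recommended without disclosure to the provider; (h) discrimination
#' reported only on peripheral attributes with no core attribute. Sub-rules
#' skip silently when their fields are missing, except (d), whose subject is
#' the missingness itself.
#'
#' @inheritParams check_completion_time
#' @return Strike tibble with zero or more rows.
#' @export
evaluate_clinical_profile <- function(record, config = default_rule_config()) {
  record <- as_record(record)
  out <- list()
  add <- function(s) out[[length(out) + 1]] <<- s

  age_dx <- record$age_at_diagnosis
  if (!is.null(age_dx) && !is.na(age_dx) && age_dx < config$age_dx_min) {
    add(strike_row("age_at_diagnosis", "clinical",
                   sprintf("age_at_diagnosis %d below plausible minimum %d",
                           as.integer(age_dx), as.integer(config$age_dx_min))))
  }
  psa <- record$psa_at_diagnosis
  if (!is.null(psa) && !is.na(psa) && psa > config$psa_max) {
    add(strike_row("psa_implausible", "clinical",
                   sprintf("psa_at_diagnosis %.1f above plausible maximum %.0f",
                           psa, config$psa_max)))
  }
  gleason <- record$gleason_total
  if (!is.null(gleason) && !is.na(gleason) && gleason > config$gleason_max) {
    add(strike_row("gleason_implausible", "clinical",
                   sprintf("gleason_total %d above plausible maximum %d",
                           as.integer(gleason), as.integer(config$gleason_max))))
  }

  hist <- record$treatment_history
  n_treat <- if (is.data.frame(hist)) nrow(hist) else 0L

  core_missing <- (is.null(age_dx) || is.na(age_dx)) &&
    (is.null(psa) || is.na(psa)) && (is.null(gleason) || is.na(gleason))
  if (core_missing && identical(record$completion_status, "complete")) {
    add(strike_row("clinical_missing", "clinical",
                   "age_at_diagnosis, psa_at_diagnosis and gleason_total all missing on a complete survey"))
  }

  if (n_treat >= 2) {
    trans <- paste(hist$treatment[-n_treat], hist$treatment[-1], sep = ">")
    forb <- vapply(config$forbidden_transitions, paste, character(1), collapse = ">")
    hit <- trans[trans %in% forb]
    if (length(hit) > 0) {
      add(strike_row("treatment_sequence", "clinical",
                     sprintf("forbidden treatment transition(s): %s",
                             paste(hit, collapse = ", "))))
    }
  }
  if (n_treat >= 1) {
    bad <- character(0)
    for (i in seq_len(n_treat)) {
      tr <- hist$treatment[i]; pv <- hist$provider[i]
      if (is.na(tr) || is.na(pv) || pv == "none") next
      ok_set <- config$provider_compat[[tr]]
      if (!is.null(ok_set) && !(pv %in% ok_set)) bad <- c(bad, paste0(tr, " from ", pv))
    }
    if (length(bad) > 0) {
      add(strike_row("provider_mismatch", "clinical",
                     sprintf("incompatible treatment/provider pair(s): %s",
                             paste(bad, collapse = ", "))))
    }
  }

  rehab <- record$rehab_recommendations
  disclosed <- record$disclosure_to_provider
  if (length(rehab) > 0 && !is.null(disclosed) && isFALSE(disclosed)) {
    hit <- intersect(rehab, config$disclosure_required_rehab)
    if (length(hit) > 0) {
      add(strike_row("rehab_disclosure", "clinical",
                     sprintf("rehab code(s) %s require disclosure but disclosure_to_provider is FALSE",
                             paste(hit, collapse = ", "))))
    }
  }

  disc <- record$discrimination_attributes
  if (length(disc) > 0 &&
      length(intersect(disc, config$peripheral_discrimination)) > 0 &&
      length(intersect(disc, config$core_discrimination)) == 0) {
    add(strike_row("discrimination_profile", "clinical",
                   sprintf("peripheral discrimination (%s) without any core attribute",
                           paste(intersect(disc, config$peripheral_discrimination),
                                 collapse = ", "))))
  }

  if (length(out) == 0) empty_strikes() else dplyr::bind_rows(out)
}

#' Response-style checks for one submission
#'
#' At most one strike per sub-rule: (i) straight-lining — for any grid block
#' with at least `grid_min_items` items, the differentiation index (distinct
#' answered values / answered items) is at or below
#' `differentiation_threshold`; (ii) item nonresponse — the fraction of
#' missing grid items over all blocks exceeds `nonresponse_threshold`; (iii)
#' text quality — every free-text prompt blank, or any response whose
#' fraction of vowel-bearing tokens is below `gibberish_vowel_fraction`, or
#' one response duplicated verbatim across two or more prompts; (iv) every
#' option of the multiple-response block selected (vocabulary = peripheral
#' plus core discrimination codes); (v) any verification item answered with
#' other than its instructed value.
#'
#' @inheritParams check_completion_time
#' @return Strike tibble with zero or more rows.
#' @export
evaluate_response_style <- function(record, config = default_rule_config()) {
  record <- as_record(record)
  out <- list()
  add <- function(s) out[[length(out) + 1]] <<- s

  grids <- record$grid_responses
  if (length(grids) > 0) {
    worst <- NULL
    n_items <- 0L
    n_missing <- 0L
    for (nm in names(grids)) {
      v <- grids[[nm]]
      n_items <- n_items + length(v)
      n_missing <- n_missing + sum(is.na(v))
      answered <- v[!is.na(v)]
      if (length(v) >= config$grid_min_items && length(answered) > 0) {
        idx <- length(unique(answered)) / length(answered)
        if (idx <= config$differentiation_threshold &&
            (is.null(worst) || idx < worst$idx)) {
          worst <- list(block = nm, idx = idx)
        }
      }
    }
    if (!is.null(worst)) {
      add(strike_row("straight_lining", "style",
                     sprintf("grid %s differentiation index %.2f at or below %.2f",
                             worst$block, worst$idx, config$differentiation_threshold)))
    }
    if (n_items > 0 && n_missing / n_items > config$nonresponse_threshold) {
      add(strike_row("nonresponse", "style",
                     sprintf("%.0f%% of grid items missing (threshold %.0f%%)",
                             100 * n_missing / n_items,
                             100 * config$nonresponse_threshold)))
    }
  }

  texts <- record$text_responses
  if (length(texts) > 0) {
    vals <- trimws(unlist(texts, use.names = FALSE))
    nonblank <- vals[nzchar(vals)]
    reason <- NULL
    if (length(nonblank) == 0) {
      reason <- "all free-text prompts left blank"
    } else {
      for (t in nonblank) {
        tokens <- strsplit(t, "\\s+")[[1]]
        tokens <- tokens[nzchar(tokens)]
        if (length(tokens) > 0) {
          frac <- mean(grepl("[AEIOUaeiou]", tokens))
          if (frac < config$gibberish_vowel_fraction) {
            reason <- sprintf("gibberish text ('%s': %.0f%% vowel-bearing tokens)",
                              substr(t, 1, 40), 100 * frac)
            break
          }
        }
      }
      if (is.null(reason) && anyDuplicated(nonblank) > 0) {
        reason <- "identical response duplicated across prompts"
      }
    }
    if (!is.null(reason)) add(strike_row("text_quality", "style", reason))
  }

  disc <- record$discrimination_attributes
  vocab <- union(config$peripheral_discrimination, config$core_discrimination)
  if (length(vocab) > 0 && length(disc) > 0 && all(vocab %in% disc)) {
    add(strike_row("all_options", "style",
                   "every option of the multiple-response block selected"))
  }

  verif <- record$verification_items
  if (length(verif) > 0) {
    failed <- character(0)
    for (nm in names(verif)) {
      pair <- verif[[nm]]
      if (length(pair) == 2 && !any(is.na(pair)) && pair[1] != pair[2]) {
        failed <- c(failed, sprintf("%s (instructed %s, given %s)", nm, pair[1], pair[2]))
      }
    }
    if (length(failed) > 0) {
      add(strike_row("verification_failure", "style",
                     sprintf("verification item(s) failed: %s",
                             paste(failed, collapse = "; "))))
    }
  }

  if (length(out) == 0) empty_strikes() else dplyr::bind_rows(out)
}

# All per-record strikes for one submission row, honouring enabled_rules.
plausibility_strikes <- function(record, config, geo = NULL,
                                 cohort_median_minutes = NA_real_) {
  s <- dplyr::bind_rows(
    check_completion_time(record, cohort_median_minutes, config),
    if (!is.null(geo)) check_geo_consistency(record, geo) else empty_strikes(),
    evaluate_clinical_profile(record, config),
    evaluate_response_style(record, config)
  )
  s[s$rule_id %in% config$enabled_rules, , drop = FALSE]
}
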