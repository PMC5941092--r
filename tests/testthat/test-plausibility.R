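cfg <- default_rule_config()
geo <- default_geo_table()

test_that("speeding strikes below 30 minutes with a strict boundary", {
  expect_equal(nrow(check_completion_time(make_record(duration_minutes = 25), config = cfg)), 1)
  expect_equal(nrow(check_completion_time(make_record(duration_minutes = 50), config = cfg)), 0)
  expect_equal(nrow(check_completion_time(make_record(duration_minutes = 30), config = cfg)), 0)
  # missing duration: no strike
  expect_equal(nrow(check_completion_time(make_record(duration_minutes = NA_real_), config = cfg)), 0)
})

test_that("relative speeding fires against the cohort median when enabled", {
  rel <- default_rule_config(relative_speed_enabled = TRUE, duration_min_minutes = 0)
  expect_equal(nrow(check_completion_time(make_record(duration_minutes = 10), 50, rel)), 1)
  expect_equal(nrow(check_completion_time(make_record(duration_minutes = 20), 50, rel)), 0)
})

test_that("geo consistency strikes only when both regions resolve and differ", {
  # 10.1.x <-> AL, zip3 010..013 <-> AL; 10.5.x <-> CA
  agree <- make_record(ip_address = "10.1.0.5", zip_code = "01012")
  expect_equal(nrow(check_geo_consistency(agree, geo)), 0)
  clash <- make_record(ip_address = "10.5.0.5", zip_code = "01012")
  s <- check_geo_consistency(clash, geo)
  expect_equal(s$rule_id, "geo_mismatch")
  unresolved <- make_record(ip_address = "203.0.113.9", zip_code = "01012")
  expect_equal(nrow(check_geo_consistency(unresolved, geo)), 0)
})

test_that("clinical profile sub-rules fire independently and at most once each", {
  hot <- make_record(age_at_diagnosis = 28L, psa_at_diagnosis = 25,
                     gleason_total = 8L)
  s <- evaluate_clinical_profile(hot, cfg)
  expect_setequal(s$rule_id, c("age_at_diagnosis", "psa_implausible",
                               "gleason_implausible"))

  benign <- make_record(age_at_diagnosis = 63L, psa_at_diagnosis = 6.5,
                        gleason_total = 6L,
                        treatment_history = tibble::tibble(
                          treatment = c("active_surveillance", "prostatectomy"),
                          provider = c("urologist", "urologist")))
  expect_equal(nrow(evaluate_clinical_profile(benign, cfg)), 0)

  # implausible sequence: one strike regardless of how many bad transitions
  seq_rec <- make_record(treatment_history = tibble::tibble(
    treatment = c("prostatectomy", "watchful_waiting", "radiation", "diet"),
    provider = c("urologist", "urologist", "radiation_oncologist", "none")))
  s <- evaluate_clinical_profile(seq_rec, cfg)
  expect_equal(s$rule_id[s$rule_id == "treatment_sequence"], "treatment_sequence")
  expect_equal(sum(s$rule_id == "treatment_sequence"), 1)

  # radiation delivered by a urologist
  prov <- make_record(treatment_history = tibble::tibble(
    treatment = "radiation", provider = "urologist"))
  expect_equal(evaluate_clinical_profile(prov, cfg)$rule_id, "provider_mismatch")

  # orientation-specific rehab without disclosure
  rehab <- make_record(rehab_recommendations = c("dilator"),
                       disclosure_to_provider = FALSE)
  expect_equal(evaluate_clinical_profile(rehab, cfg)$rule_id, "rehab_disclosure")

  # peripheral-only discrimination profile
  disc <- make_record(discrimination_attributes = c("weight", "height", "appearance"))
  expect_equal(evaluate_clinical_profile(disc, cfg)$rule_id, "discrimination_profile")

  # forgotten clinical data on a complete survey
  amnesia <- make_record(age_at_diagnosis = NA_integer_,
                         psa_at_diagnosis = NA_real_, gleason_total = NA_integer_)
  expect_equal(evaluate_clinical_profile(amnesia, cfg)$rule_id, "clinical_missing")
  partial_amnesia <- make_record(age_at_diagnosis = NA_integer_,
                                 psa_at_diagnosis = NA_real_,
                                 gleason_total = NA_integer_,
                                 completion_status = "partial")
  expect_equal(nrow(evaluate_clinical_profile(partial_amnesia, cfg)), 0)
})

test_that("response-style sub-rules detect straight-lining, nonresponse, text and verification problems", {
  lined <- make_record(grid_responses = list(block = rep(3, 10)))
  s <- evaluate_response_style(lined, cfg)
  expect_equal(s$rule_id, "straight_lining")
  expect_match(s$evidence, "0.10")

  holes <- make_record(grid_responses = list(
    b1 = c(1, NA, NA, 4, NA, 2, 5, 3), b2 = c(NA, NA, 3, 1, 4, NA, 2, 5)))
  expect_true("nonresponse" %in% evaluate_response_style(holes, cfg)$rule_id)

  blank <- make_record(text_responses = list(t1 = "", t2 = ""))
  expect_equal(evaluate_response_style(blank, cfg)$rule_id, "text_quality")

  gibber <- make_record(text_responses = list(t1 = "sdfk qwrt zzzz",
                                              t2 = "A sensible sentence here"))
  expect_equal(evaluate_response_style(gibber, cfg)$rule_id, "text_quality")

  dup <- make_record(text_responses = list(t1 = "The same answer pasted",
                                           t2 = "The same answer pasted"))
  expect_equal(evaluate_response_style(dup, cfg)$rule_id, "text_quality")

  all_opts <- make_record(discrimination_attributes = c(
    "weight", "height", "appearance", "race", "sexual_orientation"))
  expect_true("all_options" %in% evaluate_response_style(all_opts, cfg)$rule_id)

  failed <- make_record(verification_items = list(v1 = c(2, 5)))
  expect_equal(evaluate_response_style(failed, cfg)$rule_id, "verification_failure")

  clean <- make_record()
  expect_equal(nrow(evaluate_response_style(clean, cfg)), 0)
})

test_that("the differentiation rule ignores short grids and uses answered items", {
  short <- make_record(grid_responses = list(block = rep(2, 4)))  # < grid_min_items
  expect_equal(nrow(evaluate_response_style(short, cfg)), 0)
})

test_that("rules are pure: same record and config give identical strikes", {
  rec <- make_record(duration_minutes = 12, psa_at_diagnosis = 31)
  a <- dplyr::bind_rows(check_completion_time(rec, config = cfg),
                        evaluate_clinical_profile(rec, cfg),
                        evaluate_response_style(rec, cfg))
  b <- dplyr::bind_rows(check_completion_time(rec, config = cfg),
                        evaluate_clinical_profile(rec, cfg),
                        evaluate_response_style(rec, cfg))
  expect_identical(a, b)
})

test_that("disabling a rule removes exactly that rule's strikes", {
  recs <- make_records(
    make_record("X1", duration_minutes = 10, psa_at_diagnosis = 30,
                gleason_total = 9L)
  )
  full <- run_protocol(recs, cfg, geo)
  no_speed <- run_protocol(
    recs, default_rule_config(enabled_rules = setdiff(rule_registry()$rule_id,
                                                      "completion_time")), geo)
  full_rules <- full$strikes[[1]]$rule_id
  rest_rules <- no_speed$strikes[[1]]$rule_id
  expect_setequal(setdiff(full_rules, rest_rules), "completion_time")
})

test_that("the registry's per-record indicators cover the eight classic characteristics", {
  reg <- rule_registry()
  expect_equal(anyDuplicated(reg$rule_id), 0)
  expect_setequal(unique(reg$category), c("dedup", "metadata", "clinical", "style"))
  expect_equal(length(unique(reg$indicator[!is.na(reg$indicator)])), 8)
})
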