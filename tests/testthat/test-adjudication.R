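cfg <- default_rule_config()
geo <- default_geo_table()

fake_strikes <- function(n) {
  if (n == 0) return(surveyguard:::empty_strikes())
  tibble::tibble(rule_id = sprintf("psa_implausible%d", seq_len(n)),
                 category = "clinical", evidence = sprintf("evidence %d", seq_len(n)))
}

test_that("k-strikes adjudication: invalid at k, review below, valid at zero, partial always invalid", {
  rec <- make_record("K1")
  expect_equal(adjudicate(rec, fake_strikes(3), cfg)$status, "invalid")
  expect_equal(adjudicate(rec, fake_strikes(1), cfg)$status, "review")
  expect_equal(adjudicate(rec, fake_strikes(2), cfg)$status, "review")
  expect_equal(adjudicate(rec, fake_strikes(0), cfg)$status, "valid")

  part <- make_record("K2", completion_status = "partial")
  d <- adjudicate(part, fake_strikes(0), cfg)
  expect_equal(d$status, "invalid")
  expect_true("incomplete" %in% d$reason_codes[[1]])
})

test_that("adding strikes never moves a status toward valid", {
  rec <- make_record("M1")
  rank <- c(valid = 1, review = 2, invalid = 3)
  prev <- 0
  for (n in 0:4) {
    cur <- rank[[adjudicate(rec, fake_strikes(n), cfg)$status]]
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("run_protocol with a single era equals mapping adjudicate over records", {
  recs <- dplyr::bind_rows(
    benign_batch(8),
    make_record("SPAM1", duration_minutes = 12, psa_at_diagnosis = 40,
                gleason_total = 9L, age_at_diagnosis = 22L)
  )
  batch <- run_protocol(recs, cfg, geo)
  ctx <- build_dedup_context(recs, cfg)
  ctx_strikes <- surveyguard:::dedup_strikes(ctx)
  med <- median(recs$duration_minutes)
  manual <- dplyr::bind_rows(lapply(seq_len(nrow(recs)), function(i) {
    rec <- recs[i, ]
    s <- dplyr::bind_rows(
      ctx_strikes[ctx_strikes$submission_id == recs$submission_id[i],
                  c("rule_id", "category", "evidence")],
      surveyguard:::plausibility_strikes(surveyguard:::as_record(rec), cfg, geo, med)
    )
    adjudicate(rec, s, cfg)
  }))
  expect_equal(batch, manual)
  expect_equal(batch$status[batch$submission_id == "SPAM1"], "invalid")
})

test_that("era assignment uses the end date; a rule change applies only inside its window", {
  era1 <- default_rule_config(config_id = "era1",
                              effective_window = c(NA, "2015-11-10"))
  era2 <- default_rule_config(config_id = "era2", duration_min_minutes = 35,
                              effective_window = c("2015-11-11", NA))
  mk32 <- function(id, day) {
    make_record(id, start_timestamp = sprintf("%sT13:00:00-06:00", day),
                end_timestamp = sprintf("%sT13:32:00-06:00", day))
  }
  recs <- make_records(mk32("OLD", "2015-11-05"), mk32("NEW", "2015-11-20"))
  dec <- run_protocol(recs, list(era1, era2), geo)
  expect_equal(dec$config_id, c("era1", "era2"))
  expect_false("completion_time" %in% dec$strikes[[1]]$rule_id)
  expect_true("completion_time" %in% dec$strikes[[2]]$rule_id)

  # a record outside every window is an error naming the record
  era1_only <- default_rule_config(effective_window = c(NA, "2015-11-10"))
  expect_error(run_protocol(recs, list(era1_only), geo), "NEW")

  # overlapping eras are rejected
  lap <- default_rule_config(config_id = "lap",
                             effective_window = c("2015-11-01", "2015-11-15"))
  expect_error(run_protocol(recs, list(era1, lap), geo), "overlap")
})

test_that("the retrospective pass applies one uniform config and is idempotent", {
  strict <- default_rule_config(config_id = "strict", duration_min_minutes = 55,
                                strike_threshold_k = 2,
                                effective_window = c(NA, "2015-11-30"))
  final <- default_rule_config(config_id = "final")
  # 50-minute benign records: struck for speed under the strict era only
  recs <- benign_batch(4)
  era <- run_protocol(recs, list(strict), geo)
  r1 <- retrospective_pass(recs, final, geo, era)
  expect_equal(r1$era_status, era$status)
  expect_true(all(r1$retrospective_status == "valid"))
  expect_true(all(r1$era_status == "review"))  # one speed strike, below k
  r2 <- retrospective_pass(recs, final, geo, era)
  expect_identical(r1, r2)
})

test_that("run_protocol on an empty batch yields an empty decision table", {
  dec <- run_protocol(benign_batch(3)[0, ], cfg, geo)
  expect_equal(nrow(dec), 0)
})

test_that("drift monitor alerts on rate jumps and stays quiet on constant rates", {
  mkdec <- function(id, day, rules) {
    strikes <- tibble::tibble(rule_id = rules, category = "clinical",
                              evidence = rules)
    tibble::tibble(submission_id = id, status = "review",
                   strike_count = length(rules), reason_codes = list(rules),
                   strikes = list(strikes), config_id = "default",
                   end_timestamp = sprintf("%sT02:00:00-06:00", day))
  }
  # window 1 (days 0-6): clinical + email both fire; window 2 (days 7-13):
  # clinical collapses, email persists
  w1 <- dplyr::bind_rows(lapply(1:10, function(i) {
    mkdec(sprintf("a%d", i), "2015-11-01", c("psa_implausible", "email_convention"))
  }))
  w2 <- dplyr::bind_rows(lapply(1:10, function(i) {
    mkdec(sprintf("b%d", i), "2015-11-09",
          if (i <= 2) c("psa_implausible", "email_convention") else "email_convention")
  }))
  rep <- monitor_drift(dplyr::bind_rows(w1, w2), cfg)
  expect_true("psa_implausible" %in% rep$alerts$rule_id)
  expect_false("email_convention" %in% rep$alerts$rule_id)
  a <- rep$alerts[rep$alerts$rule_id == "psa_implausible", ]
  expect_equal(a$previous_rate, 1.0)
  expect_equal(a$current_rate, 0.2)

  # constant rates -> no alerts
  flat <- monitor_drift(dplyr::bind_rows(w1, dplyr::bind_rows(lapply(1:10, function(i) {
    mkdec(sprintf("c%d", i), "2015-11-09", c("psa_implausible", "email_convention"))
  }))), cfg)
  expect_equal(nrow(flat$alerts), 0)

  # a single window -> empty report
  single <- monitor_drift(w1, cfg)
  expect_equal(nrow(single$alerts), 0)
  expect_equal(nrow(single$windows), 0)
})

test_that("review queue returns exactly the review-status rows", {
  recs <- dplyr::bind_rows(benign_batch(3),
                           make_record("ONE", duration_minutes = 10))
  dec <- run_protocol(recs, cfg, geo)
  q <- review_queue(dec)
  expect_equal(q$submission_id, "ONE")
  expect_true(all(q$strike_count >= 1 & q$strike_count < cfg$strike_threshold_k))
})
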