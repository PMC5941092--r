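cfg <- default_rule_config()

test_that("duplicate-IP grouping matches the brute-force all-pairs oracle", {
  two <- make_records(
    make_record("A", ip_address = "203.0.113.5"),
    make_record("B", ip_address = "203.0.113.5")
  )
  expect_equal(find_duplicate_ips(two, cfg), list(c("A", "B")))

  distinct <- benign_batch(6)
  expect_equal(find_duplicate_ips(distinct, cfg), list())

  five <- make_records(
    make_record("A", ip_address = "10.2.0.9"),
    make_record("B", ip_address = "10.3.0.1"),
    make_record("C", ip_address = "10.2.0.9"),
    make_record("D", ip_address = "10.4.0.7"),
    make_record("E", ip_address = "10.2.0.9")
  )
  got <- find_duplicate_ips(five, cfg)
  expect_equal(got, oracle_duplicate_ips(five))
  expect_equal(got, list(c("A", "C", "E")))
})

test_that("email convention clustering flags shared host/signature batches", {
  trio <- make_records(
    make_record("E1", email_address = "abc123@me.example"),
    make_record("E2", email_address = "qrs789@me.example"),
    make_record("E3", email_address = "xyz456@me.example")
  )
  expect_equal(email_signature("abc123@me.example"), "L3D3")
  expect_equal(score_email_convention(trio, cfg), c("E1", "E2", "E3"))

  # below the cluster minimum nothing is flagged
  expect_equal(score_email_convention(trio[1:2, ], cfg), character(0))

  # a personalised handle has a different signature and is never swept up
  four <- dplyr::bind_rows(trio, make_record("E4", email_address = "john.smith@gmail.example"))
  expect_equal(email_signature("john.smith@gmail.example"), "L4O1L5")
  expect_equal(score_email_convention(four, cfg), c("E1", "E2", "E3"))

  # same signature on a different host is a different cluster
  five <- dplyr::bind_rows(trio, make_record("E5", email_address = "foo111@other.example"))
  expect_equal(score_email_convention(five, cfg), c("E1", "E2", "E3"))
})

test_that("temporal adjacency flags pairs and propagates chains like the all-pairs oracle", {
  base <- "2015-11-03"
  mk <- function(id, s, e) {
    make_record(id, start_timestamp = sprintf("%sT%s-06:00", base, s),
                end_timestamp = sprintf("%sT%s-06:00", base, e))
  }
  pair <- make_records(mk("A", "10:00:00", "10:40:00"),
                       mk("B", "10:40:10", "11:10:00"))
  expect_equal(find_temporal_adjacency(pair, cfg), c("A", "B"))

  apart <- make_records(mk("A", "10:00:00", "10:40:00"),
                        mk("B", "11:40:00", "12:10:00"))
  expect_equal(find_temporal_adjacency(apart, cfg), character(0))

  chain <- make_records(mk("A", "01:00:00", "01:20:00"),
                        mk("B", "01:20:05", "01:40:00"),
                        mk("C", "01:40:05", "02:00:00"))
  got <- find_temporal_adjacency(chain, cfg)
  expect_equal(got, c("A", "B", "C"))
  expect_equal(got, oracle_adjacency(chain, cfg$adjacency_gap_seconds))

  # boundary: a gap of exactly the configured maximum still flags;
  # a zero gap (simultaneous end/start) does not
  edge <- make_records(mk("A", "10:00:00", "10:40:00"),
                       mk("B", "10:41:00", "11:00:00"),
                       mk("C", "12:00:00", "12:30:00"),
                       mk("D", "12:30:00", "13:00:00"))
  expect_equal(find_temporal_adjacency(edge, cfg), c("A", "B"))
})

test_that("odd-hour detection uses the local clock with a half-open window", {
  mk <- function(id, clock, offset = "-06:00") {
    make_record(id, start_timestamp = sprintf("2015-11-03T00:00:00%s", offset),
                end_timestamp = sprintf("2015-11-03T%s%s", clock, offset))
  }
  recs <- make_records(mk("night", "02:30:00"), mk("day", "14:00:00"),
                       mk("edge5", "05:00:00"), mk("mid", "00:00:00"))
  expect_equal(detect_odd_hour(recs, cfg), c("mid", "night"))

  # the same UTC instant in a different offset is judged by its own wall clock
  utc_night <- make_records(mk("east", "02:30:00", "-05:00"),
                            mk("west_same_instant", "23:30:00", "-08:00"))
  expect_equal(detect_odd_hour(utc_night, cfg), "east")
})

test_that("shared-anomaly grouping needs the configured minimum", {
  trio <- make_records(
    make_record("S1", birth_date = "1901-01-01"),
    make_record("S2", birth_date = "1901-01-01"),
    make_record("S3", birth_date = "1901-01-01"),
    make_record("S4", birth_date = "1950-06-15")
  )
  got <- detect_shared_anomaly(trio, "birth_date", cfg)
  expect_equal(got, list(c("S1", "S2", "S3")))
  expect_equal(got, oracle_shared_anomaly(trio, "birth_date", cfg$shared_anomaly_min))
  expect_equal(detect_shared_anomaly(trio[c(1, 2, 4), ], "birth_date", cfg), list())
  expect_equal(detect_shared_anomaly(benign_batch(5), "birth_date", cfg), list())
})

test_that("dedup signals are order-invariant and monotone on randomized batches", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    recs <- benign_batch(n)
    # inject some duplicate IPs, convention emails, and adjacency
    recs$ip_address[1:3] <- "10.9.0.1"
    recs$email_address[4:7] <- sprintf("%s%03d@bulk.example",
                                       c("aaa", "bbb", "ccc", "ddd"), 1:4)
    recs$start_timestamp[9] <- "2015-11-21T14:00:30-06:00"
    recs$end_timestamp[9] <- "2015-11-21T14:40:00-06:00"
    recs$end_timestamp[8] <- "2015-11-21T14:00:00-06:00"
    recs$start_timestamp[8] <- "2015-11-21T13:20:00-06:00"
    recs$duration_minutes[8:9] <- c(40, 39.5)

    perm <- recs[sample.int(n), ]
    expect_equal(find_duplicate_ips(perm, cfg), find_duplicate_ips(recs, cfg))
    expect_equal(score_email_convention(perm, cfg), score_email_convention(recs, cfg))
    expect_equal(find_temporal_adjacency(perm, cfg), find_temporal_adjacency(recs, cfg))
    expect_equal(detect_odd_hour(perm, cfg), detect_odd_hour(recs, cfg))

    # all signals equal their brute-force counterparts
    expect_equal(find_duplicate_ips(recs, cfg), oracle_duplicate_ips(recs))
    expect_equal(find_temporal_adjacency(recs, cfg),
                 oracle_adjacency(recs, cfg$adjacency_gap_seconds))

    # monotonicity: adding a record never removes an existing flag
    extra <- make_record("ZZZ", ip_address = "10.9.0.1")
    grown <- dplyr::bind_rows(recs, extra)
    expect_true(all(unlist(find_duplicate_ips(recs, cfg)) %in%
                      unlist(find_duplicate_ips(grown, cfg))))
    expect_true(all(score_email_convention(recs, cfg) %in%
                      score_email_convention(grown, cfg)))
    expect_true(all(find_temporal_adjacency(recs, cfg) %in%
                      find_temporal_adjacency(grown, cfg)))
  }
})
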