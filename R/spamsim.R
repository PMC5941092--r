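#' Define a synthetic cohort scenario
#'
#' Parameters of the synthetic-cohort generator. The defaults reproduce the
#' study conditions the toolkit is built around: an older male
#' prostate-cancer survivor cohort (mean age 63.42 y, SD 8.19 y, bounded to
#' 40-95), a 45-60 minute instrument, 69.4% reporting successful treatment,
#' a 72-day recruitment window opening 2015-10-21, and spam waves that
#' complete in 5-25 minutes and claim diagnosis ages of 18-35 years.
#'
#' @param n_valid Number of valid respondents.
#' @param waves List of spam waves, each `list(start_day =, n =, profile =
#'   "naive"|"evolved", channel_id =)`; `start_day` is an offset in days from
#'   the study start.
#' @param age_mean,age_sd Target mean and SD (years) of valid respondents'
#'   ages. The generator samples a truncated normal whose parent parameters
#'   are solved so the *truncated* distribution has exactly these moments.
#' @param age_bounds Lower/upper truncation bounds for age (years).
#' @param valid_duration_minutes Uniform range of valid completion times.
#' @param successfully_treated_fraction Fraction of valid respondents
#'   reporting their cancer successfully treated.
#' @param spam_duration_minutes Uniform range of spam completion times.
#' @param spam_age_dx_range Range of the (implausible) diagnosis ages naive
#'   spam claims.
#' @param evolved_signatures Metadata signatures evolved spam retains; at
#'   least 3 of `"email_convention"`, `"adjacency"`, `"odd_hour"`,
#'   `"geo_mismatch"`.
#' @param diversion_day Day offset for the dual-link diversion, or `NULL`.
#' @param study_start First study day (valid submissions spread from here).
#' @param study_days Length of the recruitment window in days.
#' @param channel_id Channel carrying valid submissions (default `"A"`).
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A `cohort_scenario` object.
#' @export
cohort_scenario <- function(n_valid,
                            waves = list(),
                            age_mean = 63.42,
                            age_sd = 8.19,
                            age_bounds = c(40, 95),
                            valid_duration_minutes = c(45, 60),
                            successfully_treated_fraction = 0.694,
                            spam_duration_minutes = c(5, 25),
                            spam_age_dx_range = c(18, 35),
                            evolved_signatures = c("email_convention",
                                                   "adjacency", "odd_hour"),
                            diversion_day = NULL,
                            study_start = "2015-10-21",
                            study_days = 72,
                            channel_id = "A",
                            seed = 1L) {
  if (n_valid < 0) abort("n_valid must be >= 0")
  if (successfully_treated_fraction < 0 || successfully_treated_fraction > 1) {
    abort("successfully_treated_fraction must lie in [0, 1]")
  }
  if (age_bounds[1] >= age_bounds[2]) abort("age_bounds must be ordered")
  allowed_sig <- c("email_convention", "adjacency", "odd_hour", "geo_mismatch")
  bad <- setdiff(evolved_signatures, allowed_sig)
  if (length(bad) > 0) {
    abort(sprintf("Unknown evolved signature(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(evolved_signatures) < 3) {
    abort("evolved_signatures must keep at least 3 metadata signatures")
  }
  for (w in waves) {
    if (is.null(w$n) || w$n < 0) abort("every wave needs n >= 0")
    if (!w$profile %in% c("naive", "evolved")) {
      abort("wave profile must be 'naive' or 'evolved'")
    }
    if (is.null(w$start_day)) abort("every wave needs a start_day offset")
  }
  structure(list(
    n_valid = as.integer(n_valid), waves = waves,
    age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
    valid_duration_minutes = valid_duration_minutes,
    successfully_treated_fraction = successfully_treated_fraction,
    spam_duration_minutes = spam_duration_minutes,
    spam_age_dx_range = spam_age_dx_range,
    evolved_signatures = evolved_signatures,
    diversion_day = diversion_day,
    study_start = as.Date(study_start), study_days = as.integer(study_days),
    channel_id = channel_id, seed = as.integer(seed)
  ), class = "cohort_scenario")
}

# Mean and SD of a normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  lam <- (dnorm(al) - dnorm(be)) / Z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z - lam^2)
  c(mean = m, sd = sqrt(v))
}

# Parent (mu, sigma) such that the [a, b]-truncated normal has the target
# mean and SD. Truncation shrinks the SD, so the parent sigma sits slightly
# above the target; solved numerically once per generator call.
truncnorm_match <- function(target_mean, target_sd, a, b) {
  obj <- function(p) {
    m <- truncnorm_moments(p[1], exp(p[2]), a, b)
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm <- function(n, mu, sigma, a, b) {
  u <- runif(n, pnorm((a - mu) / sigma), pnorm((b - mu) / sigma))
  mu + sigma * qnorm(u)
}

first_names <- c(
  "james", "robert", "john", "michael", "david", "william", "richard",
  "joseph", "thomas", "charles", "daniel", "matthew", "anthony", "mark",
  "donald", "steven", "paul", "andrew", "joshua", "kenneth", "kevin",
  "brian", "george", "timothy", "ronald", "edward", "jason", "jeffrey",
  "ryan", "jacob", "gary", "nicholas", "eric", "jonathan", "stephen",
  "larry", "justin", "scott", "brandon", "benjamin"
)
last_names <- c(
  "smith", "johnson", "williams", "brown", "jones", "garcia", "miller",
  "davis", "rodriguez", "martinez", "hernandez", "lopez", "gonzalez",
  "wilson", "anderson", "thomas", "taylor", "moore", "jackson", "martin",
  "lee", "perez", "thompson", "white", "harris", "sanchez", "clark",
  "ramirez", "lewis", "robinson", "walker", "young", "allen", "king",
  "wright", "scott", "torres", "nguyen", "hill", "flores"
)
email_hosts <- c(
  "gmail.example", "yahoo.example", "outlook.example", "aol.example",
  "comcast.example", "icloud.example", "att.example", "verizon.example",
  "hotmail.example", "earthlink.example"
)
text_templates <- c(
  "My surgeon explained the side effects clearly before treatment",
  "Recovery took longer than I expected but support groups helped",
  "I wish rehabilitation advice had been tailored to my situation",
  "The incontinence was the hardest part of the first year",
  "My partner came to every appointment which made a difference",
  "I would like more information about managing erectile changes",
  "Finding other survivors to talk with online was invaluable",
  "My oncologist never asked about my relationships or identity",
  "Pelvic floor exercises were recommended and they helped somewhat",
  "I still worry about recurrence at every checkup",
  "The hormone therapy affected my mood more than my body",
  "Counseling after diagnosis helped me cope with the uncertainty",
  "I had to ask directly before anyone discussed sexual recovery",
  "Support from my church community carried me through treatment",
  "The decision between surgery and radiation was agonizing"
)

random_letters <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Shared skeleton of a generated submission frame.
new_submission_frame <- function(n) {
  tibble(
    submission_id = character(n), channel_id = character(n),
    screener_age_ok = rep(TRUE, n), screener_residence_ok = rep(TRUE, n),
    screener_gbm_ok = rep(TRUE, n), screener_treatment_ok = rep(TRUE, n),
    prior_completion_denied = rep(TRUE, n), consent_given = rep(TRUE, n),
    start_timestamp = character(n), end_timestamp = character(n),
    duration_minutes = numeric(n), ip_address = character(n),
    email_address = character(n), zip_code = character(n),
    birth_date = character(n), age_years = integer(n),
    age_at_diagnosis = integer(n), psa_at_diagnosis = numeric(n),
    gleason_total = integer(n),
    treatment_history = vector("list", n),
    disclosure_to_provider = rep(TRUE, n),
    rehab_recommendations = vector("list", n),
    discrimination_attributes = vector("list", n),
    cancer_status = character(n),
    grid_responses = vector("list", n),
    verification_items = vector("list", n),
    text_responses = vector("list", n),
    completion_status = rep("complete", n),
    ballot_box_cookie_present = rep(FALSE, n)
  )
}

gen_valid_block <- function(n, sc, ids) {
  df <- new_submission_frame(n)
  df$submission_id <- ids
  df$channel_id <- rep(sc$channel_id, n)

  state <- sample.int(50, n, replace = TRUE)
  slot <- sample(0:3, n, replace = TRUE)
  # distinct IPs: per /24 prefix a running counter assigns the host octet
  grp <- paste(state, slot)
  octet <- (stats::ave(seq_len(n), grp, FUN = seq_along) - 1L) %% 254L + 1L
  df$ip_address <- sprintf("10.%d.%d.%d", state, slot, octet)
  zip3 <- state * 10 + sample(0:3, n, replace = TRUE)
  df$zip_code <- sprintf("%03d%02d", zip3, sample(0:99, n, replace = TRUE))

  fit <- truncnorm_match(sc$age_mean, sc$age_sd, sc$age_bounds[1], sc$age_bounds[2])
  age <- rtruncnorm(n, fit$mu, fit$sigma, sc$age_bounds[1], sc$age_bounds[2])
  df$age_years <- as.integer(round(age))
  df$birth_date <- sprintf("%04d-%02d-%02d", 2015L - df$age_years,
                           sample(1:12, n, TRUE), sample(1:28, n, TRUE))
  df$age_at_diagnosis <- pmax(40L, df$age_years - sample(0:9, n, TRUE))
  df$psa_at_diagnosis <- round(runif(n, 0.5, 15), 1)
  df$gleason_total <- sample(3:6, n, replace = TRUE)

  r <- runif(n)
  f <- sc$successfully_treated_fraction
  df$cancer_status <- ifelse(r < f, "successfully_treated",
                             ifelse(r < f + (1 - f) / 2, "in_treatment", "progressed"))

  histories <- list(
    tibble(treatment = "prostatectomy", provider = "urologist"),
    tibble(treatment = "radiation", provider = "radiation_oncologist"),
    tibble(treatment = c("active_surveillance", "prostatectomy"),
           provider = c("urologist", "urologist")),
    tibble(treatment = c("active_surveillance", "radiation"),
           provider = c("urologist", "radiation_oncologist")),
    tibble(treatment = c("radiation", "hormone"),
           provider = c("radiation_oncologist", "oncologist")),
    tibble(treatment = c("prostatectomy", "radiation"),
           provider = c("urologist", "radiation_oncologist"))
  )
  df$treatment_history <- histories[sample.int(length(histories), n, TRUE)]

  df$disclosure_to_provider <- runif(n) < 0.8
  rehab_open <- c("pelvic_floor", "counseling", "ed_medication")
  rehab_disclosed <- c(rehab_open, "dilator")
  df$rehab_recommendations <- lapply(seq_len(n), function(i) {
    pool <- if (df$disclosure_to_provider[i]) rehab_disclosed else rehab_open
    sample(pool, sample(0:2, 1))
  })
  disc_r <- runif(n)
  df$discrimination_attributes <- lapply(seq_len(n), function(i) {
    if (disc_r[i] < 0.7) character(0)
    else if (disc_r[i] < 0.9) sample(c("race", "sexual_orientation"), 1)
    else c("sexual_orientation", sample(c("weight", "height"), 1))
  })

  # Personalised handles must spread over many (host, run-length signature)
  # keys, as real mailboxes do: several name shapes crossed with a digit
  # suffix of variable length (0-4 digits). Keeps accidental convention
  # clusters (3+ records on one key) rare at batch scale.
  pattern <- sample.int(5, n, replace = TRUE)
  fn <- sample(first_names, n, replace = TRUE)
  ln <- sample(last_names, n, replace = TRUE)
  mi <- sample(letters, n, replace = TRUE)
  dlen <- sample(0:4, n, replace = TRUE)
  digs <- vapply(seq_len(n), function(i) {
    if (dlen[i] == 0) "" else
      paste(sample(0:9, dlen[i], replace = TRUE), collapse = "")
  }, character(1))
  handle <- c(
    paste0(fn, ".", ln), paste0(substr(fn, 1, 1), ".", ln),
    paste0(fn, ".", mi, ".", ln), paste0(ln, ".", fn), fn
  )[seq_len(n) + (pattern - 1L) * n]
  df$email_address <- paste0(handle, digs, "@", sample(email_hosts, n, TRUE))

  g1 <- matrix(sample(1:5, n * 8, TRUE), nrow = n)
  g2 <- matrix(sample(1:5, n * 8, TRUE), nrow = n)
  df$grid_responses <- lapply(seq_len(n), function(i) {
    list(sexual_function = g1[i, ], mental_health = g2[i, ])
  })
  instructed <- sample(1:5, n, replace = TRUE)
  df$verification_items <- lapply(seq_len(n), function(i) {
    list(v1 = c(instructed[i], instructed[i]))
  })
  t_idx <- t(vapply(seq_len(n), function(i) sample.int(length(text_templates), 2),
                    integer(2)))
  df$text_responses <- lapply(seq_len(n), function(i) {
    list(t1 = text_templates[t_idx[i, 1]], t2 = text_templates[t_idx[i, 2]])
  })

  day <- sample.int(sc$study_days, n, replace = TRUE) - 1L
  end_sec <- round(runif(n, 8 * 3600, 22 * 3600))
  dur_sec <- round(runif(n, sc$valid_duration_minutes[1] * 60,
                         sc$valid_duration_minutes[2] * 60))
  offset <- -5L - (state %% 4L)
  df$end_timestamp <- iso_ts(sc$study_start + day, end_sec, offset)
  df$start_timestamp <- iso_ts(sc$study_start + day, end_sec - dur_sec, offset)
  df$duration_minutes <- dur_sec / 60

  df
}

# Chained night-time bursts: chunks of up to `per_chunk` submissions per
# day, each starting a handful of seconds after the previous one ends.
chain_times <- function(n, start_date, start_day, dur_sec, first_sec,
                        gap_range = c(5, 50), per_chunk = 10L, offset = -5L) {
  end_sec <- numeric(n)
  start_sec <- numeric(n)
  day <- start_day + (seq_len(n) - 1L) %/% per_chunk
  pos <- (seq_len(n) - 1L) %% per_chunk
  for (i in seq_len(n)) {
    if (pos[i] == 0) {
      start_sec[i] <- first_sec + round(runif(1, 0, 300))
    } else {
      start_sec[i] <- end_sec[i - 1] + sample(gap_range[1]:gap_range[2], 1)
    }
    end_sec[i] <- start_sec[i] + dur_sec[i]
  }
  list(
    start = iso_ts(start_date + day, start_sec, offset),
    end = iso_ts(start_date + day, end_sec, offset)
  )
}

gen_naive_wave <- function(wave, sc, ids) {
  n <- wave$n
  df <- new_submission_frame(n)
  df$submission_id <- ids
  df$channel_id <- rep(wave$channel_id %||% sc$channel_id, n)

  state <- sample.int(50, 1)                     # one source region
  zip_state <- state %% 50L + 1L                 # never equal to state
  df$ip_address <- sprintf("10.%d.0.%d", state, 200L + (seq_len(n) - 1L) %/% 5L)
  df$zip_code <- sprintf("%03d%02d", zip_state * 10 + sample(0:3, n, TRUE),
                         sample(0:99, n, TRUE))
  df$email_address <- paste0(random_letters(n, 3),
                             sprintf("%03d", sample(0:999, n, TRUE)),
                             "@qmail.example")
  df$birth_date <- rep("1901-01-01", n)
  df$age_years <- sample(45:70, n, replace = TRUE)

  implausible <- runif(n) < 0.5
  df$age_at_diagnosis <- ifelse(implausible,
                                sample(sc$spam_age_dx_range[1]:sc$spam_age_dx_range[2],
                                       n, TRUE), NA_integer_)
  df$psa_at_diagnosis <- ifelse(implausible, round(runif(n, 21, 45), 1), NA_real_)
  df$gleason_total <- ifelse(implausible, sample(7:10, n, TRUE), NA_integer_)

  bad_history <- tibble(
    treatment = c("prostatectomy", "watchful_waiting", "radiation", "diet"),
    provider = c("urologist", "urologist", "urologist", "none")
  )
  df$treatment_history <- rep(list(bad_history), n)
  df$disclosure_to_provider <- rep(FALSE, n)
  df$rehab_recommendations <- rep(list(c("dilator", "dildo", "butt_plug")), n)
  df$discrimination_attributes <- rep(list(c("weight", "height", "appearance")), n)
  df$cancer_status <- rep("successfully_treated", n)

  line <- sample(1:5, n, replace = TRUE)
  df$grid_responses <- lapply(seq_len(n), function(i) {
    list(sexual_function = rep(line[i], 8), mental_health = rep(line[i], 8))
  })
  instructed <- sample(1:5, n, replace = TRUE)
  df$verification_items <- lapply(seq_len(n), function(i) {
    list(v1 = c(instructed[i], instructed[i] %% 5 + 1))
  })
  df$text_responses <- rep(list(list(t1 = "", t2 = "")), n)

  dur_sec <- round(runif(n, sc$spam_duration_minutes[1] * 60,
                         sc$spam_duration_minutes[2] * 60))
  tm <- chain_times(n, sc$study_start, wave$start_day, dur_sec,
                    first_sec = 5 * 60)        # bursts open shortly after midnight
  df$start_timestamp <- tm$start
  df$end_timestamp <- tm$end
  df$duration_minutes <- dur_sec / 60
  df
}

gen_evolved_wave <- function(wave, sc, ids) {
  n <- wave$n
  df <- gen_valid_block(n, sc, ids)              # plausible everything
  df$channel_id <- rep(wave$channel_id %||% sc$channel_id, n)
  sig <- sc$evolved_signatures

  dur_sec <- round(runif(n, sc$spam_duration_minutes[1] * 60,
                         sc$spam_duration_minutes[2] * 60))
  first_sec <- if ("odd_hour" %in% sig) 10 * 60 else 10 * 3600
  if ("adjacency" %in% sig) {
    tm <- chain_times(n, sc$study_start, wave$start_day, dur_sec, first_sec)
    df$start_timestamp <- tm$start
    df$end_timestamp <- tm$end
  } else {
    day <- wave$start_day + (seq_len(n) - 1L) %/% 10L
    end_sec <- first_sec + round(runif(n, 0, 4 * 3600))
    df$end_timestamp <- iso_ts(sc$study_start + day, end_sec, -5L)
    df$start_timestamp <- iso_ts(sc$study_start + day, end_sec - dur_sec, -5L)
  }
  df$duration_minutes <- dur_sec / 60

  if ("email_convention" %in% sig) {
    df$email_address <- paste0(random_letters(n, 4),
                               sprintf("%02d", sample(0:99, n, TRUE)),
                               "@mailhub.example")
  }
  # evolved spam arrives on fresh, non-duplicate IPs: host octets 150-249,
  # a range the valid-record counters never reach at screening scale
  state <- sample.int(50, n, replace = TRUE)
  df$ip_address <- sprintf("10.%d.%d.%d", state, sample(0:3, n, TRUE),
                           sample(150:249, n, TRUE))
  zip_state <- if ("geo_mismatch" %in% sig) state %% 50L + 1L else state
  df$zip_code <- sprintf("%03d%02d", zip_state * 10 + sample(0:3, n, TRUE),
                         sample(0:99, n, TRUE))
  df
}

#' Generate a labelled synthetic cohort
#'
#' Produces valid respondents and the scenario's spam waves with ground-truth
#' labels. Valid records draw demographics from the scenario's truncated
#' normal age model, carry distinct IPs consistent with their zip regions in
#' the bundled synthetic geo table, personalised email handles, daytime
#' completion in 45-60 minutes, and varied complete responses. Naive spam is
#' blatant — short durations, diagnosis ages of 18-35 or "forgotten"
#' clinical data, PSA/Gleason outside plausible range, convention emails on
#' one host, blank text, straight-lined grids, failed verification items,
#' chained night-time starts and mismatched IP/zip — and accrues at least
#' three strikes by construction. Evolved spam draws its clinical profile
#' from the valid distributions but retains the scenario's metadata
#' signatures (and remains fast).
#'
#' Random streams are split per block (valid cohort first, then each wave
#' under its own derived seed), so adding a wave never perturbs the valid
#' records generated at a fixed seed.
#'
#' @param scenario A `cohort_scenario`.
#' @param seed Optional integer overriding `scenario$seed`.
#' @return A list of class `synthetic_cohort`: `records` (submissions
#'   tibble) and `labels` (tibble `submission_id`, `label` in
#'   `valid`/`naive`/`evolved`, `channel_id`).
#' @export
#' @examples
#' sc <- cohort_scenario(n_valid = 20,
#'                       waves = list(list(start_day = 2, n = 10,
#'                                         profile = "naive", channel_id = "A")))
#' cohort <- generate_cohort(sc, seed = 7)
#' table(cohort$labels$label)
generate_cohort <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  seed <- as.integer(seed %||% scenario$seed)
  blocks <- list()
  labels <- list()

  set.seed(seed)
  if (scenario$n_valid > 0) {
    ids <- sprintf("V%06d", seq_len(scenario$n_valid))
    blk <- gen_valid_block(scenario$n_valid, scenario, ids)
    blocks[[length(blocks) + 1]] <- blk
    labels[[length(labels) + 1]] <- tibble(
      submission_id = ids, label = "valid", channel_id = blk$channel_id
    )
  }
  for (w in seq_along(scenario$waves)) {
    wave <- scenario$waves[[w]]
    if (wave$n == 0) next
    set.seed((seed + 104729L * w) %% .Machine$integer.max)
    ids <- sprintf("W%d_%05d", w, seq_len(wave$n))
    blk <- if (wave$profile == "naive") {
      gen_naive_wave(wave, scenario, ids)
    } else {
      gen_evolved_wave(wave, scenario, ids)
    }
    blocks[[length(blocks) + 1]] <- blk
    labels[[length(labels) + 1]] <- tibble(
      submission_id = ids, label = wave$profile, channel_id = blk$channel_id
    )
  }
  records <- if (length(blocks) == 0) new_submission_frame(0) else dplyr::bind_rows(blocks)
  labels <- if (length(labels) == 0) {
    tibble(submission_id = character(0), label = character(0), channel_id = character(0))
  } else {
    dplyr::bind_rows(labels)
  }
  structure(list(records = records, labels = labels, scenario = scenario,
                 seed = seed), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$records), "records\n")
  print(table(x$labels$label))
  invisible(x)
}

#' Dual-link diversion scenario
#'
#' Emulates keeping a compromised survey link open to absorb spam while
#' routing newly recruited genuine respondents to a restricted copy: before
#' `diversion_day` all traffic arrives on channel A; from `diversion_day`
#' onward every newly generated valid record routes to channel B while all
#' spam stays on channel A. The restricted channel therefore carries zero
#' spam-labelled records.
#'
#' @param scenario A `cohort_scenario`.
#' @param diversion_day Day offset (from study start) when the restricted
#'   link opens; defaults to `scenario$diversion_day`.
#' @param seed Optional integer overriding `scenario$seed`.
#' @return List with `channel_a` and `channel_b` (submissions tibbles) and
#'   `labels` (with updated `channel_id`).
#' @export
make_dual_link_scenario <- function(scenario, diversion_day = NULL, seed = NULL) {
  diversion_day <- diversion_day %||% scenario$diversion_day
  if (is.null(diversion_day)) abort("diversion_day must be set")
  cohort <- generate_cohort(scenario, seed)
  rec <- cohort$records
  lab <- cohort$labels
  day <- as.numeric(ts_local_date(rec$end_timestamp) - scenario$study_start)
  to_b <- lab$label == "valid" & day >= diversion_day
  rec$channel_id[to_b] <- "B"
  lab$channel_id <- rec$channel_id
  list(
    channel_a = rec[rec$channel_id != "B", , drop = FALSE],
    channel_b = rec[rec$channel_id == "B", , drop = FALSE],
    labels = lab
  )
}
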