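#' @importFrom rlang %||% abort .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median optim pnorm qnorm dnorm runif rnorm sd setNames ave
#' @importFrom utils head tail
NULL

# Half-up decimal rounding (base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

TS_RE <- "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}[+-]\\d{2}:\\d{2}$"

ts_is_valid <- function(x) {
  !is.na(x) & grepl(TS_RE, x)
}

# Local wall-clock components are the literal characters of the stamp;
# the trailing offset converts to an absolute (UTC) instant.
ts_offset_seconds <- function(x) {
  sgn <- ifelse(substr(x, 20, 20) == "-", -1, 1)
  hh <- as.integer(substr(x, 21, 22))
  mm <- as.integer(substr(x, 24, 25))
  sgn * (hh * 3600 + mm * 60)
}

ts_epoch <- function(x) {
  local <- as.POSIXct(substr(x, 1, 19), format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  as.numeric(local) - ts_offset_seconds(x)
}

# Minutes past local midnight of the wall-clock time as written.
ts_local_minutes <- function(x) {
  as.integer(substr(x, 12, 13)) * 60 + as.integer(substr(x, 15, 16)) +
    as.integer(substr(x, 18, 19)) / 60
}

ts_local_date <- function(x) {
  as.Date(substr(x, 1, 10))
}

# Build an ISO-8601 stamp from a local date, seconds past local midnight,
# and a whole-hour UTC offset. Seconds >= 86400 roll the date forward.
iso_ts <- function(date, local_seconds, offset_hours) {
  date <- as.Date(date) + local_seconds %/% 86400
  s <- round(local_seconds %% 86400)
  sprintf(
    "%sT%02d:%02d:%02d%s%02d:00",
    format(date, "%Y-%m-%d"), s %/% 3600, (s %% 3600) %/% 60, s %% 60,
    ifelse(offset_hours < 0, "-", "+"), abs(offset_hours)
  )
}

parse_clock <- function(x) {
  # "HH:MM" -> minutes past midnight
  as.integer(substr(x, 1, 2)) * 60 + as.integer(substr(x, 4, 5))
}

# ---- pipe-delimited serialisers (CSV round-trip format) ---------------------
# Lists use "|" between elements; key/value entries use "=", pairs use ":".

ser_codes <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

parse_codes <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, "|", fixed = TRUE)[[1]]
  })
}

ser_pairs <- function(x) {
  # list of two-column data frames (treatment, provider)
  vapply(x, function(df) {
    if (is.null(df) || nrow(df) == 0) return("")
    paste(paste0(df[[1]], ":", df[[2]]), collapse = "|")
  }, character(1))
}

parse_pairs <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) {
      return(tibble(treatment = character(0), provider = character(0)))
    }
    parts <- strsplit(strsplit(v, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble(
      treatment = vapply(parts, `[`, character(1), 1),
      provider  = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                         character(1))
    )
  })
}

ser_grids <- function(x) {
  # named list of numeric vectors per record
  vapply(x, function(g) {
    if (is.null(g) || length(g) == 0) return("")
    paste(vapply(names(g), function(nm) {
      paste0(nm, "=", paste(g[[nm]], collapse = ";"))
    }, character(1)), collapse = "|")
  }, character(1))
}

parse_grids <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) return(list())
    entries <- strsplit(v, "|", fixed = TRUE)[[1]]
    out <- lapply(entries, function(e) {
      kv <- strsplit(e, "=", fixed = TRUE)[[1]]
      suppressWarnings(as.numeric(strsplit(kv[2], ";", fixed = TRUE)[[1]]))
    })
    names(out) <- vapply(strsplit(entries, "=", fixed = TRUE), `[`, character(1), 1)
    out
  })
}

ser_verification <- function(x) {
  # named list: item id -> c(instructed, given)
  vapply(x, function(g) {
    if (is.null(g) || length(g) == 0) return("")
    paste(vapply(names(g), function(nm) {
      paste0(nm, "=", g[[nm]][1], ":", g[[nm]][2])
    }, character(1)), collapse = "|")
  }, character(1))
}

parse_verification <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) return(list())
    entries <- strsplit(v, "|", fixed = TRUE)[[1]]
    out <- lapply(entries, function(e) {
      kv <- strsplit(e, "=", fixed = TRUE)[[1]]
      suppressWarnings(as.numeric(strsplit(kv[2], ":", fixed = TRUE)[[1]]))
    })
    names(out) <- vapply(strsplit(entries, "=", fixed = TRUE), `[`, character(1), 1)
    out
  })
}

ser_text <- function(x) {
  # named list: prompt id -> string (strings must not contain "|" or "=")
  vapply(x, function(g) {
    if (is.null(g) || length(g) == 0) return("")
    paste(paste0(names(g), "=", unlist(g)), collapse = "|")
  }, character(1))
}

parse_text <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) return(list())
    entries <- strsplit(v, "|", fixed = TRUE)[[1]]
    pos <- regexpr("=", entries, fixed = TRUE)
    out <- as.list(ifelse(pos > 0, substring(entries, pos + 1), ""))
    names(out) <- ifelse(pos > 0, substring(entries, 1, pos - 1), entries)
    out
  })
}
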