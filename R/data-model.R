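# Domain types and file I/O: RR sessions, phone-day logs, self reports,
# feature tables, WAV audio. Readers validate invariants and refuse to
# coerce bad input; all event sequences come back sorted by timestamp.

#' Night RR-interval session
#'
#' One night of beat-to-beat (RR) intervals recorded by a chest belt, plus
#' the metadata needed to place it: subject and session start.
#'
#' @param subject_id subject identifier (single string).
#' @param start_time session start, ISO-8601 string (timezone designator
#'   recommended) or `POSIXct`.
#' @param rr_ms numeric vector of RR intervals in milliseconds; all positive,
#'   at least one.
#' @return object of class `rr_session` with fields `subject_id`,
#'   `start_time` (ISO string), `start_epoch` (numeric seconds) and `rr_ms`.
#' @export
rr_session <- function(subject_id, start_time, rr_ms) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stopf("subject_id must be a non-empty string")
  if (inherits(start_time, "POSIXct")) {
    start_time <- format(start_time, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
    start_time <- sub("\\+0000$", "Z", start_time)
  }
  start_epoch <- parse_iso8601(start_time)
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) < 1L) stopf("rr_ms must contain at least one interval")
  if (anyNA(rr_ms) || any(rr_ms <= 0))
    stopf("all RR intervals must be positive numbers")
  structure(list(subject_id = subject_id, start_time = start_time,
                 start_epoch = start_epoch, rr_ms = rr_ms),
            class = "rr_session")
}

#' @export
print.rr_session <- function(x, ...) {
  cat(sprintf("RR session: subject %s, start %s\n  %d intervals, %.2f h, mean RR %.1f ms\n",
              x$subject_id, x$start_time, length(x$rr_ms),
              sum(x$rr_ms) / 3.6e6, mean(x$rr_ms)))
  invisible(x)
}

#' Read a night RR session from a plain-text file
#'
#' The file holds one RR interval in milliseconds per line; lines beginning
#' with `#` are comments and skipped. Session metadata (subject, start time)
#' is supplied by the caller because the raw belt dump carries none.
#'
#' @param path path to the RR text file.
#' @param subject_id subject identifier.
#' @param start_time session start (ISO-8601 string or `POSIXct`).
#' @return an [rr_session()].
#' @export
read_rr_session <- function(path, subject_id, start_time) {
  if (!file.exists(path)) stopf("RR file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[idx])))
  if (anyNA(vals)) {
    bad <- idx[which(is.na(vals))[1]]
    stopf("cannot parse RR value at line %d of %s: '%s'", bad, path, lines[bad])
  }
  if (any(vals <= 0)) {
    bad <- idx[which(vals <= 0)[1]]
    stopf("non-positive RR interval at line %d of %s", bad, path)
  }
  rr_session(subject_id, start_time, vals)
}

#' Write a night RR session to a plain-text file
#'
#' One interval per line with a `#` metadata header; the header is ignored by
#' [read_rr_session()], so write-then-read is the identity on `rr_ms`.
#'
#' @param session an [rr_session()].
#' @param path output path.
#' @export
write_rr_session <- function(session, path) {
  stopifnot(inherits(session, "rr_session"))
  hdr <- c(sprintf("# subject: %s", session$subject_id),
           sprintf("# start: %s", session$start_time))
  writeLines(c(hdr, sprintf("%.10g", session$rr_ms)), path)
  invisible(path)
}

#' Named feature vector with a modality tag
#'
#' @param modality `"phone"` or `"hrv"` (or `"all"` for merged vectors).
#' @param values named numeric vector; missing features are `NA` (never
#'   silently zero).
#' @return object of class `feature_vector`.
#' @export
feature_vector <- function(modality, values) {
  modality <- match.arg(modality, c("phone", "hrv", "all"))
  if (is.list(values)) values <- unlist(values)
  values <- vapply(values, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                   numeric(1))
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stopf("all features must be named")
  if (anyDuplicated(names(values))) stopf("feature names must be unique")
  structure(values, modality = modality, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector: %s, %d features, %d missing>\n",
              attr(x, "modality"), length(x), sum(is.na(x))))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

# ---- phone-day log ---------------------------------------------------------

empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(cl) vector(cl, 0L)),
                stringsAsFactors = FALSE, col.names = names(cols))
}

sort_by_t <- function(df, col = ".t") {
  if (nrow(df) > 1L) df[order(df[[col]]), , drop = FALSE] else df
}

check_in_date <- function(ts, date, what) {
  if (length(ts) && any(iso_date(ts) != date))
    stopf("%s timestamp outside the log's date %s", what, date)
}

#' One subject-day of smartphone records
#'
#' Container for everything the phone logged during one civil day: call
#' events, calendar events, contact-count snapshots (today and the previous
#' day), battery samples, accelerometer windows, GPS samples and questionnaire
#' audio responses. Constructors validate the type invariants (bounds,
#' non-negativity, timestamps inside the stated date) and sort every event
#' list by timestamp.
#'
#' @param subject_id subject identifier.
#' @param date civil date `YYYY-MM-DD` of the log.
#' @param calls data.frame with `timestamp`, `direction`
#'   (`"incoming"`/`"outgoing"`), `duration_s`.
#' @param calendar data.frame with `start`, `end`, `note_size`.
#' @param contacts data.frame with `timestamp`, `n_contacts`,
#'   `n_phone_numbers`, `n_emails`; the earliest snapshot is treated as the
#'   previous day's reference.
#' @param battery data.frame with `timestamp`, `level` in \code{[0,1]},
#'   `charging` logical.
#' @param accel list of windows, each `list(timestamp =, samples =)` with
#'   `samples` an n x 3 matrix in units of g.
#' @param gps data.frame with `timestamp`, `lat`, `lon` (degrees).
#' @param audio list of responses, each `list(timestamp =, samples =,
#'   sample_rate =)` with samples in \code{[-1,1]}.
#' @return object of class `phone_day_log`.
#' @export
phone_day_log <- function(subject_id, date,
                          calls = NULL, calendar = NULL, contacts = NULL,
                          battery = NULL, accel = list(), gps = NULL,
                          audio = list()) {
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", date)) stopf("date must be YYYY-MM-DD")
  calls <- calls %||% empty_df(timestamp = "character", direction = "character",
                               duration_s = "numeric")
  calendar <- calendar %||% empty_df(start = "character", end = "character",
                                     note_size = "integer")
  contacts <- contacts %||% empty_df(timestamp = "character",
                                     n_contacts = "integer",
                                     n_phone_numbers = "integer",
                                     n_emails = "integer")
  battery <- battery %||% empty_df(timestamp = "character", level = "numeric",
                                   charging = "logical")
  gps <- gps %||% empty_df(timestamp = "character", lat = "numeric",
                           lon = "numeric")

  if (nrow(calls)) {
    if (!all(calls$direction %in% c("incoming", "outgoing")))
      stopf("call direction must be incoming or outgoing")
    if (any(calls$duration_s < 0)) stopf("call duration must be >= 0")
    check_in_date(calls$timestamp, date, "call")
    calls$.t <- parse_iso8601(calls$timestamp)
    calls <- sort_by_t(calls)
  } else calls$.t <- numeric(0)

  if (nrow(calendar)) {
    calendar$.t <- parse_iso8601(calendar$start)
    calendar$.t_end <- parse_iso8601(calendar$end)
    if (any(calendar$.t_end < calendar$.t)) stopf("calendar event ends before it starts")
    if (any(calendar$note_size < 0)) stopf("note_size must be >= 0")
    check_in_date(calendar$start, date, "calendar")
    calendar <- sort_by_t(calendar)
  } else { calendar$.t <- numeric(0); calendar$.t_end <- numeric(0) }

  if (nrow(contacts)) {
    cnt <- c(contacts$n_contacts, contacts$n_phone_numbers, contacts$n_emails)
    if (any(cnt < 0)) stopf("contact counts must be >= 0")
    contacts$.t <- parse_iso8601(contacts$timestamp)
    contacts <- sort_by_t(contacts)
  } else contacts$.t <- numeric(0)

  if (nrow(battery)) {
    if (any(battery$level < 0 | battery$level > 1))
      stopf("battery level must lie in [0,1]")
    check_in_date(battery$timestamp, date, "battery")
    battery$.t <- parse_iso8601(battery$timestamp)
    battery <- sort_by_t(battery)
  } else battery$.t <- numeric(0)

  accel <- lapply(accel, function(w) {
    s <- w$samples
    if (is.data.frame(s)) s <- as.matrix(s)
    if (!is.matrix(s)) s <- matrix(s, ncol = 3, byrow = TRUE)
    if (nrow(s) < 1L) stopf("accelerometer window must be non-empty")
    check_in_date(w$timestamp, date, "accelerometer")
    list(timestamp = w$timestamp, .t = parse_iso8601(w$timestamp), samples = s)
  })
  if (length(accel) > 1L)
    accel <- accel[order(vapply(accel, `[[`, numeric(1), ".t"))]

  if (nrow(gps)) {
    if (any(gps$lat < -90 | gps$lat > 90)) stopf("latitude outside [-90, 90]")
    if (any(gps$lon < -180 | gps$lon > 180)) stopf("longitude outside [-180, 180]")
    check_in_date(gps$timestamp, date, "GPS")
    gps$.t <- parse_iso8601(gps$timestamp)
    gps <- sort_by_t(gps)
  } else gps$.t <- numeric(0)

  audio <- lapply(audio, function(a) {
    if (is.null(a$sample_rate) || a$sample_rate <= 0)
      stopf("audio sample_rate must be positive")
    if (any(abs(a$samples) > 1 + 1e-9)) stopf("audio samples must lie in [-1,1]")
    check_in_date(a$timestamp, date, "audio")
    list(timestamp = a$timestamp, .t = parse_iso8601(a$timestamp),
         samples = as.numeric(a$samples), sample_rate = as.integer(a$sample_rate))
  })
  if (length(audio) > 1L)
    audio <- audio[order(vapply(audio, `[[`, numeric(1), ".t"))]

  structure(list(subject_id = subject_id, date = date, calls = calls,
                 calendar = calendar, contacts = contacts, battery = battery,
                 accel = accel, gps = gps, audio = audio),
            class = "phone_day_log")
}

#' @export
print.phone_day_log <- function(x, ...) {
  cat(sprintf(paste0("Phone-day log: subject %s, %s\n  %d calls, %d calendar events, ",
                     "%d contact snapshots, %d battery samples,\n  %d accel windows, ",
                     "%d GPS samples, %d audio responses\n"),
              x$subject_id, x$date, nrow(x$calls), nrow(x$calendar),
              nrow(x$contacts), nrow(x$battery), length(x$accel),
              nrow(x$gps), length(x$audio)))
  invisible(x)
}

#' Read a phone-day log from JSON
#'
#' The document has keys `subject_id`, `date`, `calls`, `calendar`,
#' `contacts`, `battery`, `accel`, `gps`, `audio`. `gps` may be either an
#' inline array of `{timestamp, lat, lon}` records or a string path
#' (relative to the JSON file) to a CSV with columns `timestamp,lat,lon`.
#' Audio entries are `{timestamp, wav}` with `wav` a path (relative to the
#' JSON file) to a PCM16 mono WAV file. Unknown top-level keys are ignored
#' with a warning; missing required keys raise an error.
#'
#' @param path path to the JSON document.
#' @return a [phone_day_log()].
#' @export
read_phone_day <- function(path) {
  if (!file.exists(path)) stopf("phone-day file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  req <- c("subject_id", "date")
  miss <- setdiff(req, names(doc))
  if (length(miss)) stopf("phone-day document missing key(s): %s",
                          paste(miss, collapse = ", "))
  known <- c(req, "calls", "calendar", "contacts", "battery", "accel", "gps",
             "audio")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    warning(sprintf("ignoring unknown phone-day key(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  base <- dirname(path)

  as_df <- function(x) {
    if (is.null(x) || (is.list(x) && length(x) == 0L)) return(NULL)
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  gps <- doc$gps
  if (is.character(gps) && length(gps) == 1L) {
    gps <- read_gps_csv(file.path(base, gps))
  } else gps <- as_df(gps)

  accel <- NULL
  if (!is.null(doc$accel) && length(doc$accel)) {
    ad <- doc$accel
    if (is.data.frame(ad)) {
      accel <- lapply(seq_len(nrow(ad)), function(i)
        list(timestamp = ad$timestamp[i],
             samples = matrix(unlist(ad$samples[[i]]), ncol = 3, byrow = TRUE)))
    } else {
      accel <- lapply(ad, function(w)
        list(timestamp = w$timestamp,
             samples = matrix(unlist(w$samples), ncol = 3, byrow = TRUE)))
    }
  }

  audio <- NULL
  if (!is.null(doc$audio) && length(doc$audio)) {
    au <- doc$audio
    entries <- if (is.data.frame(au)) {
      lapply(seq_len(nrow(au)), function(i)
        list(timestamp = au$timestamp[i], wav = au$wav[i]))
    } else au
    audio <- lapply(entries, function(a) {
      w <- read_wav(file.path(base, a$wav))
      list(timestamp = a$timestamp, samples = w$samples,
           sample_rate = w$sample_rate)
    })
  }

  phone_day_log(doc$subject_id, doc$date,
                calls = as_df(doc$calls), calendar = as_df(doc$calendar),
                contacts = as_df(doc$contacts), battery = as_df(doc$battery),
                accel = accel %||% list(), gps = gps,
                audio = audio %||% list())
}

#' Write a phone-day log to JSON (plus WAV sidecar files)
#'
#' Inverse of [read_phone_day()]: audio responses are written as PCM16 mono
#' WAV files next to the JSON document and referenced by relative path.
#'
#' @param log a [phone_day_log()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_phone_day <- function(log, path) {
  stopifnot(inherits(log, "phone_day_log"))
  base <- dirname(path)
  stem <- sub("\\.json$", "", basename(path))
  drop_t <- function(df) df[, setdiff(names(df), c(".t", ".t_end")), drop = FALSE]
  audio <- lapply(seq_along(log$audio), function(i) {
    a <- log$audio[[i]]
    wav <- sprintf("%s_audio%02d.wav", stem, i)
    write_wav(a$samples, a$sample_rate, file.path(base, wav))
    list(timestamp = a$timestamp, wav = wav)
  })
  accel <- lapply(log$accel, function(w)
    list(timestamp = w$timestamp,
         samples = lapply(seq_len(nrow(w$samples)),
                          function(i) as.numeric(w$samples[i, ]))))
  doc <- list(subject_id = log$subject_id, date = log$date,
              calls = drop_t(log$calls), calendar = drop_t(log$calendar),
              contacts = drop_t(log$contacts), battery = drop_t(log$battery),
              accel = accel, gps = drop_t(log$gps), audio = audio)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read GPS samples from CSV
#'
#' @param path CSV with columns `timestamp,lat,lon`.
#' @return data.frame of GPS samples sorted by timestamp.
#' @export
read_gps_csv <- function(path) {
  if (!file.exists(path)) stopf("GPS CSV not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "lat", "lon")
  if (!all(need %in% names(df)))
    stopf("GPS CSV must have columns timestamp,lat,lon")
  df[order(parse_iso8601(df$timestamp)), need, drop = FALSE]
}

# ---- WAV PCM16 mono --------------------------------------------------------

#' Read a PCM16 mono WAV file
#'
#' Minimal RIFF/WAVE reader for the 16-bit mono PCM files the questionnaire
#' app produces. Samples are rescaled to \code{[-1, 1]}.
#'
#' @param path WAV path.
#' @return `list(samples =, sample_rate =)`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stopf("WAV file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4))
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- rawToChar(readBin(con, "raw", 4))
  if (riff != "RIFF" || wave != "WAVE") stopf("not a RIFF/WAVE file: %s", path)
  sample_rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4L) break
    id <- rawToChar(id)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, size = 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(sample_rate) || is.null(samples))
    stopf("malformed WAV file: %s", path)
  if (!identical(channels, 1L) || !identical(bits, 16L))
    stopf("only PCM16 mono WAV is supported: %s", path)
  list(samples = samples / 32768, sample_rate = sample_rate)
}

#' Write a PCM16 mono WAV file
#'
#' @param samples numeric vector in \code{[-1, 1]}.
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @export
write_wav <- function(samples, sample_rate, path) {
  pcm <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")        # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")       # block, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# ---- self reports and feature tables --------------------------------------

#' Read self-reported daily stress scores
#'
#' @param path CSV with columns `subject_id,date,stress_score` and optional
#'   `rel_yesterday,rel_lastweek` (all scores in \code{[0,1]}; empty cells are
#'   missing).
#' @return data.frame of self reports.
#' @export
read_self_reports <- function(path) {
  if (!file.exists(path)) stopf("self-report file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "date", "stress_score")
  if (!all(need %in% names(df)))
    stopf("self-report CSV must have columns subject_id,date,stress_score")
  sc <- c(df$stress_score, df$rel_yesterday, df$rel_lastweek)
  sc <- sc[!is.na(sc)]
  if (any(sc < 0 | sc > 1)) stopf("stress scores must lie in [0,1]")
  df
}

#' Write a feature table to CSV
#'
#' Rows are `(subject_id, date, feature_vector, label)` tuples; all rows must
#' share one feature-name set. Missing values are written as empty fields
#' (never zero) and the numeric formatting preserves at least 12 significant
#' digits on a round trip.
#'
#' @param rows either a list of `list(subject_id =, date =, features =,
#'   label =)` entries with `features` a [feature_vector()], or a data.frame
#'   with columns `subject_id`, `date`, the features, and `stress_score`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    nm <- names(rows[[1]]$features)
    for (r in rows) {
      if (!identical(names(r$features), nm))
        stopf("all rows must share one feature-name set")
    }
    df <- data.frame(subject_id = vapply(rows, `[[`, character(1), "subject_id"),
                     date = vapply(rows, `[[`, character(1), "date"),
                     stringsAsFactors = FALSE)
    for (f in nm) df[[f]] <- vapply(rows, function(r) unname(r$features[[f]]),
                                    numeric(1))
    df$stress_score <- vapply(rows, function(r)
      if (is.null(r$label) || is.na(r$label)) NA_real_ else as.numeric(r$label),
      numeric(1))
  }
  out <- df
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) out[[cl]] <- fmt_num(out[[cl]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data.frame with `subject_id`, `date`, feature columns and
#'   `stress_score`; empty fields come back as `NA`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
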