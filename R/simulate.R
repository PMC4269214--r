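# Seeded synthetic-data generators: RR nights with known spectral content and
# ectopic positions, phone-day logs with known event rates, and full cohorts
# with a known logit dependence of the stress class on named features. They
# let every pipeline stage be scored against ground truth without any
# external data.

#' Default night-generation parameters
#'
#' A typical adult night: 6 h of sleep at mean RR 1000 ms with sinusoidal
#' LF (0.1 Hz) and HF (0.25 Hz) modulation of the beat series, mild Gaussian
#' beat noise and a 1\% ectopic rate.
#'
#' @return named list of parameters for [generate_rr_night()].
#' @export
night_params <- function() {
  list(duration_h = 6, mean_rr_ms = 1000,
       a_lf_ms = 30, f_lf_hz = 0.10,
       a_hf_ms = 20, f_hf_hz = 0.25,
       noise_sd_ms = 10, ectopic_rate = 0.01)
}

#' Generate one synthetic night of RR intervals
#'
#' The clean series is
#' \code{RR_k = mean + A_LF sin(2 pi f_LF t_k) + A_HF sin(2 pi f_HF t_k) + e_k}
#' with `t_k` the cumulative beat time (modulation rides on the beat-time
#' axis) and `e_k` Gaussian. Ectopic beats are then injected at the stated
#' rate as plus or minus 40\% spikes; their positions are returned so the
#' artifact filter can be scored exactly.
#'
#' @param params list as from [night_params()]; `duration_h` must lie in
#'   4–10 h, `mean_rr_ms` in 600–1200 ms, modulation frequencies inside the
#'   LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) bands.
#' @param seed integer seed.
#' @param subject_id,start_time session metadata.
#' @return `list(session =, spikes =, clean_rr =)`: the [rr_session()], the
#'   integer indices of injected ectopics, and the pre-injection series.
#' @export
generate_rr_night <- function(params = night_params(), seed = 1L,
                              subject_id = "S01",
                              start_time = "2012-06-01T23:00:00Z") {
  p <- modifyList(night_params(), params)
  if (p$duration_h < 4 || p$duration_h > 10)
    stopf("duration_h must lie in [4, 10]")
  if (p$mean_rr_ms < 600 || p$mean_rr_ms > 1200)
    stopf("mean_rr_ms must lie in [600, 1200]")
  if (p$a_lf_ms > 0 && (p$f_lf_hz < 0.04 || p$f_lf_hz > 0.15))
    stopf("f_lf_hz must lie in the LF band [0.04, 0.15]")
  if (p$a_hf_ms > 0 && (p$f_hf_hz < 0.15 || p$f_hf_hz > 0.40))
    stopf("f_hf_hz must lie in the HF band [0.15, 0.40]")
  set.seed(seed)
  total_ms <- p$duration_h * 3.6e6
  n_guess <- ceiling(total_ms / (p$mean_rr_ms * 0.8))
  noise <- rnorm(n_guess, 0, p$noise_sd_ms)
  rr <- numeric(n_guess)
  t_ms <- 0
  k <- 0L
  while (t_ms < total_ms && k < n_guess) {
    k <- k + 1L
    t_s <- t_ms / 1000
    v <- p$mean_rr_ms + p$a_lf_ms * sin(2 * pi * p$f_lf_hz * t_s) +
      p$a_hf_ms * sin(2 * pi * p$f_hf_hz * t_s) + noise[k]
    v <- max(v, 0.3 * p$mean_rr_ms)
    rr[k] <- v
    t_ms <- t_ms + v
  }
  rr <- rr[seq_len(k)]
  clean <- rr
  spikes <- integer(0)
  if (p$ectopic_rate > 0) {
    hit <- which(runif(k) < p$ectopic_rate)
    hit <- hit[hit > 1L]
    if (length(hit)) {
      sign <- ifelse(runif(length(hit)) < 0.5, 0.6, 1.4)
      rr[hit] <- rr[hit] * sign
      spikes <- hit
    }
  }
  list(session = rr_session(subject_id, start_time, rr),
       spikes = spikes, clean_rr = clean)
}

#' Default phone-day parameters
#'
#' Behavioral rates of a typical working day: Poisson calls, log-normal call
#' durations, a couple of calendar events, two visited locations 5 km apart,
#' accelerometer windows every 5 minutes for 30 s, a monotone battery
#' discharge with one charging block, and up to four voice responses of
#' band-limited noise with known RMS.
#'
#' @return named list of parameters for [generate_phone_day()].
#' @export
phone_day_params <- function() {
  list(call_rate = 6, call_meanlog = log(120), call_sdlog = 0.8,
       p_incoming = 0.5,
       event_rate = 2, event_dur_s = 1800, note_chars = 80,
       contacts_base = 150L,
       gps_centers = matrix(c(47.37, 8.55, 47.415, 8.55), ncol = 2,
                            byrow = TRUE, dimnames = list(NULL, c("lat", "lon"))),
       gps_dwell = 18L, gps_jitter_m = 10,
       accel_every_s = 300, accel_window_s = 30, accel_rate_hz = 5,
       accel_active_g = 0.05,
       n_audio = 4L, audio_len_s = 10, audio_rms = 0.1, audio_rate_hz = 8000L)
}

iso_utc <- function(date, sec_of_day) {
  sprintf("%sT%02d:%02d:%02dZ", date, sec_of_day %/% 3600,
          (sec_of_day %% 3600) %/% 60, sec_of_day %% 60)
}

#' Generate one synthetic phone-day log
#'
#' Calls are Poisson with log-normal durations and Bernoulli direction;
#' calendar events have fixed duration and Poisson count; contacts snapshots
#' are yesterday/today counts around a base; the battery discharges
#' monotonically with one charging block; accelerometer windows are sensed
#' every 5 minutes for 30 seconds around 1 g; GPS alternates dwell clouds at
#' the parameter's cluster centers joined by traversal points; audio
#' responses are white noise scaled to a known RMS. Event times fall in the
#' 08:00–20:00 day window (UTC).
#'
#' @param params list as from [phone_day_params()].
#' @param seed integer seed.
#' @param subject_id,date log metadata.
#' @return a [phone_day_log()].
#' @export
generate_phone_day <- function(params = phone_day_params(), seed = 1L,
                               subject_id = "S01", date = "2012-06-01") {
  p <- modifyList(phone_day_params(), params)
  set.seed(seed)
  day0 <- 8L * 3600L; day1 <- 20L * 3600L

  n_calls <- rpois(1, p$call_rate)
  calls <- if (n_calls > 0) {
    data.frame(
      timestamp = iso_utc(date, sort(sample(day0:day1, n_calls))),
      direction = ifelse(runif(n_calls) < p$p_incoming, "incoming", "outgoing"),
      duration_s = rlnorm(n_calls, p$call_meanlog, p$call_sdlog),
      stringsAsFactors = FALSE)
  } else NULL

  n_ev <- rpois(1, p$event_rate)
  calendar <- if (n_ev > 0) {
    st <- sort(sample(day0:(day1 - p$event_dur_s), n_ev))
    data.frame(start = iso_utc(date, st),
               end = iso_utc(date, st + as.integer(p$event_dur_s)),
               note_size = rpois(n_ev, p$note_chars),
               stringsAsFactors = FALSE)
  } else NULL

  contacts <- data.frame(
    timestamp = c(iso_utc(date, day0), iso_utc(date, day1)),
    n_contacts = p$contacts_base + c(0L, rpois(1, 2)),
    n_phone_numbers = p$contacts_base + 20L + c(0L, rpois(1, 1)),
    n_emails = p$contacts_base - 50L + c(0L, rpois(1, 1)),
    stringsAsFactors = FALSE)

  bt <- seq(day0, day1, by = 1800L)
  level <- numeric(length(bt))
  charging <- logical(length(bt))
  lv <- 1.0
  for (i in seq_along(bt)) {
    charging[i] <- bt[i] >= 12 * 3600 && bt[i] < 14 * 3600
    level[i] <- lv
    lv <- if (charging[i]) min(1, lv + 0.1) else max(0.05, lv - 0.04)
    level[i] <- round(level[i] / 0.05) * 0.05   # stored in 5% steps
  }
  battery <- data.frame(timestamp = iso_utc(date, bt), level = level,
                        charging = charging, stringsAsFactors = FALSE)

  wt <- seq(day0, day1 - p$accel_window_s, by = p$accel_every_s)
  nsamp <- as.integer(p$accel_window_s * p$accel_rate_hz)
  accel <- lapply(wt, function(t0) {
    g <- cbind(rnorm(nsamp, 0, p$accel_active_g),
               rnorm(nsamp, 0, p$accel_active_g),
               1 + rnorm(nsamp, 0, p$accel_active_g))
    list(timestamp = iso_utc(date, as.integer(t0)), samples = g)
  })

  nc <- nrow(p$gps_centers)
  gps_rows <- NULL
  t_gps <- day0
  deg_per_m_lat <- 1 / 111320
  for (ci in seq_len(nc)) {
    jit <- p$gps_jitter_m * deg_per_m_lat
    lat <- p$gps_centers[ci, "lat"] + rnorm(p$gps_dwell, 0, jit)
    lon <- p$gps_centers[ci, "lon"] + rnorm(p$gps_dwell, 0, jit)
    ts <- t_gps + seq(0, by = 300, length.out = p$gps_dwell)
    gps_rows <- rbind(gps_rows, data.frame(
      timestamp = iso_utc(date, as.integer(ts)), lat = lat, lon = lon,
      stringsAsFactors = FALSE))
    t_gps <- max(ts) + 300
    if (ci < nc) {   # traversal points between consecutive centers
      frac <- c(0.25, 0.5, 0.75)
      lat_t <- p$gps_centers[ci, "lat"] +
        frac * (p$gps_centers[ci + 1, "lat"] - p$gps_centers[ci, "lat"])
      lon_t <- p$gps_centers[ci, "lon"] +
        frac * (p$gps_centers[ci + 1, "lon"] - p$gps_centers[ci, "lon"])
      ts <- t_gps + seq(0, by = 300, length.out = 3)
      gps_rows <- rbind(gps_rows, data.frame(
        timestamp = iso_utc(date, as.integer(ts)), lat = lat_t, lon = lon_t,
        stringsAsFactors = FALSE))
      t_gps <- max(ts) + 300
    }
  }

  audio <- lapply(seq_len(p$n_audio), function(i) {
    n <- as.integer(p$audio_len_s * p$audio_rate_hz)
    x <- rnorm(n, 0, p$audio_rms)
    x <- pmax(-1, pmin(1, x))
    list(timestamp = iso_utc(date, as.integer(day0 + i * 10800 - 3600)),
         samples = x, sample_rate = p$audio_rate_hz)
  })

  phone_day_log(subject_id, date, calls = calls, calendar = calendar,
                contacts = contacts, battery = battery, accel = accel,
                gps = gps_rows, audio = audio)
}

#' Cohort specification for the synthetic study
#'
#' Defines the simulated study conditions: number of users and days, the
#' ground-truth logit dependence of the stress class on named features, and
#' the typical level and spread of every feature in the battery. The default
#' effect runs through six features (LF/HF, SD1/SD2, sleep duration, RMSSD,
#' call count, audio length) with class-2 slopes twice the class-1 slopes —
#' a strong, ordinal signal.
#'
#' @param n_users number of users, default 10.
#' @param n_days labeled days per user, default 30.
#' @param seed integer base seed.
#' @param effect list with `features` (names), `beta` (2 x (1 + k) matrix:
#'   rows classes 1 and 2, columns intercept then slopes on the standardized
#'   latent features). Zero slopes give a null cohort.
#' @param night raw-mode night parameters: baseline values and additive
#'   per-class offsets for sleep duration (h), mean RR (ms) and the LF/HF
#'   modulation amplitudes (ms). Defaults: 7 h − 0.9 h/class, 1000 ms −
#'   60 ms/class, LF 15 + 15/class, HF 35 − 10/class.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_users = 10L, n_days = 30L, seed = 1L,
                        effect = NULL, night = NULL) {
  feats <- c("lf_hf", "sd1_sd2", "sleep_duration_h", "rmssd_ms",
             "n_calls", "audio_length_s")
  if (is.null(effect)) {
    b1 <- c(0, 1.5, 1.0, -1.0, -0.8, 0.8, 0.5)
    effect <- list(features = feats, beta = rbind(b1, 2 * b1))
  }
  stopifnot(nrow(effect$beta) == 2L,
            ncol(effect$beta) == length(effect$features) + 1L)
  night <- modifyList(list(base_h = 7, class_h = -0.9,
                           base_rr_ms = 1000, class_rr_ms = -60,
                           base_alf_ms = 15, class_alf_ms = 15,
                           base_ahf_ms = 35, class_ahf_ms = -10),
                      night %||% list())
  structure(list(n_users = as.integer(n_users), n_days = as.integer(n_days),
                 seed = as.integer(seed), effect = effect, night = night),
            class = "cohort_spec")
}

# Typical level and spread of each feature, used to place the standardized
# latent values on a realistic scale. Features are drawn independently.
feature_scales <- function() {
  rbind(
    data.frame(feature = c("sleep_duration_h", "mean_rr_ms", "sdnn_ms",
                           "rmssd_ms", "pnn50_pct", "hrv_index", "tinn_ms",
                           "apen", "sd1_ms", "sd2_ms", "sd1_sd2", "lf_nu",
                           "hf_nu", "lf_hf"),
               mean = c(7, 950, 60, 40, 15, 12, 250, 1.1, 30, 80, 0.4,
                        0.6, 0.4, 1.6),
               sd = c(1, 100, 15, 12, 8, 3, 60, 0.2, 8, 20, 0.1,
                      0.12, 0.12, 0.5)),
    data.frame(feature = c("n_calls", "sum_call_s", "mean_call_s",
                           "var_call_s", "in_out_ratio", "n_cal_events",
                           "cal_total_s", "cal_mean_s", "cal_note_mean_chars",
                           "d_contacts", "d_phone_numbers", "d_emails",
                           "battery_ratio", "accel_mag_mean_g",
                           "accel_mag_var_g2", "gps_distance_m", "n_locations",
                           "audio_length_s", "speech_energy"),
               mean = c(6, 900, 150, 8000, 1, 2, 3600, 1800, 80,
                        0.01, 0.01, 0.01, 4, 1, 0.01, 8000, 2, 10, 0.1),
               sd = c(3, 400, 60, 3000, 0.4, 1, 1500, 600, 30,
                      0.02, 0.02, 0.02, 1.5, 0.05, 0.005, 3000, 0.7, 3, 0.03))
  )
}

softmax3 <- function(y1, y2) {
  z <- cbind(0, y1, y2)
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

#' Generate a synthetic study cohort with known ground truth
#'
#' Per user-day, draws standardized latent values for the effect features,
#' computes the three-class probabilities through the ground-truth logit,
#' samples the class, and sets the self-report uniformly inside the sampled
#' class's score band (so the mapped class equals the sampled class — label
#' noise is deliberately a separate knob, not baked in). All remaining
#' features of the battery are independent noise at realistic levels.
#'
#' With `raw = TRUE` the generator additionally writes a full input directory
#' (`rr/`, `days/`, `reports/`) under `dir`: per-night RR files with metadata
#' sidecars and per-day phone JSON logs whose generation parameters are tied
#' to the day's class (shorter sleep, higher LF/HF, more and longer calls at
#' higher stress), so the end-to-end pipeline sees a recoverable signal.
#'
#' @param spec a [cohort_spec()].
#' @param raw also write raw files, default `FALSE`.
#' @param dir output directory for raw files (required when `raw = TRUE`).
#' @return `list(features =, ground_truth =, spec =)`: the per-day feature
#'   table with `stress_score`, and the ground truth (`beta`, effect feature
#'   names, sampled classes, per-night spike indices when raw).
#' @export
generate_cohort <- function(spec = cohort_spec(), raw = FALSE, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (raw && is.null(dir)) stopf("raw = TRUE requires an output directory")
  sc <- feature_scales()
  eff <- spec$effect
  all_feats <- sc$feature
  rows <- NULL
  gt_classes <- NULL
  spikes <- list()
  if (raw) {
    for (d in c("rr", "days", "reports"))
      dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  dates <- format(as.Date("2012-06-01") + seq_len(spec$n_days) - 1L)
  for (u in seq_len(spec$n_users)) {
    uid <- sprintf("S%02d", u)
    for (d in seq_len(spec$n_days)) {
      set.seed(derive_seed(spec$seed, u * 1000L + d))
      z <- stats::setNames(rnorm(length(eff$features)), eff$features)
      y <- eff$beta %*% c(1, z)
      pr <- softmax3(y[1], y[2])[1, ]
      cls <- sample(0:2, 1, prob = pr)
      score <- switch(as.character(cls),
                      "0" = runif(1, 0.0, 0.3),
                      "1" = runif(1, 0.31, 0.69),
                      "2" = runif(1, 0.7, 1.0))
      vals <- stats::setNames(numeric(length(all_feats)), all_feats)
      for (f in all_feats) {
        zi <- if (f %in% eff$features) z[[f]] else rnorm(1)
        vals[f] <- sc$mean[sc$feature == f] + sc$sd[sc$feature == f] * zi
      }
      rows <- rbind(rows, data.frame(subject_id = uid, date = dates[d],
                                     as.list(vals), stress_score = score,
                                     stringsAsFactors = FALSE))
      gt_classes <- rbind(gt_classes, data.frame(subject_id = uid,
                                                 date = dates[d], class = cls))
      if (raw) {
        np <- night_params()
        ns <- spec$night
        np$duration_h <- max(4, ns$base_h + ns$class_h * cls)
        np$mean_rr_ms <- ns$base_rr_ms + ns$class_rr_ms * cls
        np$a_lf_ms <- ns$base_alf_ms + ns$class_alf_ms * cls
        np$a_hf_ms <- ns$base_ahf_ms + ns$class_ahf_ms * cls
        night <- generate_rr_night(np, seed = derive_seed(spec$seed, "rr", u, d),
                                   subject_id = uid,
                                   start_time = paste0(dates[d], "T23:00:00Z"))
        stem <- sprintf("%s_%s", uid, dates[d])
        write_rr_session(night$session, file.path(dir, "rr", paste0(stem, ".txt")))
        jsonlite::write_json(list(subject_id = uid, date = dates[d],
                                  start_time = night$session$start_time),
                             file.path(dir, "rr", paste0(stem, ".json")),
                             auto_unbox = TRUE)
        spikes[[stem]] <- night$spikes
        pp <- phone_day_params()
        pp$call_rate <- 4 + 3 * cls
        pp$audio_len_s <- 8 + 4 * cls
        day <- generate_phone_day(pp, seed = derive_seed(spec$seed, "day", u, d),
                                  subject_id = uid, date = dates[d])
        write_phone_day(day, file.path(dir, "days", paste0(stem, ".json")))
      }
    }
  }
  if (raw) {
    rep_df <- rows[, c("subject_id", "date", "stress_score")]
    rep_out <- rep_df
    rep_out$stress_score <- fmt_num(rep_out$stress_score)
    write.csv(rep_out, file.path(dir, "reports", "reports.csv"),
              row.names = FALSE, quote = FALSE)
  }
  list(features = rows,
       ground_truth = list(beta = eff$beta, features = eff$features,
                           classes = gt_classes, spikes = spikes,
                           seed = spec$seed),
       spec = spec)
}
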