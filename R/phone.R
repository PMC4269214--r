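# Smartphone daytime features: calls, calendar, contacts, battery,
# accelerometer, GPS (with DBSCAN location clustering) and the two audio
# features that feed the stress model, plus the audio and GPS anonymization.

#' Anonymize a voice recording by chunk permutation
#'
#' Slices the signal into `chunk_ms` chunks and randomly permutes the chunk
#' order within every 1-second window, destroying intelligibility while
#' conserving the sample multiset (hence duration and RMS energy exactly).
#' A trailing partial second has its complete chunks permuted; a remainder
#' shorter than one chunk stays in place.
#'
#' @param audio `list(samples =, sample_rate =)` (as in a phone-day log entry).
#' @param chunk_ms chunk length in milliseconds; must divide 1000.
#' @param seed integer seed for the permutation.
#' @return the audio entry with permuted samples.
#' @export
anonymize_audio <- function(audio, chunk_ms = 50, seed = 1L) {
  if (1000 %% chunk_ms != 0) stopf("chunk_ms must divide 1000")
  x <- audio$samples
  sr <- audio$sample_rate
  if (length(x) == 0L) stopf("audio must be non-empty")
  spc <- sr * chunk_ms / 1000
  if (spc != round(spc))
    stopf("chunk_ms x sample_rate must give an integer number of samples")
  spc <- as.integer(spc)
  cps <- as.integer(1000 / chunk_ms)            # chunks per second
  out <- x
  set.seed(seed)
  sec_starts <- seq(1L, length(x), by = sr)
  for (s0 in sec_starts) {
    s1 <- min(s0 + sr - 1L, length(x))
    n_full <- (s1 - s0 + 1L) %/% spc
    if (n_full < 2L) next
    perm <- sample.int(n_full)
    idx <- s0 - 1L + seq_len(n_full * spc)
    chunks <- matrix(x[idx], nrow = spc)
    out[idx] <- as.numeric(chunks[, perm])
  }
  audio$samples <- out
  audio
}

#' Basic audio features: length and speech energy
#'
#' @param audio `list(samples =, sample_rate =)`.
#' @return `list(audio_length_s =, speech_energy =)`; energy is the RMS of
#'   the samples (permutation-invariant, so unaffected by anonymization).
#' @export
audio_basic_features <- function(audio) {
  if (length(audio$samples) == 0L) stopf("audio must be non-empty")
  list(audio_length_s = length(audio$samples) / audio$sample_rate,
       speech_energy = sqrt(mean(audio$samples^2)))
}

#' Call features
#'
#' @param calls data.frame with `direction` and `duration_s`.
#' @return list with `n_calls`, `sum_call_s`, `mean_call_s`, `var_call_s`
#'   (population variance), `in_out_ratio` (#incoming / #outgoing). With no
#'   calls the mean, variance and ratio are missing; with no outgoing calls
#'   the ratio is missing.
#' @export
call_features <- function(calls) {
  n <- nrow(calls)
  if (n == 0L)
    return(list(n_calls = 0, sum_call_s = 0, mean_call_s = NA_real_,
                var_call_s = NA_real_, in_out_ratio = NA_real_))
  n_in <- sum(calls$direction == "incoming")
  n_out <- sum(calls$direction == "outgoing")
  list(n_calls = n,
       sum_call_s = sum(calls$duration_s),
       mean_call_s = mean(calls$duration_s),
       var_call_s = var_pop(calls$duration_s),
       in_out_ratio = if (n_out > 0) n_in / n_out else NA_real_)
}

#' Calendar features
#'
#' Overlapping events are counted independently (no merging).
#'
#' @param calendar data.frame with `.t`, `.t_end` (epoch seconds) and
#'   `note_size`.
#' @return list with `n_cal_events`, `cal_total_s`, `cal_mean_s`,
#'   `cal_note_mean_chars`; means are missing for an empty list.
#' @export
calendar_features <- function(calendar) {
  n <- nrow(calendar)
  if (n == 0L)
    return(list(n_cal_events = 0, cal_total_s = 0, cal_mean_s = NA_real_,
                cal_note_mean_chars = NA_real_))
  dur <- calendar$.t_end - calendar$.t
  list(n_cal_events = n, cal_total_s = sum(dur), cal_mean_s = mean(dur),
       cal_note_mean_chars = mean(calendar$note_size))
}

#' Relative change of contact counts
#'
#' The absolute size of the address book is irrelevant; what may track social
#' behavior is the day-over-day relative change of the number of contacts,
#' phone numbers and e-mail addresses.
#'
#' @param today,previous single-row snapshots with `n_contacts`,
#'   `n_phone_numbers`, `n_emails`; `previous` may be `NULL`.
#' @return list with `d_contacts`, `d_phone_numbers`, `d_emails`; a feature
#'   is missing when the previous count is zero or the previous snapshot is
#'   absent.
#' @export
contacts_delta <- function(today, previous = NULL) {
  if (is.null(previous) || is.null(today))
    return(list(d_contacts = NA_real_, d_phone_numbers = NA_real_,
                d_emails = NA_real_))
  rel <- function(a, b) if (b > 0) (a - b) / b else NA_real_
  list(d_contacts = rel(today$n_contacts, previous$n_contacts),
       d_phone_numbers = rel(today$n_phone_numbers, previous$n_phone_numbers),
       d_emails = rel(today$n_emails, previous$n_emails))
}

#' Battery charging ratio
#'
#' Piecewise-constant interpolation of the charging state between samples;
#' the feature is seconds-not-charging / seconds-charging. Missing with fewer
#' than two samples or when the phone never charged.
#'
#' @param battery data.frame with `.t` (epoch seconds) and `charging`.
#' @return scalar ratio or `NA`.
#' @export
battery_ratio <- function(battery) {
  if (nrow(battery) < 2L) return(NA_real_)
  dt <- diff(battery$.t)
  st <- battery$charging[-nrow(battery)]
  charging_s <- sum(dt[st])
  not_charging_s <- sum(dt[!st])
  if (charging_s <= 0) return(NA_real_)
  not_charging_s / charging_s
}

#' Accelerometer magnitude features
#'
#' Per-sample Euclidean norm of the 3-axis acceleration, pooled over all
#' windows of the day; returns the mean and the population variance.
#'
#' @param accel list of windows with `samples` (n x 3 matrices, units of g).
#' @return `list(accel_mag_mean_g =, accel_mag_var_g2 =)`; both missing with
#'   no windows.
#' @export
accel_features <- function(accel) {
  if (length(accel) == 0L)
    return(list(accel_mag_mean_g = NA_real_, accel_mag_var_g2 = NA_real_))
  mags <- unlist(lapply(accel, function(w) sqrt(rowSums(w$samples^2))))
  list(accel_mag_mean_g = mean(mags), accel_mag_var_g2 = var_pop(mags))
}

#' Total GPS distance traveled
#'
#' Sum of haversine distances between consecutive samples (Earth radius
#' 6,371,000 m); samples must be time-sorted.
#'
#' @param gps data.frame with `lat`, `lon` in degrees.
#' @return distance in meters; 0 with fewer than two samples.
#' @export
gps_distance <- function(gps) {
  n <- nrow(gps)
  if (n < 2L) return(0)
  p <- cbind(gps$lon, gps$lat)
  sum(geosphere::distHaversine(p[-n, , drop = FALSE], p[-1, , drop = FALSE],
                               r = 6371000))
}

#' Number of visited locations (DBSCAN over GPS points)
#'
#' Density-based clustering under the haversine metric; returns the number of
#' clusters found (noise points excluded). Deterministic given the input
#' order. A brute-force implementation: day tracks are at most a few hundred
#' points.
#'
#' @param gps data.frame with `lat`, `lon`.
#' @param eps_m neighborhood radius in meters (> 0), default 100.
#' @param min_pts minimum neighborhood size (>= 1, point itself included),
#'   default 5.
#' @return `list(n_clusters =, labels =, centroids =)`; `labels` is 0 for
#'   noise, `centroids` a matrix (lat, lon) of cluster means.
#' @export
cluster_locations <- function(gps, eps_m = 100, min_pts = 5L) {
  if (eps_m <= 0) stopf("eps_m must be positive")
  if (min_pts < 1L) stopf("min_pts must be >= 1")
  n <- nrow(gps)
  if (n == 0L)
    return(list(n_clusters = 0L, labels = integer(0),
                centroids = matrix(numeric(0), ncol = 2,
                                   dimnames = list(NULL, c("lat", "lon")))))
  p <- cbind(gps$lon, gps$lat)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dmat[i, ] <- geosphere::distHaversine(p[i, , drop = FALSE], p, r = 6371000)
  }
  labels <- integer(n)          # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- which(dmat[i, ] <= eps_m)
    if (length(nb) < min_pts) next        # noise (may be claimed later)
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) labels[j] <- cl
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- which(dmat[j, ] <= eps_m)
        if (length(nbj) >= min_pts)
          queue <- c(queue, setdiff(nbj, which(visited | labels > 0L)))
      }
    }
  }
  cents <- if (cl > 0) {
    t(vapply(seq_len(cl), function(k)
      c(mean(gps$lat[labels == k]), mean(gps$lon[labels == k])), numeric(2)))
  } else matrix(numeric(0), ncol = 2)
  colnames(cents) <- c("lat", "lon")
  list(n_clusters = cl, labels = labels, centroids = cents)
}

#' Anonymize a GPS track by centroid shift
#'
#' Shifts all coordinates so that the centroid of the cluster centroids
#' becomes the origin. Longitude offsets are scaled by the cosine of the
#' reference latitude (a local equirectangular projection about the
#' centroid), so the relative geometry — and hence the distance feature — is
#' preserved to first order; a plain subtraction would stretch east–west
#' distances when a mid-latitude track lands on the equator. With no
#' clusters, the track centroid is used as the reference.
#'
#' @param gps data.frame with `lat`, `lon`.
#' @param centroids matrix of cluster centroids (columns lat, lon), possibly
#'   empty.
#' @return the track with shifted `lat`, `lon`.
#' @export
anonymize_gps <- function(gps, centroids) {
  if (nrow(gps) == 0L) return(gps)
  if (is.null(centroids) || nrow(centroids) == 0L) {
    ref <- c(mean(gps$lat), mean(gps$lon))
  } else {
    ref <- c(mean(centroids[, "lat"]), mean(centroids[, "lon"]))
  }
  gps$lat <- gps$lat - ref[1]
  gps$lon <- (gps$lon - ref[2]) * cos(ref[1] * pi / 180)
  gps
}

#' Names of the 19 smartphone features
#' @return character vector of feature names.
#' @export
phone_feature_names <- function() {
  c("n_calls", "sum_call_s", "mean_call_s", "var_call_s", "in_out_ratio",
    "n_cal_events", "cal_total_s", "cal_mean_s", "cal_note_mean_chars",
    "d_contacts", "d_phone_numbers", "d_emails", "battery_ratio",
    "accel_mag_mean_g", "accel_mag_var_g2", "gps_distance_m", "n_locations",
    "audio_length_s", "speech_energy")
}

#' Extract the smartphone day features from one phone-day log
#'
#' Emits the 19 named phone features. Audio features are averaged over the
#' day's responses. Contact deltas use the earliest snapshot as the previous
#' day's reference and the latest as today's. Undefined features are `NA`.
#'
#' @param daylog a [phone_day_log()].
#' @param config configuration list (see [default_config()]).
#' @return a [feature_vector()] with modality `"phone"`.
#' @export
extract_phone_features <- function(daylog, config = default_config()) {
  stopifnot(inherits(daylog, "phone_day_log"))
  pc <- config$phone
  cf <- call_features(daylog$calls)
  cal <- calendar_features(daylog$calendar)
  cd <- if (nrow(daylog$contacts) >= 2L) {
    contacts_delta(daylog$contacts[nrow(daylog$contacts), ],
                   daylog$contacts[1, ])
  } else contacts_delta(NULL, NULL)
  bat <- battery_ratio(daylog$battery)
  acc <- accel_features(daylog$accel)
  clus <- cluster_locations(daylog$gps, pc$dbscan_eps_m, pc$dbscan_min_pts)
  dist_m <- gps_distance(daylog$gps)
  if (length(daylog$audio)) {
    af <- lapply(daylog$audio, audio_basic_features)
    alen <- mean(vapply(af, `[[`, numeric(1), "audio_length_s"))
    aen <- mean(vapply(af, `[[`, numeric(1), "speech_energy"))
  } else {
    alen <- NA_real_; aen <- NA_real_
  }
  feature_vector("phone", c(
    n_calls = cf$n_calls, sum_call_s = cf$sum_call_s,
    mean_call_s = cf$mean_call_s, var_call_s = cf$var_call_s,
    in_out_ratio = cf$in_out_ratio,
    n_cal_events = cal$n_cal_events, cal_total_s = cal$cal_total_s,
    cal_mean_s = cal$cal_mean_s, cal_note_mean_chars = cal$cal_note_mean_chars,
    d_contacts = cd$d_contacts, d_phone_numbers = cd$d_phone_numbers,
    d_emails = cd$d_emails,
    battery_ratio = bat,
    accel_mag_mean_g = acc$accel_mag_mean_g,
    accel_mag_var_g2 = acc$accel_mag_var_g2,
    gps_distance_m = dist_m,
    n_locations = as.numeric(clus$n_clusters),
    audio_length_s = alen,
    speech_energy = aen
  ))
}
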