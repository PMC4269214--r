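# Smartphone feature extraction and the anonymization procedures.

test_that("audio anonymization conserves samples, energy and duration", {
  set.seed(1)
  audio <- list(samples = rnorm(16000, 0, 0.2), sample_rate = 8000L)
  out <- anonymize_audio(audio, chunk_ms = 250, seed = 99)
  expect_length(out$samples, length(audio$samples))
  expect_equal(sort(out$samples), sort(audio$samples))
  expect_false(identical(out$samples, audio$samples))
  a0 <- audio_basic_features(audio); a1 <- audio_basic_features(out)
  expect_equal(a1$speech_energy, a0$speech_energy, tolerance = 1e-12)
  expect_equal(a1$audio_length_s, a0$audio_length_s)
  # deterministic under a fixed seed
  expect_identical(anonymize_audio(audio, 250, seed = 99)$samples, out$samples)
  # one chunk per second: permutation is the identity
  one <- list(samples = rnorm(8000), sample_rate = 8000L)
  expect_identical(anonymize_audio(one, 1000, seed = 3)$samples, one$samples)
  expect_error(anonymize_audio(audio, chunk_ms = 300), "divide")
})

test_that("audio features follow their closed forms", {
  expect_equal(audio_basic_features(list(samples = numeric(16000) + 0,
                                         sample_rate = 16000L))$audio_length_s, 1)
  expect_equal(audio_basic_features(list(samples = rep(0, 100),
                                         sample_rate = 100L))$speech_energy, 0)
  expect_equal(audio_basic_features(list(samples = rep(-0.25, 100),
                                         sample_rate = 100L))$speech_energy, 0.25)
})

test_that("call features handle counts, ratios and empty days", {
  calls <- data.frame(direction = c("incoming", "outgoing", "incoming"),
                      duration_s = c(60, 120, 300))
  cf <- call_features(calls)
  expect_equal(cf$n_calls, 3)
  expect_equal(cf$sum_call_s, 480)
  expect_equal(cf$mean_call_s, 160)
  expect_equal(cf$in_out_ratio, 2)
  expect_equal(cf$var_call_s, mean((calls$duration_s - 160)^2))
  empty <- call_features(calls[0, ])
  expect_equal(empty$n_calls, 0)
  expect_equal(empty$sum_call_s, 0)
  expect_true(is.na(empty$mean_call_s) && is.na(empty$in_out_ratio))
  # all incoming: ratio undefined
  onein <- call_features(data.frame(direction = "incoming", duration_s = 5))
  expect_true(is.na(onein$in_out_ratio))
  expect_equal(call_features(data.frame(direction = c("incoming", "incoming"),
                                        duration_s = c(7, 7)))$var_call_s, 0)
})

test_that("calendar features sum durations and average note sizes", {
  cal <- data.frame(.t = c(0, 5000), .t_end = c(1800, 6800),
                    note_size = c(0L, 100L))
  f <- calendar_features(cal)
  expect_equal(f$n_cal_events, 2)
  expect_equal(f$cal_total_s, 3600)
  expect_equal(f$cal_mean_s, 1800)
  expect_equal(f$cal_note_mean_chars, 50)
  e <- calendar_features(cal[0, ])
  expect_equal(e$n_cal_events, 0)
  expect_equal(e$cal_total_s, 0)
  expect_true(is.na(e$cal_mean_s) && is.na(e$cal_note_mean_chars))
})

test_that("contact deltas are relative changes with division guards", {
  today <- list(n_contacts = 110, n_phone_numbers = 120, n_emails = 50)
  prev <- list(n_contacts = 100, n_phone_numbers = 120, n_emails = 0)
  d <- contacts_delta(today, prev)
  expect_equal(d$d_contacts, 0.10)
  expect_equal(d$d_phone_numbers, 0)
  expect_true(is.na(d$d_emails))          # previous count 0
  allna <- contacts_delta(today, NULL)
  expect_true(all(is.na(unlist(allna))))
})

test_that("battery ratio interpolates the charging state piecewise", {
  # 8 h not charging then 2 h charging
  b <- data.frame(.t = c(0, 8, 10) * 3600,
                  charging = c(FALSE, TRUE, TRUE))
  expect_equal(battery_ratio(b), 4)
  allch <- data.frame(.t = c(0, 3600), charging = c(TRUE, TRUE))
  expect_equal(battery_ratio(allch), 0)
  never <- data.frame(.t = c(0, 3600), charging = c(FALSE, FALSE))
  expect_true(is.na(battery_ratio(never)))
  expect_true(is.na(battery_ratio(never[1, ])))
})

test_that("accelerometer features pool magnitudes across windows", {
  w1 <- list(samples = matrix(c(0, 0, 1), 1))
  w2 <- list(samples = matrix(c(0, 0, 3), 1))
  f <- accel_features(list(w1, w2))
  expect_equal(f$accel_mag_mean_g, 2)
  expect_equal(f$accel_mag_var_g2, 1)
  expect_equal(accel_features(list(w2, w1)), f)     # order invariant
  g <- accel_features(list(list(samples = matrix(rep(c(0, 0, 1), 5),
                                                 ncol = 3, byrow = TRUE))))
  expect_equal(g$accel_mag_mean_g, 1)
  expect_equal(g$accel_mag_var_g2, 0)
  expect_true(all(is.na(unlist(accel_features(list())))))
})

test_that("GPS distance is the haversine chain with R = 6371 km", {
  two <- data.frame(lat = c(47.00, 47.01), lon = c(8.55, 8.55))
  expect_equal(gps_distance(two), 1111.9, tolerance = 0.5 / 1111.9)
  expect_equal(gps_distance(two),
               oracle_haversine(47.00, 8.55, 47.01, 8.55), tolerance = 1e-9)
  # identical consecutive points add nothing; reversal is symmetric
  three <- data.frame(lat = c(47, 47, 47.01), lon = c(8.55, 8.55, 8.55))
  expect_equal(gps_distance(three), gps_distance(two))
  expect_equal(gps_distance(two[2:1, ]), gps_distance(two))
  expect_equal(gps_distance(two[1, ]), 0)
})

test_that("DBSCAN location clustering matches the brute-force oracle", {
  set.seed(5)
  jit <- 10 / 111320
  g1 <- data.frame(lat = 47.37 + rnorm(6, 0, jit), lon = 8.55 + rnorm(6, 0, jit))
  g2 <- data.frame(lat = 47.415 + rnorm(6, 0, jit), lon = 8.55 + rnorm(6, 0, jit))
  track <- rbind(g1, g2)
  cl <- cluster_locations(track, eps_m = 100, min_pts = 5)
  expect_equal(cl$n_clusters, 2L)
  dmat <- outer(seq_len(12), seq_len(12), Vectorize(function(i, j)
    oracle_haversine(track$lat[i], track$lon[i], track$lat[j], track$lon[j])))
  expect_equal(cl$n_clusters, oracle_dbscan_n(dmat, 100, 5))
  # everything within eps of everything: one cluster
  expect_equal(cluster_locations(g1, 200, 5)$n_clusters, 1L)
  # fewer than min_pts scattered points: all noise
  sparse <- data.frame(lat = c(47, 48, 49), lon = c(8, 9, 10))
  expect_equal(cluster_locations(sparse, 100, 5)$n_clusters, 0L)
  expect_true(all(cluster_locations(sparse, 100, 5)$labels == 0L))
  expect_equal(cluster_locations(track[0, ], 100, 5)$n_clusters, 0L)
})

test_that("GPS anonymization zeroes the cluster centroid, keeps distances", {
  set.seed(6)
  jit <- 10 / 111320
  track <- data.frame(lat = c(47.37 + rnorm(6, 0, jit), 47.415 + rnorm(6, 0, jit)),
                      lon = 8.55 + rnorm(12, 0, jit))
  cl <- cluster_locations(track, 100, 5)
  shifted <- anonymize_gps(track, cl$centroids)
  cl2 <- cluster_locations(shifted, 100, 5)
  expect_equal(mean(cl2$centroids[, "lat"]), 0, tolerance = 1e-9)
  expect_equal(mean(cl2$centroids[, "lon"]), 0, tolerance = 1e-9)
  d0 <- gps_distance(track); d1 <- gps_distance(shifted)
  expect_lt(abs(d1 - d0) / d0, 0.001)
  # no clusters: fall back to the track centroid
  sparse <- data.frame(lat = c(47.0, 47.2), lon = c(8.0, 8.4))
  sh <- anonymize_gps(sparse, matrix(numeric(0), ncol = 2,
                                     dimnames = list(NULL, c("lat", "lon"))))
  expect_equal(mean(sh$lat), 0)
  expect_equal(mean(sh$lon), 0)
})

test_that("extract_phone_features emits the full 19-feature battery", {
  empty <- phone_day_log("S01", "2012-06-01")
  fv <- extract_phone_features(empty)
  expect_length(fv, 19L)
  expect_setequal(names(fv), phone_feature_names())
  expect_equal(unname(fv["n_calls"]), 0)
  expect_equal(unname(fv["gps_distance_m"]), 0)
  expect_true(is.na(fv["mean_call_s"]))
  expect_true(is.na(fv["audio_length_s"]))

  # only audio present: exactly the audio features are defined beyond counts
  au <- phone_day_log("S01", "2012-06-01",
    audio = list(list(timestamp = "2012-06-01T12:00:00Z",
                      samples = rep(0.1, 8000), sample_rate = 8000L),
                 list(timestamp = "2012-06-01T15:00:00Z",
                      samples = rep(0.3, 16000), sample_rate = 8000L)))
  fa <- extract_phone_features(au)
  expect_equal(unname(fa["audio_length_s"]), 1.5)   # mean of 1 s and 2 s
  expect_equal(unname(fa["speech_energy"]), 0.2)    # mean of 0.1 and 0.3
  expect_true(is.na(fa["battery_ratio"]))

  # generator ground truth: event counts reproduced exactly
  day <- generate_phone_day(seed = 21)
  fd <- extract_phone_features(day)
  expect_equal(unname(fd["n_calls"]), nrow(day$calls))
  expect_equal(unname(fd["n_cal_events"]), nrow(day$calendar))
  expect_equal(unname(fd["n_locations"]), 2)
})
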