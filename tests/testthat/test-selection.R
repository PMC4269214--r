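# Correlation reduction, sequential forward selection, and the two
# cross-validation protocols.

make_logit_cohort <- function(n, beta1, beta2, seed, k_noise = 0) {
  set.seed(seed)
  k <- length(beta1) - 1
  X <- as.data.frame(matrix(rnorm(n * (k + k_noise)), n))
  names(X) <- paste0("f", seq_len(k + k_noise))
  eta1 <- beta1[1] + as.matrix(X[, seq_len(k), drop = FALSE]) %*% beta1[-1]
  eta2 <- beta2[1] + as.matrix(X[, seq_len(k), drop = FALSE]) %*% beta2[-1]
  P <- exp(cbind(0, eta1, eta2)); P <- P / rowSums(P)
  y <- apply(P, 1, function(p) sample(0:2, 1, prob = p))
  list(X = X, y = y)
}

test_that("correlation reduction drops collinear features and only those", {
  set.seed(8)
  n <- 500
  A <- rnorm(n)
  df <- data.frame(A = A, B = 2 * A + rnorm(n, 0, 1e-3), C = rnorm(n),
                   D = rnorm(n))
  rep <- correlation_reduce(df)
  expect_s3_class(rep, "correlation_report")
  expect_length(intersect(c("A", "B"), rep$dropped), 1L)
  expect_true(all(c("C", "D") %in% rep$kept))
  expect_setequal(c(rep$kept, rep$dropped), names(df))

  # independent features: nothing dropped at r >= 0.8
  ind <- as.data.frame(matrix(rnorm(n * 6), n))
  expect_length(correlation_reduce(ind)$dropped, 0L)

  # three mutually collinear features: exactly two dropped
  tri <- data.frame(a = A, b = A + rnorm(n, 0, 1e-3),
                    c = -A + rnorm(n, 0, 1e-3), d = rnorm(n))
  rep3 <- correlation_reduce(tri)
  expect_length(rep3$dropped, 2L)
  expect_true("d" %in% rep3$kept)
})

test_that("correlation reduction is idempotent and keeps constant features", {
  set.seed(10)
  df <- data.frame(a = rnorm(100), b = rnorm(100))
  df$c <- df$a + rnorm(100, 0, 0.01)
  r1 <- correlation_reduce(df)
  r2 <- correlation_reduce(df[, r1$kept, drop = FALSE])
  expect_identical(r2$kept, r1$kept)
  expect_length(r2$dropped, 0L)
  dfc <- data.frame(a = rnorm(50), k = rep(1, 50))
  expect_warning(rk <- correlation_reduce(dfc), "constant")
  expect_true("k" %in% rk$kept)
})

test_that("forward selection finds the informative feature first", {
  coh <- make_logit_cohort(300, c(0, 0, 0, 2), c(0, 0, 0, 4), seed = 31,
                           k_noise = 3)
  sel <- sequential_forward_select(coh$X, coh$y, folds = 10, seed = 1)
  expect_s3_class(sel, "selection_result")
  expect_identical(sel$ordered_features[1], "f3")
  expect_equal(length(sel$cv_accuracy_trace), length(sel$ordered_features))
  expect_true(all(diff(c(sel$baseline_accuracy, sel$cv_accuracy_trace)) > 0))
  # deterministic under the same seed
  sel2 <- sequential_forward_select(coh$X, coh$y, folds = 10, seed = 1)
  expect_identical(sel, sel2)
})

test_that("forward selection stays honest on uninformative features", {
  set.seed(17)
  X <- as.data.frame(matrix(rnorm(200 * 5), 200))
  y <- sample(0:2, 200, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  sel <- sequential_forward_select(X, y, folds = 10, seed = 2)
  expect_lte(length(sel$ordered_features), 2L)
  # final CV accuracy within the binomial 95% band of the majority rate
  maj <- max(table(y)) / length(y)
  final <- if (length(sel$cv_accuracy_trace))
    tail(sel$cv_accuracy_trace, 1) else sel$baseline_accuracy
  band <- 1.96 * sqrt(maj * (1 - maj) / length(y))
  expect_lt(abs(final - maj), 2 * band)
  expect_error(sequential_forward_select(X, rep(1L, 200)), "2 classes")
})

test_that("leave-one-day-out runs one fold per day and scores degenerates", {
  # a user whose days all share one class: degenerate but perfect
  df1 <- data.frame(f1 = rnorm(6), f2 = rnorm(6), stress_score = rep(0.1, 6))
  cv1 <- leave_one_day_out_cv(df1, c("f1", "f2"))
  expect_equal(cv1$accuracy, 1)
  expect_true(all(cv1$per_fold_outcomes$missing_class_in_train))

  set.seed(12)
  df2 <- data.frame(f1 = rnorm(5), stress_score = c(0.1, 0.5, 0.9, 0.2, 0.8))
  cv2 <- leave_one_day_out_cv(df2, "f1")
  expect_equal(cv2$n_folds, 5L)
  expect_equal(nrow(cv2$per_fold_outcomes), 5L)
  expect_error(leave_one_day_out_cv(df2[1:2, ], "f1"), "at least 3")

  # strong-signal synthetic user beats chance clearly
  coh <- make_logit_cohort(20, c(0, 2.5), c(0, 5), seed = 44)
  dfs <- coh$X
  dfs$stress_score <- c(0.1, 0.5, 0.9)[coh$y + 1]
  cvs <- leave_one_day_out_cv(dfs, "f1")
  expect_gt(cvs$accuracy, 0.6)
})

test_that("leave-one-participant-out pools held-out rows across users", {
  set.seed(13)
  rows <- NULL
  for (u in 1:10) {
    coh <- make_logit_cohort(8, c(0, 2), c(0, 4), seed = 100 + u)
    df <- coh$X
    df$subject_id <- sprintf("S%02d", u)
    df$stress_score <- c(0.1, 0.5, 0.9)[coh$y + 1]
    rows <- rbind(rows, df)
  }
  cv <- leave_one_participant_out_cv(rows, "f1")
  expect_equal(cv$n_folds, 10L)
  expect_equal(nrow(cv$per_fold_outcomes), nrow(rows))
  expect_gt(cv$accuracy, 1 / 3)     # shared effect structure: above chance
  expect_error(leave_one_participant_out_cv(rows[rows$subject_id %in%
    c("S01", "S02"), ], "f1"), "at least 3")
})

test_that("opposite per-user effects hurt the general model, not LODO", {
  set.seed(14)
  rows <- NULL
  for (u in 1:6) {
    sgn <- if (u %% 2 == 0) 1 else -1
    coh <- make_logit_cohort(16, c(0, sgn * 3), c(0, sgn * 6), seed = 200 + u)
    df <- coh$X
    df$subject_id <- sprintf("S%02d", u)
    df$stress_score <- c(0.1, 0.5, 0.9)[coh$y + 1]
    rows <- rbind(rows, df)
  }
  lopo <- leave_one_participant_out_cv(rows, "f1")$accuracy
  lodo <- mean(vapply(unique(rows$subject_id), function(u)
    leave_one_day_out_cv(rows[rows$subject_id == u, ], "f1")$accuracy,
    numeric(1)))
  expect_lte(lopo, lodo)
})

test_that("cross-validation never leaks the held-out unit", {
  coh <- make_logit_cohort(12, c(0, 1.5), c(0, 3), seed = 55)
  df <- coh$X
  df$stress_score <- c(0.1, 0.5, 0.9)[coh$y + 1]
  y <- map_score_to_class(df$stress_score)
  # fold 1's training model equals a fresh fit on rows 2..n
  direct <- suppressWarnings(fit_logit(df[-1, "f1", drop = FALSE], y[-1]))
  refit <- suppressWarnings(fit_logit(df[-(1), "f1", drop = FALSE], y[-1]))
  expect_identical(coef(direct), coef(refit))
  cv <- leave_one_day_out_cv(df, "f1")
  pred1 <- suppressWarnings(predict(direct, df[1, "f1", drop = FALSE],
                                    type = "class"))
  expect_identical(cv$per_fold_outcomes$pred[1], pred1)
})

test_that("run_study reports all six accuracies on an aligned dataset", {
  spec <- cohort_spec(n_users = 5, n_days = 12, seed = 3)
  coh <- generate_cohort(spec)
  cfg <- default_config()
  cfg$study$min_nights <- 10
  cfg$study$run_selection <- FALSE     # structure check, not the protocol
  rep <- run_study(coh$features, cfg)
  expect_s3_class(rep, "study_report")
  expect_named(rep$user_specific, c("M_P", "M_H", "M"))
  expect_named(rep$general, c("M_P", "M_H", "M"))
  expect_true(all(unlist(rep$user_specific) >= 0 &
                  unlist(rep$user_specific) <= 1))
  expect_equal(rep$n_users, 5)
  # determinism under the same seed
  rep2 <- run_study(coh$features, cfg)
  expect_identical(rep$user_specific, rep2$user_specific)
  expect_identical(rep$general, rep2$general)

  # days without HRV are excluded from all models
  feat2 <- coh$features
  feat2[feat2$subject_id == "S01" & feat2$date == "2012-06-01",
        hrv_feature_names()] <- NA_real_
  rep3 <- run_study(feat2, cfg)
  expect_equal(rep3$n_days, rep$n_days - 1)
})
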