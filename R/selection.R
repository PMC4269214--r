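# Feature selection and evaluation: correlation-based reduction (pooled over
# users), per-user sequential forward selection with seeded stratified
# k-fold CV, and the leave-one-day-out / leave-one-participant-out protocols.

#' Correlation-based feature reduction
#'
#' Linear models want independent predictors, so highly correlated features
#' are removed before selection. Pearson r and its two-sided p-value are
#' computed for every feature pair over pairwise-complete rows; while any
#' pair with \code{|r| >= r_threshold} and \code{p < p_threshold} remains,
#' the member of the worst pair with the larger mean absolute correlation to
#' the remaining features is dropped. Deterministic; constant features have
#' undefined correlations and are kept with a warning.
#'
#' @param feature_table data.frame of numeric feature columns (at least 3
#'   complete rows).
#' @param r_threshold absolute-correlation flag threshold in (0,1),
#'   default 0.8.
#' @param p_threshold significance flag threshold in (0,1), default 0.01.
#' @return object of class `correlation_report`: `pairs` (feature_a,
#'   feature_b, r, p), `kept`, `dropped`.
#' @export
correlation_reduce <- function(feature_table, r_threshold = 0.8,
                               p_threshold = 0.01) {
  if (r_threshold <= 0 || r_threshold >= 1 || p_threshold <= 0 || p_threshold >= 1)
    stopf("thresholds must lie in (0,1)")
  ft <- as.data.frame(feature_table)
  ft <- ft[vapply(ft, is.numeric, logical(1))]
  feats <- names(ft)
  if (sum(complete.cases(ft)) < 3L && nrow(ft) < 3L)
    stopf("need at least 3 rows")
  constant <- vapply(ft, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2L || sd(v) == 0
  }, logical(1))
  if (any(constant))
    warning(sprintf("constant feature(s) kept (correlations undefined): %s",
                    paste(feats[constant], collapse = ", ")), call. = FALSE)
  nf <- length(feats)
  R <- matrix(NA_real_, nf, nf, dimnames = list(feats, feats))
  P <- R
  pairs <- NULL
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      if (constant[i] || constant[j]) next
      ok <- complete.cases(ft[[i]], ft[[j]])
      if (sum(ok) < 3L) next
      ct <- suppressWarnings(cor.test(ft[[i]][ok], ft[[j]][ok],
                                      method = "pearson"))
      R[i, j] <- R[j, i] <- unname(ct$estimate)
      P[i, j] <- P[j, i] <- ct$p.value
      pairs <- rbind(pairs, data.frame(feature_a = feats[i],
                                       feature_b = feats[j],
                                       r = unname(ct$estimate),
                                       p = ct$p.value,
                                       stringsAsFactors = FALSE))
    }
  }
  kept <- feats
  repeat {
    sub <- which(outer(kept, kept, function(a, b) a < b) &
                 abs(R[kept, kept, drop = FALSE]) >= r_threshold &
                 P[kept, kept, drop = FALSE] < p_threshold, arr.ind = TRUE)
    if (nrow(sub) == 0L) break
    rs <- abs(R[kept, kept, drop = FALSE])
    worst <- sub[order(-rs[sub]), , drop = FALSE][1, ]
    a <- kept[worst[1]]; b <- kept[worst[2]]
    mean_abs <- function(f) mean(abs(R[f, setdiff(kept, f)]), na.rm = TRUE)
    drop <- if (mean_abs(a) >= mean_abs(b)) a else b
    kept <- setdiff(kept, drop)
  }
  structure(list(pairs = pairs %||% data.frame(), kept = kept,
                 dropped = setdiff(feats, kept)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Correlation reduction: kept %d, dropped %d feature(s)\n",
              length(x$kept), length(x$dropped)))
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

# Seeded, class-stratified fold assignment.
stratified_folds <- function(y, folds, seed) {
  folds <- min(folds, length(y))
  set.seed(seed)
  assign <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# Pooled k-fold CV accuracy of the logit on the given feature subset.
cv_accuracy <- function(X, y, feats, fold_id, ridge) {
  pred <- integer(length(y))
  for (k in sort(unique(fold_id))) {
    te <- fold_id == k
    fit <- suppressWarnings(fit_logit(X[!te, feats, drop = FALSE], y[!te],
                                      ridge = ridge))
    pred[te] <- suppressWarnings(
      predict(fit, X[te, feats, drop = FALSE], type = "class"))
  }
  mean(pred == y)
}

#' Sequential forward feature selection
#'
#' Starting from the empty set, repeatedly adds the candidate feature that
#' maximizes the k-fold cross-validated accuracy of the stress logit, and
#' stops when the best improvement does not exceed `min_improvement`
#' (default 0: strict no-improvement). Folds are seeded and stratified by
#' class and fixed across all steps, so the result is reproducible. The
#' importance of a feature is its accuracy gain at the step it was added.
#'
#' @param X data.frame of candidate features; rows with missing values are
#'   dropped.
#' @param y labels in \{0,1,2\} (same length as rows of `X`).
#' @param folds number of CV folds, default 10 (capped at the row count).
#' @param seed integer seed for the fold assignment.
#' @param min_improvement minimum accuracy gain required to keep adding.
#' @param ridge logit ridge penalty.
#' @return object of class `selection_result` with `ordered_features`,
#'   `importance`, `cv_accuracy_trace` and `baseline_accuracy`.
#' @export
sequential_forward_select <- function(X, y, folds = 10L, seed = 1L,
                                      min_improvement = 0, ridge = 1e-4) {
  X <- as.data.frame(X)
  ok <- complete.cases(X)
  X <- X[ok, , drop = FALSE]
  y <- as.integer(y[ok])
  if (length(unique(y)) < 2L)
    stopf("selection requires at least 2 classes present")
  if (nrow(X) < 2L) stopf("not enough rows for selection")
  fold_id <- stratified_folds(y, folds, seed)
  candidates <- names(X)
  selected <- character(0)
  trace <- numeric(0)
  importance <- numeric(0)
  current <- cv_accuracy(X, y, character(0), fold_id, ridge)
  baseline <- current
  while (length(candidates)) {
    accs <- vapply(candidates, function(f)
      cv_accuracy(X, y, c(selected, f), fold_id, ridge), numeric(1))
    best <- which.max(accs)        # first max: deterministic tie-break
    gain <- accs[best] - current
    if (gain <= min_improvement) break
    selected <- c(selected, candidates[best])
    importance <- c(importance, gain)
    trace <- c(trace, accs[best])
    current <- accs[best]
    candidates <- candidates[-best]
  }
  structure(list(ordered_features = selected,
                 importance = stats::setNames(importance, selected),
                 cv_accuracy_trace = trace,
                 baseline_accuracy = baseline,
                 folds = min(folds, length(y)), seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Sequential forward selection: %d feature(s) (baseline %.3f)\n",
              length(x$ordered_features), x$baseline_accuracy))
  if (length(x$ordered_features)) {
    for (i in seq_along(x$ordered_features))
      cat(sprintf("  %d. %-22s gain %+.3f -> CV accuracy %.3f\n", i,
                  x$ordered_features[i], x$importance[i],
                  x$cv_accuracy_trace[i]))
  }
  invisible(x)
}

cv_result <- function(model_tag, protocol, per_fold) {
  acc <- mean(per_fold$correct)
  structure(list(model_tag = model_tag, protocol = protocol,
                 n_folds = length(unique(per_fold$fold)),
                 accuracy = acc, per_fold_outcomes = per_fold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s %s: accuracy %.3f over %d folds\n",
              x$model_tag %||% "model", x$protocol, x$accuracy, x$n_folds))
  invisible(x)
}

#' Leave-one-day-out cross-validation for one user
#'
#' One fold per labeled day: the model is trained on all other days and the
#' held-out day is classified; accuracy is the fraction of days whose
#' predicted class equals the class mapped from the self-report. Folds whose
#' training data miss a class are still evaluated (the absent class is simply
#' unreachable) and flagged in the per-fold outcomes.
#'
#' @param user_rows data.frame with feature columns and a `stress_score`
#'   column in \code{[0,1]} (one row per day); rows with missing feature
#'   values are dropped.
#' @param features character vector of feature names to use.
#' @param ridge logit ridge penalty.
#' @param thresholds class cut points, default `c(0.3, 0.7)`.
#' @param model_tag label stored in the result (e.g. "M_P").
#' @return object of class `cv_result`.
#' @export
leave_one_day_out_cv <- function(user_rows, features, ridge = 1e-4,
                                 thresholds = c(0.3, 0.7), model_tag = "M") {
  df <- as.data.frame(user_rows)
  ok <- complete.cases(df[, features, drop = FALSE]) & !is.na(df$stress_score)
  df <- df[ok, , drop = FALSE]
  n <- nrow(df)
  if (n < 3L) stopf("need at least 3 labeled days")
  y <- map_score_to_class(df$stress_score, thresholds)
  X <- df[, features, drop = FALSE]
  out <- data.frame(fold = seq_len(n), true = y, pred = NA_integer_,
                    correct = NA, missing_class_in_train = NA)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    fit <- suppressWarnings(fit_logit(X[-i, , drop = FALSE], ytr, ridge = ridge))
    out$pred[i] <- suppressWarnings(
      predict(fit, X[i, , drop = FALSE], type = "class"))
    out$missing_class_in_train[i] <- length(unique(ytr)) < 3L
  }
  out$correct <- out$pred == out$true
  cv_result(model_tag, "LODO", out)
}

#' Leave-one-participant-out cross-validation (general model)
#'
#' One fold per user: the model is trained on all other users' rows and
#' evaluated on the held-out user's rows; accuracy is pooled over all
#' held-out rows.
#'
#' @param all_rows data.frame with `subject_id`, feature columns and
#'   `stress_score`.
#' @param features feature names to use.
#' @param ridge logit ridge penalty.
#' @param thresholds class cut points.
#' @param model_tag label stored in the result.
#' @return object of class `cv_result`; `per_fold_outcomes` has one row per
#'   held-out day with the user in `subject_id`.
#' @export
leave_one_participant_out_cv <- function(all_rows, features, ridge = 1e-4,
                                         thresholds = c(0.3, 0.7),
                                         model_tag = "M") {
  df <- as.data.frame(all_rows)
  ok <- complete.cases(df[, features, drop = FALSE]) & !is.na(df$stress_score)
  df <- df[ok, , drop = FALSE]
  users <- unique(df$subject_id)
  if (length(users) < 3L) stopf("need at least 3 users")
  y <- map_score_to_class(df$stress_score, thresholds)
  X <- df[, features, drop = FALSE]
  out <- NULL
  for (k in seq_along(users)) {
    te <- df$subject_id == users[k]
    ytr <- y[!te]
    fit <- suppressWarnings(fit_logit(X[!te, , drop = FALSE], ytr,
                                      ridge = ridge))
    pred <- suppressWarnings(predict(fit, X[te, , drop = FALSE],
                                     type = "class"))
    out <- rbind(out, data.frame(fold = k, subject_id = users[k],
                                 true = y[te], pred = pred,
                                 correct = pred == y[te],
                                 missing_class_in_train =
                                   length(unique(ytr)) < 3L))
  }
  cv_result(model_tag, "LOPO", out)
}

#' Run the full model-evaluation study
#'
#' From a day-aligned feature table (one row per subject-day with phone
#' features, HRV features and the self-report score), evaluates the three
#' models — phone-only `M_P`, HRV-only `M_H`, and all-features `M` — under
#' both protocols: user-specific leave-one-day-out for every user with at
#' least `config$study$min_nights` labeled nights (unweighted mean accuracy
#' across users), and the general leave-one-participant-out model. Days
#' without an HRV recording are excluded throughout, so both modalities
#' always describe the same days. Feature sets are first reduced by pooled
#' correlation analysis per modality; when `config$study$run_selection` is
#' `TRUE`, per-user sequential forward selection additionally picks each
#' user's subset for the user-specific models.
#'
#' @param dataset data.frame with `subject_id`, `date`, phone and HRV feature
#'   columns and `stress_score`.
#' @param config configuration list (see [default_config()]).
#' @param seed integer seed for fold construction inside selection.
#' @return object of class `study_report` with accuracies for 3 models x 2
#'   protocols, per-user detail and the feature sets used.
#' @export
run_study <- function(dataset, config = default_config(), seed = config$seed) {
  df <- as.data.frame(dataset)
  hrv_feats <- intersect(hrv_feature_names(), names(df))
  phone_feats <- intersect(phone_feature_names(), names(df))
  if (!length(hrv_feats) || !length(phone_feats))
    stopf("dataset must contain phone and HRV feature columns")
  has_hrv <- rowSums(!is.na(df[, hrv_feats, drop = FALSE])) > 0
  df <- df[has_hrv & !is.na(df$stress_score), , drop = FALSE]

  reduce_set <- function(feats) {
    sub <- df[, feats, drop = FALSE]
    usable <- feats[vapply(sub, function(v) sum(!is.na(v)) >= 3, logical(1))]
    if (length(usable) < 2L) return(usable)
    rep <- suppressWarnings(correlation_reduce(
      df[, usable, drop = FALSE],
      config$selection$r_threshold, config$selection$p_threshold))
    rep$kept
  }
  phone_kept <- reduce_set(phone_feats)
  hrv_kept <- reduce_set(hrv_feats)
  sets <- list(M_P = phone_kept, M_H = hrv_kept, M = c(phone_kept, hrv_kept))

  thr <- config$model$class_thresholds
  ridge <- config$model$ridge
  counts <- table(df$subject_id)
  eligible <- names(counts)[counts >= config$study$min_nights]

  user_specific <- list()
  per_user <- NULL
  for (tag in names(sets)) {
    accs <- numeric(0)
    for (u in eligible) {
      rows <- df[df$subject_id == u, , drop = FALSE]
      feats <- sets[[tag]]
      if (isTRUE(config$study$run_selection)) {
        sel <- tryCatch(sequential_forward_select(
          rows[, feats, drop = FALSE],
          map_score_to_class(rows$stress_score, thr),
          folds = config$selection$folds,
          seed = derive_seed(seed, u, tag),
          min_improvement = config$selection$min_improvement,
          ridge = ridge), error = function(e) NULL)
        if (!is.null(sel) && length(sel$ordered_features))
          feats <- sel$ordered_features
      }
      acc <- tryCatch(
        leave_one_day_out_cv(rows, feats, ridge, thr, tag)$accuracy,
        error = function(e) NA_real_)
      accs <- c(accs, acc)
      per_user <- rbind(per_user,
                        data.frame(subject_id = u, model = tag,
                                   n_days = nrow(rows), accuracy = acc))
    }
    user_specific[[tag]] <- if (length(accs)) mean(accs, na.rm = TRUE)
                            else NA_real_
  }
  if (!length(eligible))
    warning("no user meets the minimum-nights threshold; user-specific section empty",
            call. = FALSE)

  general <- list()
  for (tag in names(sets)) {
    general[[tag]] <- tryCatch(
      leave_one_participant_out_cv(df, sets[[tag]], ridge, thr, tag)$accuracy,
      error = function(e) NA_real_)
  }

  structure(list(user_specific = user_specific, general = general,
                 per_user = per_user, feature_sets = sets,
                 n_users = length(unique(df$subject_id)),
                 n_days = nrow(df), eligible_users = eligible,
                 seed = seed),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d users, %d aligned days (%d eligible for user-specific models)\n",
              x$n_users, x$n_days, length(x$eligible_users)))
  cat("  user-specific LODO: ",
      paste(sprintf("%s %.3f", names(x$user_specific),
                    unlist(x$user_specific)), collapse = ", "), "\n")
  cat("  general LOPO:       ",
      paste(sprintf("%s %.3f", names(x$general), unlist(x$general)),
            collapse = ", "), "\n")
  invisible(x)
}
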