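# Stress scoring core: ridge-penalised multinomial logistic regression with
# reference class 0, class mapping, daily stress score, modality fusion,
# long-term stress filtering and the relative-slider transform.

#' Map a self-reported stress score to a stress class
#'
#' The continuous score in \code{[0,1]} is segmented into three ordinal
#' classes: 0 (low) for score <= 0.3, 1 (moderate) for 0.3 < score < 0.7 and
#' 2 (high) for score >= 0.7.
#'
#' @param s numeric vector of scores in \code{[0,1]}.
#' @param thresholds the two cut points, default `c(0.3, 0.7)`.
#' @return integer vector of classes in \{0, 1, 2\}.
#' @export
map_score_to_class <- function(s, thresholds = c(0.3, 0.7)) {
  if (any(is.na(s)) || any(s < 0 | s > 1)) stopf("scores must lie in [0,1]")
  ifelse(s <= thresholds[1], 0L, ifelse(s >= thresholds[2], 2L, 1L))
}

# Design matrix with intercept from a data.frame/matrix of features.
logit_design <- function(x, feature_names) {
  if (is.vector(x) && !is.null(names(x))) x <- as.data.frame(as.list(x))
  x <- as.data.frame(x)
  miss <- setdiff(feature_names, names(x))
  if (length(miss)) stopf("missing feature(s): %s", paste(miss, collapse = ", "))
  m <- as.matrix(x[, feature_names, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stopf("missing feature values are not allowed here")
  cbind(`(intercept)` = 1, m)
}

#' Fit the three-class stress logit model
#'
#' Maximum-likelihood multinomial logistic regression with reference class 0
#' and a small ridge penalty on the non-intercept coefficients, which keeps
#' the optimum finite on separable data (per-user training sets can be as
#' small as ten nights). The objective is the mean negative log-likelihood
#' plus `ridge * sum(beta^2)`, so duplicating every observation leaves the
#' fit unchanged. The fit is a full Newton iteration and is deterministic
#' given the inputs.
#'
#' Classes absent from `y` trigger a degenerate-fit warning; their predicted
#' probability is 0.
#'
#' @param x data.frame or matrix of features (no missing values).
#' @param y integer classes in \{0, 1, 2\}, one per row of `x`.
#' @param ridge ridge penalty, default 1e-4.
#' @param classes the full class set, default `0:2`.
#' @return object of class `stress_logit` with coefficients `beta`
#'   (rows intercept + features, one column per non-reference observed
#'   class), `feature_names`, `classes` and fit diagnostics.
#' @export
fit_logit <- function(x, y, ridge = 1e-4, classes = 0:2) {
  x <- as.data.frame(x)
  feature_names <- names(x)
  X <- logit_design(x, feature_names)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stopf("x and y lengths differ")
  if (!all(y %in% classes)) stopf("labels must lie in {%s}",
                                  paste(classes, collapse = ", "))
  obs <- sort(unique(y))
  if (!all(classes %in% obs))
    warning(sprintf("degenerate fit: class(es) %s absent from training data",
                    paste(setdiff(classes, obs), collapse = ", ")),
            call. = FALSE)
  n <- nrow(X); d <- ncol(X)
  K <- length(obs)
  model <- structure(list(feature_names = feature_names, classes = classes,
                          observed = obs, ridge = ridge, n = n),
                     class = "stress_logit")
  if (K == 1L) {       # single observed class: predict it with certainty
    model$beta <- matrix(numeric(0), nrow = d, ncol = 0,
                         dimnames = list(colnames(X), NULL))
    model$converged <- TRUE
    return(model)
  }
  ref <- obs[1]
  nonref <- obs[-1]
  Yind <- vapply(nonref, function(k) as.numeric(y == k), numeric(n))
  np <- d * (K - 1)
  pen <- rep(c(0, rep(1, d - 1)), K - 1)   # intercepts unpenalised
  b <- numeric(np)
  objective <- function(b) {
    B <- matrix(b, nrow = d)
    eta <- X %*% B
    zmax <- pmax(0, apply(eta, 1, max))
    lse <- zmax + log(exp(-zmax) + rowSums(exp(eta - zmax)))
    -mean(rowSums(Yind * eta) - lse) + ridge * sum((b * pen)^2)
  }
  for (iter in 1:200) {
    B <- matrix(b, nrow = d)
    eta <- X %*% B
    zmax <- pmax(0, apply(eta, 1, max))
    den <- exp(-zmax) + rowSums(exp(eta - zmax))
    P <- exp(eta - zmax) / den                   # n x (K-1)
    grad <- numeric(np)
    H <- matrix(0, np, np)
    for (j in seq_len(K - 1)) {
      rj <- (j - 1) * d + seq_len(d)
      grad[rj] <- crossprod(X, P[, j] - Yind[, j]) / n +
        2 * ridge * pen[rj] * b[rj]
      for (k in seq_len(K - 1)) {
        rk <- (k - 1) * d + seq_len(d)
        wjk <- if (j == k) P[, j] * (1 - P[, j]) else -P[, j] * P[, k]
        H[rj, rk] <- crossprod(X, X * wjk) / n
      }
      H[rj, rj] <- H[rj, rj] + diag(2 * ridge * pen[rj], d)
    }
    if (max(abs(grad)) < 1e-10) break
    # Levenberg-style damping if the Hessian is numerically singular
    # (tiny separable fits with many features)
    step <- NULL
    damp <- 0
    for (try in 0:6) {
      step <- tryCatch(solve(H + diag(damp, np), grad),
                       error = function(e) NULL)
      if (!is.null(step)) break
      damp <- if (damp == 0) 1e-8 * max(1, max(abs(diag(H)))) else damp * 100
    }
    if (is.null(step)) break
    f0 <- objective(b)
    lam <- 1
    repeat {
      bn <- b - lam * step
      if (objective(bn) <= f0 + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    if (max(abs(bn - b)) < 1e-12) { b <- bn; break }
    b <- bn
  }
  beta <- matrix(b, nrow = d,
                 dimnames = list(colnames(X), as.character(nonref)))
  model$beta <- beta
  model$reference <- ref
  model$converged <- max(abs(grad)) < 1e-6
  model$logLik <- -objective(b) * n
  model
}

#' @export
print.stress_logit <- function(x, ...) {
  cat(sprintf("Multinomial stress logit: %d features, classes {%s}, n = %d\n",
              length(x$feature_names), paste(x$classes, collapse = ", "), x$n))
  if (length(x$observed) < length(x$classes))
    cat(sprintf("  degenerate: observed classes {%s}\n",
                paste(x$observed, collapse = ", ")))
  if (ncol(x$beta %||% matrix(0, 0, 0)) > 0) {
    cat(sprintf("  reference class %s; ridge %.3g\n", x$reference, x$ridge))
    print(round(x$beta, 4))
  }
  invisible(x)
}

#' @export
coef.stress_logit <- function(object, ...) object$beta

#' @export
summary.stress_logit <- function(object, ...) {
  out <- list(model = object,
              n = object$n,
              k_features = length(object$feature_names),
              observed = object$observed,
              converged = object$converged,
              logLik = object$logLik %||% NA_real_)
  class(out) <- "summary.stress_logit"
  out
}

#' @export
print.summary.stress_logit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  log-likelihood %.4f, converged: %s\n",
              x$logLik, x$converged))
  invisible(x)
}

#' Class probabilities for new feature rows
#'
#' Softmax of the linear predictors; probabilities over the full class set
#' sum to one, with zero probability on classes unseen in training.
#'
#' @param object a fitted `stress_logit`.
#' @param newdata data.frame of features, or a single named numeric vector.
#' @param type `"probs"` (matrix of class probabilities), `"class"`
#'   (argmax with ties toward the lower class) or `"ds"` (daily stress
#'   scores).
#' @param ... unused.
#' @return matrix n x 3 of probabilities, integer classes, or numeric scores.
#' @export
predict.stress_logit <- function(object, newdata,
                                 type = c("probs", "class", "ds"), ...) {
  type <- match.arg(type)
  X <- logit_design(newdata, object$feature_names)
  n <- nrow(X)
  K_all <- length(object$classes)
  probs <- matrix(0, n, K_all,
                  dimnames = list(NULL, as.character(object$classes)))
  if (length(object$observed) == 1L) {
    probs[, as.character(object$observed)] <- 1
  } else {
    eta <- X %*% object$beta
    zmax <- pmax(0, apply(eta, 1, max))
    den <- exp(-zmax) + rowSums(exp(eta - zmax))
    probs[, as.character(object$reference)] <- exp(-zmax) / den
    probs[, colnames(object$beta)] <- exp(eta - zmax) / den
  }
  switch(type,
         probs = probs,
         class = apply(probs, 1, function(p) object$classes[which.max(p)]),
         ds = as.numeric(probs %*% seq(0, 1, length.out = K_all)))
}

#' Class probabilities for a single feature vector
#'
#' @param model a fitted `stress_logit`.
#' @param x named numeric vector (or one-row data.frame) of features.
#' @return named numeric vector `(p0, p1, p2)` summing to one.
#' @export
predict_probs <- function(model, x) {
  p <- predict(model, x, type = "probs")
  stats::setNames(as.numeric(p[1, ]), colnames(p))
}

#' Simulate class labels from a fitted stress logit
#'
#' @param object fitted `stress_logit`.
#' @param nsim number of replicate label vectors.
#' @param seed optional integer seed.
#' @param newdata feature rows to simulate labels for.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated classes.
#' @export
simulate.stress_logit <- function(object, nsim = 1, seed = NULL,
                                  newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata, type = "probs")
  out <- replicate(nsim, apply(p, 1, function(pr)
    sample(object$classes, 1, prob = pr)))
  as.data.frame(out)
}

#' Pick the most probable class
#'
#' Argmax over the class probabilities; ties are broken toward the lower
#' class index.
#'
#' @param probs numeric vector of class probabilities (classes 0, 1, 2 in
#'   order).
#' @return integer class.
#' @export
classify <- function(probs) {
  probs <- as.numeric(probs)
  (seq_along(probs) - 1L)[which.max(probs)]
}

#' Daily stress score from class probabilities
#'
#' The probability-weighted score \code{DS = p0*0 + p1*0.5 + p2*1}, a
#' continuous acute-stress value in \code{[0,1]}.
#'
#' @param probs numeric vector `(p0, p1, p2)`.
#' @return scalar in \code{[0,1]}.
#' @export
daily_score <- function(probs) {
  probs <- as.numeric(probs)
  if (length(probs) != 3L) stopf("probs must have three components")
  sum(probs * c(0, 0.5, 1))
}

#' Class prior under a uniform stress score
#'
#' If the self-reported score were uniform on \code{[0,1]}, the three classes
#' would occur with probabilities `thr1`, `thr2 - thr1` and `1 - thr2`; with
#' the default 0.3/0.7 cut points the moderate band dominates at 0.40, the
#' chance baseline of the three-class problem.
#'
#' @param thresholds class cut points, default `c(0.3, 0.7)`.
#' @return named probability vector `(p0, p1, p2)`.
#' @export
uniform_class_prior <- function(thresholds = c(0.3, 0.7)) {
  c(p0 = thresholds[1], p1 = thresholds[2] - thresholds[1],
    p2 = 1 - thresholds[2])
}

#' A-priori fusion weights from per-modality accuracies
#'
#' Normalizes the classification accuracies of the phone-only and HRV-only
#' models into convex weights.
#'
#' @param acc_p,acc_h non-negative accuracies, not both zero.
#' @return `list(w_p =, w_h =)` with `w_p + w_h = 1`.
#' @export
fusion_weights <- function(acc_p, acc_h) {
  if (acc_p < 0 || acc_h < 0) stopf("accuracies must be >= 0")
  tot <- acc_p + acc_h
  if (tot == 0) stopf("at least one accuracy must be positive")
  list(w_p = acc_p / tot, w_h = acc_h / tot)
}

#' Fuse per-modality daily stress scores
#'
#' Convex combination \code{DS = w_p * DS_p + w_h * DS_h}. If one modality is
#' missing its weight is renormalized onto the other; with both missing the
#' result is `NA` (no-score marker).
#'
#' @param ds_p,ds_h daily scores in \code{[0,1]} or `NA`.
#' @param w fusion weights from [fusion_weights()].
#' @return fused score or `NA`.
#' @export
fuse_daily_score <- function(ds_p, ds_h, w) {
  if (is.na(ds_p) && is.na(ds_h)) return(NA_real_)
  if (is.na(ds_p)) return(ds_h)
  if (is.na(ds_h)) return(ds_p)
  w$w_p * ds_p + w$w_h * ds_h
}

#' Fuse per-modality class probabilities and classify
#'
#' Weighted probability fusion \code{q_i = w_p p_i_phone + w_h p_i_hrv},
#' then the usual argmax with ties toward the lower class. Used when no
#' common (both-modality) model is available.
#'
#' @param probs_p,probs_h probability vectors `(p0, p1, p2)`.
#' @param w fusion weights.
#' @return integer class.
#' @export
fuse_classify <- function(probs_p, probs_h, w) {
  q <- w$w_p * as.numeric(probs_p) + w$w_h * as.numeric(probs_h)
  classify(q)
}

#' Long-term stress state
#'
#' @param value current long-term stress in \code{[0,1]}.
#' @param filter_alpha first-order low-pass filter coefficient in (0,1]; the
#'   maximum change of the long-term score from one day to the next.
#' @return object of class `lts_state`.
#' @export
lts_state <- function(value, filter_alpha = 0.1) {
  if (is.na(value) || value < 0 || value > 1) stopf("LTS value must lie in [0,1]")
  if (filter_alpha <= 0 || filter_alpha > 1) stopf("filter_alpha must lie in (0,1]")
  structure(list(value = value, filter_alpha = filter_alpha),
            class = "lts_state")
}

#' @export
print.lts_state <- function(x, ...) {
  cat(sprintf("LTS = %.4f (alpha = %g)\n", x$value, x$filter_alpha))
  invisible(x)
}

#' Initialize the long-term stress score
#'
#' The starting value is the mean of the daily stress scores observed over
#' the training days.
#'
#' @param training_ds non-empty numeric vector of daily scores.
#' @param filter_alpha filter coefficient, default 0.1.
#' @return an [lts_state()].
#' @export
init_lts <- function(training_ds, filter_alpha = 0.1) {
  training_ds <- training_ds[!is.na(training_ds)]
  if (length(training_ds) == 0L) stopf("no training daily scores available")
  lts_state(mean(training_ds), filter_alpha)
}

#' One-day update of the long-term stress score
#'
#' First-order low-pass filter
#' \code{LTS' = LTS + alpha * (class/2 - LTS)}: the step never exceeds
#' `alpha` in magnitude and the score stays in \code{[0,1]}.
#'
#' @param state an [lts_state()].
#' @param day_class the day's stress class (0, 1 or 2).
#' @return updated [lts_state()].
#' @export
update_lts <- function(state, day_class) {
  stopifnot(inherits(state, "lts_state"))
  if (!day_class %in% 0:2) stopf("day_class must be 0, 1 or 2")
  a <- state$filter_alpha
  state$value <- state$value + a * (day_class / 2 - state$value)
  state
}

#' Turn a relative slider answer into an absolute stress score
#'
#' The relative questions ("compared to yesterday / last week") start at the
#' neutral middle (0.5). Moving toward an end covers up to a fraction
#' `slider_alpha` (default 0.75) of the distance from the reference value
#' toward 0 (below middle) or toward 1 (above middle):
#' \deqn{out = ref - ref (1 - in/0.5) \alpha \quad (in \le 0.5)}
#' \deqn{out = ref + (1 - ref) ((in - 0.5)/0.5) \alpha \quad (in > 0.5)}
#'
#' @param input slider position in \code{[0,1]}.
#' @param ref reference score in \code{[0,1]} (yesterday's score, or the
#'   last-week average).
#' @param slider_alpha gain in (0,1], default 0.75.
#' @return absolute score in \code{[0,1]}.
#' @export
slider_to_absolute <- function(input, ref, slider_alpha = 0.75) {
  if (is.na(input) || input < 0 || input > 1) stopf("slider input must lie in [0,1]")
  if (is.na(ref) || ref < 0 || ref > 1) stopf("reference must lie in [0,1]")
  if (slider_alpha <= 0 || slider_alpha > 1) stopf("slider_alpha must lie in (0,1]")
  if (input <= 0.5) {
    ref - ref * (1 - input / 0.5) * slider_alpha
  } else {
    ref + (1 - ref) * ((input - 0.5) / 0.5) * slider_alpha
  }
}

#' Combine the absolute and relative daily stress answers
#'
#' The day's overall self-report is the mean of the absolute answer and the
#' two relative answers after the slider transform; missing answers are
#' dropped from the mean. The yesterday reference is yesterday's score; the
#' last-week reference is the mean of the last (up to) seven available daily
#' scores.
#'
#' @param absolute absolute answer in \code{[0,1]} or `NA`.
#' @param rel_yesterday,rel_lastweek relative slider answers or `NA`.
#' @param ref_yesterday,ref_lastweek reference values or `NA`.
#' @param slider_alpha slider gain, default 0.75.
#' @return combined score, or `NA` if no answer is available.
#' @export
combine_daily_inputs <- function(absolute, rel_yesterday = NA,
                                 rel_lastweek = NA, ref_yesterday = NA,
                                 ref_lastweek = NA, slider_alpha = 0.75) {
  vals <- c(
    if (!is.na(absolute)) absolute,
    if (!is.na(rel_yesterday) && !is.na(ref_yesterday))
      slider_to_absolute(rel_yesterday, ref_yesterday, slider_alpha),
    if (!is.na(rel_lastweek) && !is.na(ref_lastweek))
      slider_to_absolute(rel_lastweek, ref_lastweek, slider_alpha)
  )
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}
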