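# The stress-scoring core: class mapping, multinomial logit, daily and
# long-term scores, fusion, and the relative-slider transform.

test_that("score-to-class mapping honors the 0.3/0.7 boundary rules", {
  expect_identical(map_score_to_class(0.3), 0L)
  expect_identical(map_score_to_class(0.7), 2L)
  expect_identical(map_score_to_class(0.5), 1L)
  expect_identical(map_score_to_class(c(0, 0.31, 0.69, 1)), c(0L, 1L, 1L, 2L))
  expect_error(map_score_to_class(1.2), "\\[0,1\\]")
})

test_that("the uniform-score class prior peaks at 40% moderate", {
  pr <- uniform_class_prior()
  expect_equal(unname(pr), c(0.3, 0.4, 0.3))
  expect_equal(sum(pr), 1)
})

test_that("the logit fit is symmetric, duplication-invariant and calibrated", {
  # symmetric two-class data about the origin: intercept ~ 0
  x <- data.frame(f = c(-2, -1, -0.5, 0.5, 1, 2))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  fit <- suppressWarnings(fit_logit(x, y, ridge = 1e-4))
  expect_lt(abs(coef(fit)["(intercept)", "1"]), 1e-6)

  # duplicating every row leaves the coefficients unchanged
  fit2 <- suppressWarnings(fit_logit(rbind(x, x), c(y, y), ridge = 1e-4))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)

  # mean predicted probabilities reproduce the class frequencies (ridge -> 0)
  set.seed(2)
  n <- 600
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  eta1 <- 0.3 + X$a; eta2 <- -0.2 + 1.5 * X$b
  P <- exp(cbind(0, eta1, eta2)); P <- P / rowSums(P)
  yy <- apply(P, 1, function(p) sample(0:2, 1, prob = p))
  f3 <- fit_logit(X, yy, ridge = 1e-9)
  expect_equal(unname(colMeans(predict(f3, X, type = "probs"))),
               unname(as.numeric(table(factor(yy, 0:2)) / n)),
               tolerance = 1e-6)
})

test_that("the fit recovers known coefficients from strong-signal data", {
  set.seed(4)
  n <- 2000
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  b1 <- c(0.5, 1.2, -0.8); b2 <- c(-0.3, 2.0, 0.6)
  eta1 <- b1[1] + b1[2] * X$a + b1[3] * X$b
  eta2 <- b2[1] + b2[2] * X$a + b2[3] * X$b
  P <- exp(cbind(0, eta1, eta2)); P <- P / rowSums(P)
  y <- apply(P, 1, function(p) sample(0:2, 1, prob = p))
  fit <- fit_logit(X, y, ridge = 1e-6)
  est <- coef(fit)
  expect_equal(unname(est[, "1"]), b1, tolerance = 0.15)
  expect_equal(unname(est[, "2"]), b2, tolerance = 0.15)
  # mean predicted probability of the true class beats chance comfortably
  pr <- predict(fit, X, type = "probs")
  expect_gt(mean(pr[cbind(seq_len(n), y + 1)]), 1 / 3)
})

test_that("the logit agrees with an independent optimizer", {
  skip_if_not_installed("nnet")
  set.seed(9)
  n <- 800
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  eta1 <- 0.4 + X$a - 0.5 * X$b; eta2 <- -0.6 + 1.2 * X$a
  P <- exp(cbind(0, eta1, eta2)); P <- P / rowSums(P)
  y <- apply(P, 1, function(p) sample(0:2, 1, prob = p))
  ours <- coef(fit_logit(X, y, ridge = 1e-10))
  ref <- nnet::multinom(factor(y) ~ a + b, data = X, trace = FALSE,
                        reltol = 1e-14, maxit = 500)
  refc <- t(coef(ref))
  rownames(refc)[1] <- "(intercept)"
  expect_equal(ours, refc[rownames(ours), colnames(ours)], tolerance = 1e-4)
})

test_that("degenerate training sets are handled explicitly", {
  x <- data.frame(f = rnorm(8))
  expect_warning(fit <- fit_logit(x, rep(1L, 8)), "degenerate")
  p <- predict_probs(fit, c(f = 0))
  expect_equal(unname(p), c(0, 1, 0))
  expect_warning(fit2 <- fit_logit(x, rep(c(0L, 2L), 4)), "degenerate")
  p2 <- predict_probs(fit2, c(f = 0))
  expect_equal(unname(p2["1"]), 0)
  expect_equal(sum(p2), 1, tolerance = 1e-9)
})

test_that("prediction normalizes, classifies and refuses missing features", {
  set.seed(1)
  x <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- rep(0:2, 10)
  fit <- fit_logit(x, y)
  p <- predict(fit, x, type = "probs")
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 30), tolerance = 1e-9)
  expect_error(predict(fit, data.frame(a = 1)), "missing feature")
  expect_error(predict(fit, data.frame(a = 1, b = NA_real_)), "missing")
})

test_that("classification breaks ties toward the lower class", {
  expect_identical(classify(c(0.15, 0.3, 0.55)), 2L)
  expect_identical(classify(c(1, 1, 1) / 3), 0L)
  expect_identical(classify(c(0.5, 0.5, 0)), 0L)
  expect_identical(classify(c(0, 0.5, 0.5)), 1L)
})

test_that("the daily stress score is the probability-weighted class mean", {
  expect_equal(daily_score(c(0.15, 0.3, 0.55)), 0.70)
  expect_equal(daily_score(c(1, 0, 0)), 0)
  expect_equal(daily_score(c(0, 0, 1)), 1)
  # monotone: moving mass from p0 to p2 never decreases DS
  set.seed(3)
  for (i in 1:20) {
    p <- runif(3); p <- p / sum(p)
    eps <- runif(1, 0, p[1])
    expect_gte(daily_score(p + c(-eps, 0, eps)), daily_score(p))
  }
})

test_that("fusion weights normalize accuracies and fusion falls back", {
  w <- fusion_weights(0.55, 0.59)
  expect_equal(w$w_p, 0.55 / 1.14)
  expect_equal(w$w_h, 0.59 / 1.14)
  expect_equal(fusion_weights(0.4, 0.4), list(w_p = 0.5, w_h = 0.5))
  expect_equal(fusion_weights(0.7, 0), list(w_p = 1, w_h = 0))
  expect_error(fusion_weights(0, 0), "positive")

  expect_equal(fuse_daily_score(0.2, 0.8, list(w_p = 0.5, w_h = 0.5)), 0.5)
  expect_equal(fuse_daily_score(0.6, 0.6, list(w_p = 0.9, w_h = 0.1)), 0.6)
  expect_equal(fuse_daily_score(0.3, NA, w), 0.3)
  expect_equal(fuse_daily_score(NA, 0.9, w), 0.9)
  expect_true(is.na(fuse_daily_score(NA, NA, w)))
})

test_that("probability-level fusion reproduces single-modality decisions", {
  pp <- c(1, 0, 0); ph <- c(0, 0, 1)
  expect_identical(fuse_classify(pp, ph, list(w_p = 0.6, w_h = 0.4)), 0L)
  expect_identical(fuse_classify(pp, ph, list(w_p = 1, w_h = 0)), classify(pp))
  expect_identical(fuse_classify(pp, ph, list(w_p = 0, w_h = 1)), classify(ph))
  q <- c(0.2, 0.5, 0.3)
  expect_identical(fuse_classify(q, q, list(w_p = 0.3, w_h = 0.7)), classify(q))
})

test_that("the long-term stress filter contracts toward class/2", {
  s <- lts_state(0.5, 0.1)
  expect_equal(update_lts(s, 2)$value, 0.55)
  expect_equal(update_lts(lts_state(0.5, 0.1), 1)$value, 0.5)  # fixed point
  # geometric convergence from 0 under constant class 2
  s <- lts_state(0, 0.1)
  for (i in 1:100) s <- update_lts(s, 2)
  expect_equal(1 - s$value, (1 - 0.1)^100, tolerance = 1e-9)
  expect_equal(init_lts(c(0.2, 0.4))$value, 0.3)
  expect_equal(init_lts(rep(0.77, 5))$value, 0.77)
  expect_equal(init_lts(c(0.2, 0.4))$filter_alpha, 0.1)
  expect_error(init_lts(numeric(0)), "no training")
})

test_that("the slider transform matches its closed form and is monotone", {
  expect_equal(slider_to_absolute(0.5, 0.37), 0.37)
  expect_equal(slider_to_absolute(1.0, 0.2, 0.75), 0.8)
  expect_equal(slider_to_absolute(0.0, 0.8, 0.75), 0.2)
  for (ref in c(0, 0.25, 0.5, 0.8, 1)) {
    grid <- seq(0, 1, by = 0.01)
    out <- vapply(grid, slider_to_absolute, numeric(1), ref = ref)
    expect_true(all(diff(out) >= -1e-12))
    expect_true(all(out >= -1e-12 & out <= 1 + 1e-12))
    # continuity at the neutral middle
    expect_equal(slider_to_absolute(0.5 - 1e-9, ref),
                 slider_to_absolute(0.5 + 1e-9, ref), tolerance = 1e-6)
  }
})

test_that("daily inputs combine by mean with missing answers dropped", {
  expect_equal(combine_daily_inputs(0.6, 0.5, 0.5, 0.3, 0.9), 0.6)
  expect_equal(combine_daily_inputs(0.6, NA, NA), 0.6)
  # absolute 0.6 with transformed relatives 0.3 and 0.9 averages to 0.6
  # (rel = 0.5 leaves the reference unchanged)
  expect_equal(combine_daily_inputs(0.6, 0.5, 0.5, 0.3, 0.9),
               mean(c(0.6, 0.3, 0.9)))
  expect_true(is.na(combine_daily_inputs(NA, NA, NA)))
})
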