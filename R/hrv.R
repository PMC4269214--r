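# HRV feature extraction from one night of RR intervals: artifact rejection,
# time-domain, geometric, nonlinear and spectral (Lomb-Scargle) features.

#' Remove artifactual RR intervals
#'
#' Discards intervals deviating more than `threshold` (default 20\%) from the
#' previously *retained* interval; the first interval is always retained.
#' Comparing to the previously retained (not previous raw) interval keeps an
#' isolated ectopic spike from cascading deletions of the normal beats that
#' follow it. The filter is idempotent.
#'
#' @param rr_ms positive RR intervals in milliseconds.
#' @param threshold maximum relative deviation, default 0.2.
#' @return the retained subsequence, in original order, with a logical
#'   attribute `"kept"` marking which input positions were retained (useful
#'   for scoring the filter against known artifact positions).
#' @export
filter_rr_artifacts <- function(rr_ms, threshold = 0.2) {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) == 0L) stopf("rr_ms must be non-empty")
  if (anyNA(rr_ms) || any(rr_ms <= 0)) stopf("rr_ms must be positive")
  keep <- logical(length(rr_ms))
  keep[1] <- TRUE
  ref <- rr_ms[1]
  for (i in seq_along(rr_ms)[-1]) {
    if (abs(rr_ms[i] - ref) <= threshold * ref) {
      keep[i] <- TRUE
      ref <- rr_ms[i]
    }
  }
  structure(rr_ms[keep], kept = keep)
}

#' RR-interval histogram at 1/128 s resolution
#'
#' Bin width is exactly 1000/128 = 7.8125 ms with edges aligned at integer
#' multiples of the width, the convention behind the HRV triangular index and
#' TINN.
#'
#' @param rr_ms non-empty RR series (milliseconds).
#' @return `list(edges =, counts =, width =)`; `edges` has one more element
#'   than `counts`, and `sum(counts)` equals the series length.
#' @export
hrv_histogram <- function(rr_ms) {
  if (length(rr_ms) == 0L) stopf("rr_ms must be non-empty")
  w <- 1000 / 128
  idx <- floor(rr_ms / w)
  rng <- range(idx)
  counts <- tabulate(idx - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  edges <- (rng[1]:(rng[2] + 1L)) * w
  list(edges = edges, counts = counts, width = w)
}

#' Triangular interpolation of the RR histogram (TINN)
#'
#' Fits the triangle that is zero outside \code{[N, M]} and peaks at the modal
#' bin (modal height) to the histogram by least squares, searching `N` and `M`
#' over bin edges (extended one bin beyond the occupied range), and returns
#' the base width `M - N` in milliseconds. A single-bin histogram returns one
#' bin width.
#'
#' @param hist histogram as returned by [hrv_histogram()].
#' @return TINN in milliseconds.
#' @export
tinn <- function(hist) {
  counts <- hist$counts
  edges <- hist$edges
  w <- hist$width
  if (sum(counts > 0) == 0L) stopf("histogram has no mass")
  # pad one empty bin each side so the triangle can end just outside the data
  counts <- c(0, counts, 0)
  edges <- c(edges[1] - w, edges, edges[length(edges)] + w)
  centers <- edges[-length(edges)] + w / 2
  p <- which.max(counts)
  peak_x <- centers[p]
  peak_y <- counts[p]
  n_cand <- edges[edges <= edges[p]]            # left edge of modal bin or left
  m_cand <- edges[edges >= edges[p + 1]]        # right edge of modal bin or right
  best <- Inf; best_nm <- c(NA, NA)
  for (N in n_cand) {
    for (M in m_cand) {
      q <- numeric(length(centers))
      left <- centers >= N & centers <= peak_x
      right <- centers > peak_x & centers <= M
      if (peak_x > N) q[left] <- peak_y * (centers[left] - N) / (peak_x - N)
      else q[centers == peak_x] <- peak_y
      if (M > peak_x) q[right] <- peak_y * (M - centers[right]) / (M - peak_x)
      err <- sum((counts - q)^2)
      if (err < best - 1e-12) { best <- err; best_nm <- c(N, M) }
    }
  }
  best_nm[2] - best_nm[1]
}

#' Time-domain HRV features
#'
#' Computes sleep duration (hours, sum of intervals), mean RR, SDNN (sample
#' standard deviation), RMSSD, pNN50 (percentage of successive differences
#' exceeding 50 ms), the HRV triangular index (series length over the modal
#' height of the 1/128 s histogram) and TINN.
#'
#' @param rr_ms artifact-filtered RR series with at least 3 intervals.
#' @return named list with `sleep_duration_h`, `mean_rr_ms`, `sdnn_ms`,
#'   `rmssd_ms`, `pnn50_pct`, `hrv_index`, `tinn_ms`.
#' @export
time_domain_features <- function(rr_ms) {
  if (length(rr_ms) < 3L)
    stopf("insufficient data: need at least 3 intervals")
  d <- diff(rr_ms)
  h <- hrv_histogram(rr_ms)
  list(
    sleep_duration_h = sum(rr_ms) / 3.6e6,
    mean_rr_ms = mean(rr_ms),
    sdnn_ms = sd(rr_ms),
    rmssd_ms = sqrt(mean(d^2)),
    pnn50_pct = 100 * mean(abs(d) > 50),
    hrv_index = length(rr_ms) / max(h$counts),
    tinn_ms = tinn(h)
  )
}

#' Approximate entropy of an RR series
#'
#' Standard ApEn: \eqn{\Phi_m(r) - \Phi_{m+1}(r)} with template-match counts
#' under the Chebyshev distance, self-matches included. Large values indicate
#' an irregular signal; a constant series has ApEn 0.
#'
#' @param rr_ms numeric series, length > `m` + 1.
#' @param m template length, default 2.
#' @param r tolerance; default 0.2 x SDNN of the input.
#' @return non-negative scalar.
#' @export
approximate_entropy <- function(rr_ms, m = 2L, r = NULL) {
  if (length(rr_ms) <= m + 1L)
    stopf("insufficient data: series must be longer than m + 1")
  if (is.null(r)) r <- 0.2 * sd(rr_ms)
  if (r < 0) stopf("tolerance r must be >= 0")
  .apen_cpp(as.numeric(rr_ms), as.integer(m), as.numeric(r))
}

#' Poincare plot descriptors SD1 and SD2
#'
#' With x the series lagged by one and y the series advanced by one,
#' SD1 = sqrt(Var(y - x)/2) captures fast beat-to-beat variability and
#' SD2 = sqrt(Var(y + x)/2) the long-range variability (population variance
#' convention). The ratio is missing for a constant series (SD2 = 0).
#'
#' @param rr_ms RR series with at least 3 intervals.
#' @return `list(sd1 =, sd2 =, sd1_sd2 =)` in milliseconds (ratio unitless).
#' @export
poincare <- function(rr_ms) {
  n <- length(rr_ms)
  if (n < 3L) stopf("insufficient data: need at least 3 intervals")
  x <- rr_ms[-n]
  y <- rr_ms[-1]
  sd1 <- sqrt(var_pop(y - x) / 2)
  sd2 <- sqrt(var_pop(y + x) / 2)
  list(sd1 = sd1, sd2 = sd2,
       sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

#' Lomb-Scargle power spectral density of an unevenly sampled series
#'
#' Classical Lomb-Scargle estimator with the per-frequency time offset tau,
#' suited to RR series because beats are inherently unevenly spaced: beat k
#' occurs at the cumulative sum of the retained intervals. Values are
#' mean-subtracted internally. The default grid spans `fmin`–`fmax` with
#' spacing `1/(oversample * span)`.
#'
#' @param times_s strictly increasing sample times in seconds (>= 10).
#' @param values_ms sample values (RR intervals, milliseconds).
#' @param freq_grid optional explicit frequency grid (Hz).
#' @param fmin,fmax grid limits in Hz, defaults 0.01 and 0.4.
#' @param oversample oversampling factor, default 4.
#' @return object of class `psd`: `list(frequencies =, power =)`.
#' @export
lomb_scargle_psd <- function(times_s, values_ms, freq_grid = NULL,
                             fmin = 0.01, fmax = 0.4, oversample = 4) {
  if (length(times_s) < 10L) stopf("need at least 10 samples")
  if (length(times_s) != length(values_ms))
    stopf("times and values must have equal length")
  if (any(diff(times_s) <= 0)) stopf("times must be strictly increasing")
  if (is.null(freq_grid)) {
    span <- times_s[length(times_s)] - times_s[1]
    df <- 1 / (oversample * span)
    nstep <- ceiling((fmax - fmin) / df)
    freq_grid <- seq(fmin, fmax, length.out = nstep + 1L)
  }
  if (any(diff(freq_grid) <= 0)) stopf("frequency grid must be increasing")
  y <- values_ms - mean(values_ms)
  p <- .lomb_cpp(as.numeric(times_s), as.numeric(y), as.numeric(freq_grid))
  structure(list(frequencies = freq_grid, power = pmax(p, 0)), class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd: %d frequencies, %.4g-%.4g Hz>\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

trapz_band <- function(f, p, lo, hi) {
  if (hi <= f[1] || lo >= f[length(f)]) return(0)
  lo <- max(lo, f[1]); hi <- min(hi, f[length(f)])
  inside <- f > lo & f < hi
  fs <- c(lo, f[inside], hi)
  ps <- c(stats::approx(f, p, xout = lo)$y, p[inside],
          stats::approx(f, p, xout = hi)$y)
  pracma::trapz(fs, ps)
}

#' Spectral band powers and normalized units
#'
#' Integrates the PSD over the VLF (0.01–0.04 Hz), LF (0.04–0.15 Hz) and HF
#' (0.15–0.4 Hz) bands by the trapezoidal rule, and reports the normalized
#' units lf_nu = LF/(LF+HF), hf_nu = HF/(LF+HF) (VLF excluded from the
#' denominator, the standard HRV convention) plus the LF/HF ratio.
#'
#' @param psd a `psd` object from [lomb_scargle_psd()].
#' @param bands list with elements `vlf`, `lf`, `hf`, each `c(low, high)` Hz.
#' @return named list `vlf`, `lf`, `hf`, `lf_nu`, `hf_nu`, `lf_hf`; ratios are
#'   `NA` when the denominator is zero.
#' @export
band_powers <- function(psd, bands = default_config()$hrv$bands) {
  f <- psd$frequencies; p <- psd$power
  vlf <- trapz_band(f, p, bands$vlf[1], bands$vlf[2])
  lf <- trapz_band(f, p, bands$lf[1], bands$lf[2])
  hf <- trapz_band(f, p, bands$hf[1], bands$hf[2])
  tot <- lf + hf
  list(vlf = vlf, lf = lf, hf = hf,
       lf_nu = if (tot > 0) lf / tot else NA_real_,
       hf_nu = if (tot > 0) hf / tot else NA_real_,
       lf_hf = if (hf > 0) lf / hf else NA_real_)
}

#' Names of the 14 HRV features
#' @return character vector of feature names.
#' @export
hrv_feature_names <- function() {
  c("sleep_duration_h", "mean_rr_ms", "sdnn_ms", "rmssd_ms", "pnn50_pct",
    "hrv_index", "tinn_ms", "apen", "sd1_ms", "sd2_ms", "sd1_sd2",
    "lf_nu", "hf_nu", "lf_hf")
}

#' Extract the 14 HRV features from one night session
#'
#' Applies the artifact filter, then computes the time-domain, geometric,
#' nonlinear and frequency-domain features. Sleep duration is the sum of the
#' retained intervals. Beat times for the spectral features are the
#' cumulative sums of the retained intervals. Features that are undefined on
#' the input are returned as `NA`, never silently zero.
#'
#' @param session an [rr_session()].
#' @param config configuration list (see [default_config()]).
#' @return a [feature_vector()] with modality `"hrv"` and 14 named features.
#' @export
extract_hrv_features <- function(session, config = default_config()) {
  stopifnot(inherits(session, "rr_session"))
  hc <- config$hrv
  rr <- filter_rr_artifacts(session$rr_ms, hc$artifact_threshold)
  if (sum(rr) < hc$min_session_s * 1000)
    stopf("insufficient data: session shorter than %g s of beats",
          hc$min_session_s)
  td <- time_domain_features(rr)
  pc <- poincare(rr)
  apen <- if (length(rr) > hc$apen_m + 1L)
    approximate_entropy(rr, hc$apen_m, hc$apen_r_factor * sd(rr))
  else NA_real_
  bp <- list(lf_nu = NA_real_, hf_nu = NA_real_, lf_hf = NA_real_)
  if (length(rr) >= 10L) {
    t_s <- cumsum(rr) / 1000
    psd <- lomb_scargle_psd(t_s, rr, fmin = hc$bands$vlf[1],
                            fmax = hc$bands$hf[2], oversample = hc$oversample)
    bp <- band_powers(psd, hc$bands)
  }
  feature_vector("hrv", c(
    sleep_duration_h = td$sleep_duration_h,
    mean_rr_ms = td$mean_rr_ms,
    sdnn_ms = td$sdnn_ms,
    rmssd_ms = td$rmssd_ms,
    pnn50_pct = td$pnn50_pct,
    hrv_index = td$hrv_index,
    tinn_ms = td$tinn_ms,
    apen = apen,
    sd1_ms = pc$sd1,
    sd2_ms = pc$sd2,
    sd1_sd2 = pc$sd1_sd2,
    lf_nu = bp$lf_nu,
    hf_nu = bp$hf_nu,
    lf_hf = bp$lf_hf
  ))
}
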