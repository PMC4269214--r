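#' Default pipeline configuration
#'
#' Returns the full configuration tree with the package defaults. Every
#' tunable threshold, band edge, filter coefficient and seed used by the
#' pipeline lives here, so a JSON config file only needs to override the
#' values it changes.
#'
#' Defaults:
#' \itemize{
#'   \item \code{hrv$artifact_threshold} 0.2 — RR intervals deviating more
#'     than 20\% from the previously retained interval are discarded.
#'   \item \code{hrv$apen_m} 2, \code{hrv$apen_r_factor} 0.2 — approximate
#'     entropy template length and tolerance factor (r = factor x SDNN).
#'   \item \code{hrv$bands} VLF 0.01–0.04 Hz, LF 0.04–0.15 Hz,
#'     HF 0.15–0.4 Hz.
#'   \item \code{hrv$oversample} 4 — Lomb–Scargle grid spacing 1/(oversample
#'     x span).
#'   \item \code{hrv$min_session_s} 300 — sessions shorter than 5 minutes of
#'     beats are rejected.
#'   \item \code{phone$chunk_ms} 50, \code{phone$audio_seed} 1 — audio
#'     anonymization chunk size and permutation seed.
#'   \item \code{phone$dbscan_eps_m} 100, \code{phone$dbscan_min_pts} 5 —
#'     location clustering parameters.
#'   \item \code{model$ridge} 1e-4 — ridge penalty of the multinomial logit.
#'   \item \code{model$filter_alpha} 0.1 — long-term stress filter
#'     coefficient.
#'   \item \code{model$slider_alpha} 0.75 — relative-slider gain.
#'   \item \code{model$class_thresholds} c(0.3, 0.7) — low/moderate/high
#'     stress-score cut points.
#'   \item \code{selection$r_threshold} 0.8, \code{selection$p_threshold}
#'     0.01, \code{selection$folds} 10, \code{selection$min_improvement} 0.
#'   \item \code{study$min_nights} 10 — user-specific models require at
#'     least this many labeled nights.
#'   \item \code{study$run_selection} TRUE — run per-user sequential forward
#'     selection before the user-specific cross-validation.
#' }
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    hrv = list(
      artifact_threshold = 0.2,
      apen_m = 2L,
      apen_r_factor = 0.2,
      bands = list(vlf = c(0.01, 0.04), lf = c(0.04, 0.15),
                   hf = c(0.15, 0.40)),
      oversample = 4,
      min_session_s = 300
    ),
    phone = list(
      chunk_ms = 50,
      audio_seed = 1L,
      dbscan_eps_m = 100,
      dbscan_min_pts = 5L
    ),
    model = list(
      ridge = 1e-4,
      filter_alpha = 0.1,
      slider_alpha = 0.75,
      class_thresholds = c(0.3, 0.7)
    ),
    selection = list(
      r_threshold = 0.8,
      p_threshold = 0.01,
      folds = 10L,
      min_improvement = 0
    ),
    study = list(
      min_nights = 10L,
      run_selection = TRUE
    )
  )
}

#' Read a JSON configuration file
#'
#' Values present in the file override the corresponding entries of
#' [default_config()]; everything else keeps its default.
#'
#' @param path path to a JSON file, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  modifyList(cfg, user)
}
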