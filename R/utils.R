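# Internal helpers shared across modules.

#' Parse ISO-8601 timestamps to epoch seconds
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` with an optional fractional part and a
#' timezone designator: `Z`, `+HH:MM` or `+HHMM`. A timestamp without a
#' designator is taken as UTC. Returns the epoch second (numeric); the local
#' civil date of a timestamp is its first ten characters, which is how
#' day-membership is validated throughout the package.
#'
#' @param x character vector of timestamps.
#' @return numeric vector of seconds since 1970-01-01T00:00:00Z.
#' @keywords internal
parse_iso8601 <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  m <- regmatches(x, regexec(
    "^(\\d{4}-\\d{2}-\\d{2})[T ](\\d{2}:\\d{2}:\\d{2})(\\.\\d+)?(Z|[+-]\\d{2}:?\\d{2})?$",
    x))
  out <- vapply(seq_along(x), function(i) {
    p <- m[[i]]
    if (length(p) == 0L || p[1] == "") {
      stop("malformed timestamp: ", x[i], call. = FALSE)
    }
    base <- as.POSIXct(paste(p[2], p[3]), tz = "UTC",
                       format = "%Y-%m-%d %H:%M:%S")
    if (is.na(base)) stop("malformed timestamp: ", x[i], call. = FALSE)
    frac <- if (nzchar(p[4])) as.numeric(p[4]) else 0
    off <- 0
    tzs <- p[5]
    if (nzchar(tzs) && tzs != "Z") {
      tzs <- gsub(":", "", tzs)
      sgn <- if (substr(tzs, 1, 1) == "-") -1 else 1
      off <- sgn * (as.numeric(substr(tzs, 2, 3)) * 3600 +
                    as.numeric(substr(tzs, 4, 5)) * 60)
    }
    as.numeric(base) + frac - off
  }, numeric(1))
  out
}

# Local civil date (YYYY-MM-DD) of an ISO-8601 timestamp string.
iso_date <- function(x) substr(x, 1, 10)

# Population variance (denominator n); stats::var uses n - 1.
var_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

# Format numerics for CSV so a round trip preserves 12+ significant digits.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.15g", v)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Deterministic child seed (< 2^31) from a base seed and stream labels.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
  })))
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}
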