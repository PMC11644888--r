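#' Read a frequency series from CSV
#'
#' Expects the two-column format `time_s,frequency_hz` written by
#' [write_series()] or by an acquisition front end. Timestamps must be
#' strictly increasing; violations are reported with the offending data
#' line number.
#'
#' @param path CSV file path.
#' @return A tibble with columns `time_s`, `frequency_hz`.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE),
    error = function(e) abort(sprintf("could not parse %s: %s", path, conditionMessage(e)))
  )
  if (!all(c("time_s", "frequency_hz") %in% names(df))) {
    abort(sprintf("%s must have columns time_s, frequency_hz.", path))
  }
  if (nrow(df) == 0) abort(sprintf("%s contains no samples.", path))
  if (!is.numeric(df$time_s) || !is.numeric(df$frequency_hz)) {
    abort(sprintf("%s: time_s and frequency_hz must be numeric.", path))
  }
  if (anyNA(df$time_s) || anyNA(df$frequency_hz)) {
    bad <- which(is.na(df$time_s) | is.na(df$frequency_hz))[1]
    abort(sprintf("%s: missing value at data line %d.", path, bad))
  }
  dtime <- diff(df$time_s)
  if (any(dtime <= 0)) {
    bad <- which(dtime <= 0)[1] + 1L
    abort(sprintf(
      "%s: time_s not strictly increasing at data line %d (t = %g).",
      path, bad, df$time_s[bad]
    ))
  }
  tibble::as_tibble(df[c("time_s", "frequency_hz")])
}

#' Write a frequency series to CSV
#'
#' Full double precision, so a write/read round trip reproduces the series
#' exactly to within parsing precision.
#'
#' @param series Data frame with `time_s`, `frequency_hz`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  series <- as_series(series)
  uniform_ok <- !is.unsorted(series$time_s, strictly = TRUE)
  if (!uniform_ok) abort("`series$time_s` must be strictly increasing.")
  readr::write_csv(series, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Nested configuration covering every stage, with defaults matching the
#' method's published operating point: passband \[2.0, 5.5\] Hz, filter
#' order 128, detection threshold 4.0, 40 s windows with 2 s steps, an
#' 80/20 train/test split, and at least 1500 training iterations.
#'
#' @return A nested list of class `capblink_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 42,
    capacitance = list(
      L = 18e-6, C = 33e-12, eps = c(1, 100, 100),
      d = c(5e-3, 1e-3, 50e-3), S = 25e-3 * 8e-3, k = 8.99e9
    ),
    synth = list(
      onsets = seq(2, 38, by = 4), closing = 0.15, hold = 0.08,
      opening = 0.25, duration = 40, fs = 100, noise = "bench"
    ),
    interp = list(period = 0.01, sigma = 1, half_width = 3, normalize = TRUE),
    filter = list(order = 128, band = c(2, 5.5)),
    detector = list(threshold = 4, min_exceed = 0.05, refractory = 0.35),
    window = list(length = 40, step = 2),
    train = list(
      n = 2000, iterations = 2000, learning_rate = 0.5,
      momentum = 0.9, train_fraction = 0.8, noise_sd = 1.5, hidden = 5
    )
  ), class = "capblink_config")
}

#' Read and validate a pipeline configuration from JSON
#'
#' Unspecified blocks and fields fall back to [default_config()] values.
#'
#' @param path JSON file path.
#' @return A validated `capblink_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_config(user)
}

#' Validate (and complete) a pipeline configuration
#'
#' @param config A (possibly partial) nested configuration list.
#' @return A completed `capblink_config`; aborts with the failing field on
#'   invalid values.
#' @export
validate_config <- function(config) {
  base <- unclass(default_config())
  merged <- utils::modifyList(base, as.list(config))
  f <- merged$filter
  if (f$order < 2 || f$order %% 2 != 0) abort("filter$order must be even and >= 2.")
  if (!(f$band[1] > 0 && f$band[1] < f$band[2])) abort("filter$band must satisfy 0 < low < high.")
  if (merged$detector$threshold <= 0) abort("detector$threshold must be > 0.")
  if (merged$window$length <= 0 || merged$window$step <= 0) {
    abort("window$length and window$step must be positive.")
  }
  tf <- merged$train$train_fraction
  if (!(tf > 0 && tf < 1)) abort("train$train_fraction must be in (0, 1).")
  if (merged$synth$fs < 20) abort("synth$fs must be >= 20 Hz.")
  structure(merged, class = "capblink_config")
}
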