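#' Differentiate a uniform series into detector units
#'
#' Central differences in the interior, one-sided at the edges (units Hz/s).
#' By default the derivative is then divided by a robust local scale - 1.4826
#' times the rolling median absolute deviation over a `baseline_window`
#' baseline, floored by the global robust scale - so the detection threshold
#' is expressed in dimensionless "robust scales" and transfers across
#' hardware gains. `rescale = FALSE` returns raw Hz/s.
#'
#' @param series Uniform data frame with `time_s`, `frequency_hz`, at least
#'   3 samples.
#' @param rescale Divide by the rolling robust scale (default `TRUE`).
#' @param baseline_window Width of the rolling baseline in seconds.
#' @return A tibble with columns `time_s`, `deriv`.
#' @export
differentiate <- function(series, rescale = TRUE, baseline_window = 10) {
  series <- as_series(series)
  n <- nrow(series)
  if (n < 3) abort("`series` must have at least 3 samples.")
  dt <- uniform_dt(series$time_s)
  x <- series$frequency_hz
  d <- c(
    (x[2] - x[1]) / dt,
    (x[3:n] - x[1:(n - 2)]) / (2 * dt),
    (x[n] - x[n - 1]) / dt
  )
  if (rescale) {
    k <- min(2L * floor(baseline_window / dt / 2) + 1L, n - (1 - n %% 2))
    if (k >= 3) {
      rmed <- runmed(d, k)
      rscale <- 1.4826 * runmed(abs(d - rmed), k)
    } else {
      rscale <- 0
    }
    gscale <- 1.4826 * mad(d, constant = 1)
    if (gscale <= 0) gscale <- 1e-8 * max(abs(d), .Machine$double.xmin)
    d <- d / pmax(rscale, gscale)
  }
  tibble::tibble(time_s = series$time_s, deriv = d)
}

#' Detector configuration
#'
#' @param threshold Derivative magnitude threshold in robust-scale units
#'   (default 4.0).
#' @param min_exceed Duration (s) a supra-threshold run must reach for a
#'   duration confidence of 1.
#' @param refractory Maximum gap (s) across which supra-threshold runs are
#'   merged into one candidate, so the closing-edge and opening-edge
#'   excursions of a single blink form one event. The default covers the
#'   longest quiet stretch a 0.2 s close / 0.1 s hold / 0.3 s open blink
#'   leaves between its two excursions, while staying well below
#'   physiological inter-blink intervals.
#' @return A `detector_config` list.
#' @export
detector_config <- function(threshold = 4, min_exceed = 0.05,
                            refractory = 0.35) {
  check_number(threshold, "threshold", lower = 0, strict = TRUE)
  check_number(min_exceed, "min_exceed", lower = 0, strict = TRUE)
  check_number(refractory, "refractory", lower = 0)
  structure(
    list(
      threshold = threshold, min_exceed = min_exceed,
      refractory = refractory
    ),
    class = "detector_config"
  )
}

# expand from index i over positions where keep is TRUE
lobe_bounds <- function(sign_ok, i) {
  lo <- i
  while (lo > 1 && sign_ok[lo - 1]) lo <- lo - 1
  hi <- i
  n <- length(sign_ok)
  while (hi < n && sign_ok[hi + 1]) hi <- hi + 1
  c(lo, hi)
}

#' Detect blink events from a differentiated series
#'
#' Frame-by-frame thresholding with confidence fusion. Maximal runs where
#' `|deriv|` exceeds the threshold are merged across gaps shorter than the
#' refractory, then each candidate is scored with the geometric mean of its
#' amplitude excess (`max |deriv| / threshold`) and duration excess (run
#' length / `min_exceed`); an event is emitted when that fused confidence
#' exceeds 1.
#'
#' Because a lid closure lowers the sensed resonance frequency, the closing
#' phase is the contiguous negative-derivative lobe containing the
#' candidate's most negative sample and the opening phase is the positive
#' lobe that follows; the event onset is the start of the closing lobe.
#' Phase durations are `(lobe samples - 1) * dt`.
#'
#' @param deriv Tibble from [differentiate()].
#' @param config A [detector_config()].
#' @return A tibble of events: `onset_s`, `closing_s`, `opening_s`,
#'   `confidence` (zero rows when nothing exceeds the threshold).
#' @export
detect_blinks <- function(deriv, config = detector_config()) {
  if (!is.data.frame(deriv) || !all(c("time_s", "deriv") %in% names(deriv))) {
    abort("`deriv` must be a data frame with columns time_s, deriv.")
  }
  stopifnot(inherits(config, "detector_config"))
  d <- deriv$deriv
  n <- length(d)
  empty <- tibble::tibble(
    onset_s = numeric(), closing_s = numeric(),
    opening_s = numeric(), confidence = numeric()
  )
  if (n < 3) {
    return(empty)
  }
  dt <- uniform_dt(deriv$time_s)
  above <- abs(d) > config$threshold
  if (!any(above)) {
    return(empty)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  gap_max <- config$refractory / dt
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs[i, 1] - merged[nrow(merged), 2] - 1 < gap_max) {
      merged[nrow(merged), 2] <- runs[i, 2]
    } else {
      merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  events <- purrr::map_dfr(seq_len(nrow(merged)), function(i) {
    a <- merged[i, 1]
    b <- merged[i, 2]
    c_amp <- max(abs(d[a:b])) / config$threshold
    c_dur <- ((b - a + 1) * dt) / config$min_exceed
    conf <- sqrt(c_amp * c_dur)
    if (conf <= 1) {
      return(NULL)
    }
    imin <- a - 1 + which.min(d[a:b])
    neg <- lobe_bounds(d < 0, imin)
    p1 <- neg[2] + 1
    while (p1 < n && d[p1] <= 0) p1 <- p1 + 1
    op_n <- if (p1 > n || d[p1] <= 0) {
      0 # truncated at series end; zero-length opening
    } else {
      pos <- lobe_bounds(d > 0, p1)
      max(pos[2] - pos[1] - 1, 1)
    }
    # central differences smear a lobe's support outward by one sample on
    # each side; subtracting one sample from first-to-last span unbiases
    # the duration to within +/- 1 sample
    tibble::tibble(
      onset_s = deriv$time_s[neg[1]],
      closing_s = max(neg[2] - neg[1] - 1, 1) * dt,
      opening_s = op_n * dt,
      confidence = conf
    )
  })
  if (nrow(events) == 0) empty else events
}

#' Aggregate blink features over one window
#'
#' Events whose onset falls in `[start, start + length)` contribute. Idle
#' time is the mean gap from the end of one event's opening phase to the
#' next event's onset. Degenerate windows: with no events the features are
#' `(0, 0, window length)`; with one event the idle time is the window
#' length minus the event's duration.
#'
#' @param events Event tibble from [detect_blinks()].
#' @param start Window start in seconds.
#' @param length Window length in seconds (default 40).
#' @return One-row tibble: `window_start_s`, `closing_s`, `opening_s`,
#'   `idle_s`, `count`.
#' @export
extract_features <- function(events, start = 0, length = 40) {
  check_number(start, "start")
  check_number(length, "length", lower = 0, strict = TRUE)
  ev <- events[events$onset_s >= start & events$onset_s < start + length, ]
  k <- nrow(ev)
  if (k == 0) {
    return(tibble::tibble(
      window_start_s = start, closing_s = 0, opening_s = 0,
      idle_s = length, count = 0L
    ))
  }
  dur <- ev$closing_s + ev$opening_s
  idle <- if (k == 1) {
    length - dur
  } else {
    mean(ev$onset_s[-1] - (ev$onset_s[-k] + dur[-k]))
  }
  tibble::tibble(
    window_start_s = start, closing_s = mean(ev$closing_s),
    opening_s = mean(ev$opening_s), idle_s = idle, count = k
  )
}

#' Sliding analysis windows
#'
#' Windows of fixed length advancing by a fixed step, kept only while fully
#' inside the recording: starts `0, step, 2 step, ...` with
#' `start + window <= duration`. A 260 s recording with the default 40 s /
#' 2 s settings yields 111 windows.
#'
#' @param x Either a recording duration in seconds, or a series data frame
#'   (duration taken as sample count times the sampling interval, offset at
#'   the first timestamp).
#' @param window Window length in seconds.
#' @param step Step between window starts in seconds.
#' @return A tibble with columns `start_s`, `end_s` (possibly zero rows).
#' @export
sliding_windows <- function(x, window = 40, step = 2) {
  check_number(window, "window", lower = 0, strict = TRUE)
  check_number(step, "step", lower = 0, strict = TRUE)
  if (is.data.frame(x)) {
    s <- as_series(x)
    duration <- nrow(s) * uniform_dt(s$time_s)
    offset <- s$time_s[1]
  } else {
    check_number(x, "x", lower = 0)
    duration <- x
    offset <- 0
  }
  tol <- 1e-6 * window # guard against floating-point duration round-off
  if (duration < window - tol) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  starts <- offset + seq(0, duration - window + tol, by = step)
  tibble::tibble(start_s = starts, end_s = starts + window)
}

#' Blink features for every sliding window
#'
#' @param events Event tibble from [detect_blinks()].
#' @param x Recording duration in seconds or a series data frame (see
#'   [sliding_windows()]).
#' @inheritParams sliding_windows
#' @return A tibble with one [extract_features()] row per window.
#' @export
window_features <- function(events, x, window = 40, step = 2) {
  w <- sliding_windows(x, window, step)
  if (nrow(w) == 0) {
    return(tibble::tibble(
      window_start_s = numeric(), closing_s = numeric(),
      opening_s = numeric(), idle_s = numeric(), count = integer()
    ))
  }
  purrr::map_dfr(w$start_s, function(s) extract_features(events, s, window))
}
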