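#' Blink schedule
#'
#' Ground-truth timing of synthetic blinks. Each event has a lid-descent
#' (closing) phase, a fully-closed hold, and a lid-ascent (opening) phase.
#' Defaults reflect typical human blink kinematics (a full blink lasts
#' roughly 0.2-0.4 s).
#'
#' @param onsets Event onset times in seconds, sorted ascending.
#' @param closing,hold,opening Phase durations in seconds (scalar or one per
#'   event), all > 0.
#' @param duration Recording length in seconds; every event must finish
#'   before `duration`.
#' @return A tibble of class `blink_schedule` with columns `onset_s`,
#'   `closing_s`, `hold_s`, `opening_s` and a `duration` attribute.
#' @examples
#' blink_schedule(seq(2, 38, by = 4))
#' @export
blink_schedule <- function(onsets, closing = 0.15, hold = 0.08, opening = 0.25,
                           duration = 40) {
  if (length(onsets) && is.unsorted(onsets, strictly = TRUE)) {
    abort("`onsets` must be strictly increasing.")
  }
  check_number(duration, "duration", lower = 0, strict = TRUE)
  n <- length(onsets)
  sched <- tibble::tibble(
    onset_s = as.numeric(onsets),
    closing_s = rep_len(closing, n),
    opening_s = rep_len(opening, n),
    hold_s = rep_len(hold, n)
  )[, c("onset_s", "closing_s", "hold_s", "opening_s")]
  if (n > 0) {
    if (any(sched$closing_s <= 0) || any(sched$hold_s <= 0) ||
      any(sched$opening_s <= 0)) {
      abort("all phase durations must be positive.")
    }
    ends <- sched$onset_s + sched$closing_s + sched$hold_s + sched$opening_s
    if (any(ends > duration) || any(sched$onset_s < 0)) {
      abort("events must lie inside [0, duration].")
    }
    if (n > 1 && any(sched$onset_s[-1] < ends[-n])) {
      abort("events overlap: each onset must follow the previous event's end.")
    }
  }
  structure(sched, class = c("blink_schedule", class(sched)), duration = duration)
}

#' Random non-overlapping blink schedule
#'
#' Draws event onsets by jittering a regular grid and phase durations from
#' uniform ranges, guaranteeing non-overlap and a minimum quiet gap between
#' consecutive blinks (humans do not blink back-to-back; inter-blink
#' intervals are seconds long). Used for property-style testing of the
#' detector.
#'
#' @param n_events Number of blinks.
#' @param duration Recording length in seconds.
#' @param closing_range,hold_range,opening_range Uniform ranges (s) for the
#'   phase durations.
#' @param min_gap Minimum quiet time (s) between one blink's end and the
#'   next blink's onset.
#' @param seed Optional integer seed.
#' @return A [blink_schedule()].
#' @export
random_blink_schedule <- function(n_events, duration = 40,
                                  closing_range = c(0.1, 0.2),
                                  hold_range = c(0.05, 0.1),
                                  opening_range = c(0.15, 0.3),
                                  min_gap = 0.8, seed = NULL) {
  check_number(n_events, "n_events", lower = 1)
  with_optional_seed(seed, {
    slot <- (duration - 1) / n_events
    max_dur <- max(closing_range) + max(hold_range) + max(opening_range)
    if (slot < max_dur + min_gap + 0.1) {
      abort("too many events for the recording length.")
    }
    onsets <- 0.5 + slot * (seq_len(n_events) - 1) +
      runif(n_events, 0, slot - max_dur - min_gap)
    blink_schedule(
      onsets,
      closing = runif(n_events, closing_range[1], closing_range[2]),
      hold = runif(n_events, hold_range[1], hold_range[2]),
      opening = runif(n_events, opening_range[1], opening_range[2]),
      duration = duration
    )
  })
}

#' Noise specification for synthetic recordings
#'
#' Amplitude parameters are expressed relative to the blink drop amplitude
#' (the open-minus-closed resonance-frequency difference of the configured
#' dielectric model), since the absolute carrier scale depends on the tank
#' circuit. Absolute values in Hz may be supplied instead and take
#' precedence.
#'
#' @param white_sd_rel White (broadband) noise standard deviation, as a
#'   fraction of the blink drop amplitude.
#' @param drift_rel Amplitude of a slow sinusoidal baseline drift, as a
#'   fraction of the drop amplitude.
#' @param drift_period Drift period in seconds.
#' @param jitter_sd Sampling-time jitter standard deviation in seconds
#'   (truncated so timestamps stay strictly increasing).
#' @param white_sd,drift_amplitude Optional absolute values in Hz overriding
#'   the relative ones.
#' @return A `noise_spec` list.
#' @seealso [noise_preset()]
#' @export
noise_spec <- function(white_sd_rel = 0, drift_rel = 0, drift_period = 10,
                       jitter_sd = 0, white_sd = NULL, drift_amplitude = NULL) {
  check_number(white_sd_rel, "white_sd_rel", lower = 0)
  check_number(drift_rel, "drift_rel", lower = 0)
  check_number(drift_period, "drift_period", lower = 0, strict = TRUE)
  check_number(jitter_sd, "jitter_sd", lower = 0)
  structure(list(
    white_sd_rel = white_sd_rel, drift_rel = drift_rel,
    drift_period = drift_period, jitter_sd = jitter_sd,
    white_sd = white_sd, drift_amplitude = drift_amplitude
  ), class = "noise_spec")
}

#' Built-in noise regimes
#'
#' `"none"` is exactly noiseless; `"bench"` emulates a still, seated subject
#' (white noise 0.5% of the drop amplitude, 2% slow drift, 1 ms timing
#' jitter); `"driving"` and `"walking"` add progressively more drift and
#' broadband noise, mirroring eyewear shake during motion.
#'
#' @param name One of `"none"`, `"bench"`, `"driving"`, `"walking"`.
#' @return A [noise_spec()].
#' @examples
#' noise_preset("bench")
#' @export
noise_preset <- function(name = c("bench", "none", "driving", "walking")) {
  switch(match.arg(name),
    none = noise_spec(),
    bench = noise_spec(
      white_sd_rel = 0.005, drift_rel = 0.02,
      drift_period = 10, jitter_sd = 1e-3
    ),
    driving = noise_spec(
      white_sd_rel = 0.01, drift_rel = 0.1,
      drift_period = 5, jitter_sd = 1e-3
    ),
    walking = noise_spec(
      white_sd_rel = 0.02, drift_rel = 0.2,
      drift_period = 2, jitter_sd = 2e-3
    )
  )
}

# lid position in [0, 1] at times t for one scheduled event (raised cosine)
lid_position <- function(t, onset, closing, hold, opening) {
  y <- numeric(length(t))
  t1 <- onset + closing
  t2 <- t1 + hold
  t3 <- t2 + opening
  i <- t >= onset & t < t1
  y[i] <- 0.5 - 0.5 * cos(pi * (t[i] - onset) / closing)
  y[t >= t1 & t < t2] <- 1
  i <- t >= t2 & t < t3
  y[i] <- 0.5 + 0.5 * cos(pi * (t[i] - t2) / opening)
  y
}

#' Generate a labelled synthetic frequency recording
#'
#' Produces the resonance-frequency trace an eyewear-mounted capacitive
#' front end would measure for a given blink schedule. The baseline is the
#' open-eye resonance frequency of the configured tank and dielectric model;
#' during each blink the trace ramps to the closed-eye frequency and back
#' with raised-cosine lid kinematics. White noise, sinusoidal baseline
#' drift, and sampling-time jitter are added per the noise specification.
#'
#' @param schedule A [blink_schedule()].
#' @param model An [eye_model()].
#' @param circuit A [circuit_params()].
#' @param fs Nominal sampling rate in Hz; must be at least 20 Hz so the
#'   blink band (up to 5.5 Hz) is well below Nyquist.
#' @param noise A [noise_spec()] or preset name.
#' @param seed Optional integer seed for noise and jitter.
#' @return A list of class `blink_recording`: `series` (tibble with
#'   `time_s`, `frequency_hz`), `labels` (the schedule), `f_open`,
#'   `f_closed`, `fs`, `noise`.
#' @examples
#' rec <- generate_recording(blink_schedule(c(5, 15)), noise = "none")
#' range(rec$series$frequency_hz)
#' @export
generate_recording <- function(schedule, model = eye_model(),
                               circuit = circuit_params(), fs = 100,
                               noise = noise_preset("bench"), seed = NULL) {
  stopifnot(inherits(schedule, "blink_schedule"))
  check_number(fs, "fs", lower = 20)
  if (is.character(noise)) noise <- noise_preset(noise)
  stopifnot(inherits(noise, "noise_spec"))

  f_open <- resonance_frequency(circuit, capacitance_open(model))
  f_closed <- resonance_frequency(circuit, capacitance_closed(model))
  drop <- f_open - f_closed
  white_sd <- noise$white_sd %||% (noise$white_sd_rel * drop)
  drift_amp <- noise$drift_amplitude %||% (noise$drift_rel * drop)

  duration <- attr(schedule, "duration")
  n <- floor(duration * fs)
  t_nom <- (seq_len(n) - 1) / fs

  with_optional_seed(seed, {
    jit <- if (noise$jitter_sd > 0) {
      pmin(pmax(rnorm(n, 0, noise$jitter_sd), -0.45 / fs), 0.45 / fs)
    } else {
      numeric(n)
    }
    t <- t_nom + jit
    lid <- numeric(n)
    for (i in seq_len(nrow(schedule))) {
      lid <- lid + lid_position(
        t, schedule$onset_s[i], schedule$closing_s[i],
        schedule$hold_s[i], schedule$opening_s[i]
      )
    }
    phase <- runif(1, 0, 2 * pi)
    f <- f_open - drop * lid +
      drift_amp * sin(2 * pi * t / noise$drift_period + phase) +
      (if (white_sd > 0) rnorm(n, 0, white_sd) else 0)
    structure(list(
      series = tibble::tibble(time_s = t, frequency_hz = f),
      labels = schedule, f_open = f_open, f_closed = f_closed,
      fs = fs, noise = noise
    ), class = "blink_recording")
  })
}

#' Generate a labelled synthetic feature dataset
#'
#' Draws per-window blink features (mean closing, opening, and idle time)
#' from uniform ranges and assigns each window a fatigue scale through a
#' monotone linear map plus Gaussian noise, clamped to the FSAS range
#' \[10, 50\]. This stands in for windows extracted from instrumented
#' recordings paired with questionnaire totals, and gives the fatigue
#' network a dataset with known ground truth.
#'
#' @param n Number of windows.
#' @param coefs Named mapping coefficients
#'   `c(intercept, closing, opening, idle)` (scale points per second for the
#'   feature terms). The closing coefficient must be positive so the map is
#'   monotone increasing in closing time, the feature most associated with
#'   drowsiness.
#' @param closing_range,opening_range,idle_range Uniform feature ranges in
#'   seconds.
#' @param noise_sd Gaussian label noise, in scale points.
#' @param seed Optional integer seed.
#' @return A tibble with columns `closing_s`, `opening_s`, `idle_s`,
#'   `scale`.
#' @examples
#' generate_feature_dataset(3, seed = 1)
#' @export
generate_feature_dataset <- function(n,
                                     coefs = c(
                                       intercept = 10, closing = 60,
                                       opening = 40, idle = -2
                                     ),
                                     closing_range = c(0.1, 0.5),
                                     opening_range = c(0.15, 0.6),
                                     idle_range = c(1, 10),
                                     noise_sd = 1.5, seed = NULL) {
  check_number(n, "n", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (coefs[["closing"]] <= 0) abort("`coefs['closing']` must be positive.")
  with_optional_seed(seed, {
    closing <- runif(n, closing_range[1], closing_range[2])
    opening <- runif(n, opening_range[1], opening_range[2])
    idle <- runif(n, idle_range[1], idle_range[2])
    scale <- coefs[["intercept"]] + coefs[["closing"]] * closing +
      coefs[["opening"]] * opening + coefs[["idle"]] * idle +
      (if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
    tibble::tibble(
      closing_s = closing, opening_s = opening, idle_s = idle,
      scale = pmin(pmax(scale, 10), 50)
    )
  })
}

#' @export
print.blink_recording <- function(x, ...) {
  cat(sprintf(
    "<blink_recording> %d samples @ %g Hz, %d scheduled blinks\n",
    nrow(x$series), x$fs, nrow(x$labels)
  ))
  cat(sprintf(
    "  open-eye %.6g Hz, closed-eye %.6g Hz (drop %.4g Hz)\n",
    x$f_open, x$f_closed, x$f_open - x$f_closed
  ))
  invisible(x)
}
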