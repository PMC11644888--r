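test_that("differentiation is exact on constants, ramps, and sinusoids", {
  t <- seq(0, 10, by = 0.01)
  const <- tibble::tibble(time_s = t, frequency_hz = 5)
  d <- differentiate(const, rescale = FALSE)
  expect_true(all(d$deriv == 0))

  ramp <- tibble::tibble(time_s = t, frequency_hz = 2.5 * t)
  dr <- differentiate(ramp, rescale = FALSE)
  expect_equal(dr$deriv[2:(length(t) - 1)], rep(2.5, length(t) - 2))

  # analytic oracle: d/dt sin(2 pi 3 t) = 6 pi cos(2 pi 3 t)
  sine <- tibble::tibble(time_s = t, frequency_hz = sin(2 * pi * 3 * t))
  ds <- differentiate(sine, rescale = FALSE)
  mid <- 2:(length(t) - 1)
  truth <- 6 * pi * cos(2 * pi * 3 * t[mid])
  rel_rms <- sqrt(mean((ds$deriv[mid] - truth)^2)) / sqrt(mean(truth^2))
  expect_lt(rel_rms, 0.01)

  expect_error(
    differentiate(tibble::tibble(time_s = c(0, 1), frequency_hz = c(0, 1))),
    "at least 3"
  )
})

test_that("a flat derivative and sub-threshold bumps produce no events", {
  t <- seq(0, 10, by = 0.01)
  flat <- tibble::tibble(time_s = t, deriv = numeric(length(t)))
  expect_identical(nrow(detect_blinks(flat)), 0L)

  # peak at half the threshold: never crosses, no candidate at all
  half <- tibble::tibble(time_s = t, deriv = -2 * exp(-(t - 5)^2 / 0.01))
  expect_identical(nrow(detect_blinks(half)), 0L)

  # single-sample spike just above threshold: duration confidence kills it
  spike <- numeric(length(t))
  spike[500] <- -4.4
  short <- tibble::tibble(time_s = t, deriv = spike)
  expect_identical(nrow(detect_blinks(short)), 0L)
})

test_that("the full chain recovers a ten-blink bench recording", {
  rec <- generate_recording(ten_blink_schedule(), noise = "bench", seed = 42)
  events <- run_detection_chain(rec)
  expect_identical(nrow(events), 10L)
  expect_lt(max(abs(events$onset_s - rec$labels$onset_s)), 0.1)
  expect_true(all(events$confidence > 1))
})

test_that("noiseless detection has perfect recall, precision, and durations", {
  # the detector runs on the unfiltered signal here: this isolates its own
  # accuracy from band-pass waveform distortion
  for (seed in 1:20) {
    n_ev <- 3L + seed %% 6L
    sched <- random_blink_schedule(n_ev, duration = 40, seed = seed)
    rec <- generate_recording(sched, noise = "none", seed = seed)
    events <- detect_blinks(differentiate(rec$series))
    expect_identical(nrow(events), n_ev)
    m <- match_events(events, sched)
    expect_identical(unname(m), c(n_ev, 0L))
    dt <- 1 / rec$fs
    expect_lte(max(abs(events$onset_s - sched$onset_s)), dt + 1e-9)
    expect_lte(max(abs(events$closing_s - sched$closing_s)), dt + 1e-9)
    expect_lte(max(abs(events$opening_s - sched$opening_s)), dt + 1e-9)
  }
})

test_that("detection count ignores constant offsets and sub-band drift", {
  for (seed in 1:10) {
    sched <- random_blink_schedule(5, duration = 20, seed = 100 + seed)
    rec <- generate_recording(sched, noise = "bench", seed = 200 + seed)
    base <- run_detection_chain(rec)
    drop <- rec$f_open - rec$f_closed
    shifted <- rec
    shifted$series$frequency_hz <- rec$series$frequency_hz + 1e4 +
      5 * drop * sin(2 * pi * 0.1 * rec$series$time_s)
    expect_identical(nrow(run_detection_chain(shifted)), nrow(base))
  }
})

test_that("recall degrades monotonically as white noise grows", {
  sched <- ten_blink_schedule()
  recalls <- vapply(
    c(0.005, 0.05, 0.15, 0.3, 0.5),
    function(wsd) {
      rec <- generate_recording(sched,
        noise = noise_spec(white_sd_rel = wsd, drift_rel = 0.02, jitter_sd = 1e-3),
        seed = 77
      )
      match_events(run_detection_chain(rec), sched)[["tp"]] / 10
    },
    numeric(1)
  )
  expect_equal(recalls[1], 1)
  # allow at most one inversion from sampling error
  expect_lte(sum(diff(recalls) > 0), 1)
  expect_lt(recalls[5], recalls[1])
})

test_that("window features follow their definitions", {
  none <- detect_blinks(tibble::tibble(time_s = seq(0, 1, 0.01), deriv = 0))
  expect_equal(
    extract_features(none, 0, 40),
    tibble::tibble(
      window_start_s = 0, closing_s = 0, opening_s = 0,
      idle_s = 40, count = 0L
    )
  )

  two <- tibble::tibble(
    onset_s = c(5, 15), closing_s = 0.15, opening_s = 0.25,
    confidence = 2
  )
  f <- extract_features(two, 0, 40)
  expect_equal(f$idle_s, 15 - (5 + 0.4))
  expect_equal(f$closing_s, 0.15)
  expect_identical(f$count, 2L)

  # one scheduled noiseless blink: phases recovered within one sample
  sched <- blink_schedule(5, closing = 0.15, hold = 0.08, opening = 0.25, duration = 20)
  rec <- generate_recording(sched, noise = "none", seed = 3)
  ev <- detect_blinks(differentiate(rec$series))
  f1 <- extract_features(ev, 0, 20)
  expect_identical(f1$count, 1L)
  expect_lte(abs(f1$closing_s - 0.15), 0.01 + 1e-9)
  expect_lte(abs(f1$opening_s - 0.25), 0.01 + 1e-9)
})

test_that("sliding windows tile the recording as specified", {
  expect_identical(nrow(sliding_windows(260)), 111L)
  expect_identical(nrow(sliding_windows(40)), 1L)
  expect_identical(nrow(sliding_windows(39)), 0L)
  w <- sliding_windows(260)
  expect_equal(w$start_s[1:3], c(0, 2, 4))
  expect_equal(w$end_s - w$start_s, rep(40, 111))

  # a series input is measured by its sample span
  s <- tibble::tibble(time_s = seq(0, 99.99, by = 0.01), frequency_hz = 0)
  expect_identical(nrow(sliding_windows(s)), 31L)
})
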