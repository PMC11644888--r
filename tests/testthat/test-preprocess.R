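test_that("the Gaussian weight peaks at 1/sqrt(2 pi) on the grid point", {
  expect_equal(gaussian_weight(0, 1), 1 / sqrt(2 * pi))
  expect_equal(gaussian_weight(0, 0.01), 0.3989423, tolerance = 1e-6)
  # symmetric, decreasing in |dt|
  expect_equal(gaussian_weight(0.3, 0.5), gaussian_weight(-0.3, 0.5))
  expect_lt(gaussian_weight(0.2, 0.1), gaussian_weight(0.1, 0.1))
})

test_that("constants are fixed points of normalized interpolation", {
  withr::with_seed(31, {
    t <- sort(runif(400, 0, 4))
    s <- tibble::tibble(time_s = t, frequency_hz = 7.25)
    u <- gaussian_interpolate(s, period = 0.05)
    expect_true(all(abs(u$frequency_hz - 7.25) < 1e-12))
    # without renormalization the output tracks local sample density instead
    raw <- gaussian_interpolate(s, period = 0.05, normalize = FALSE)
    expect_gt(sd(raw$frequency_hz), 0)
  })
})

test_that("a jittered linear ramp interpolates within one period of the line", {
  withr::with_seed(32, {
    a <- 3
    T <- 0.01
    t <- seq(0, 10, by = T) + rnorm(1001, 0, 0.1 * T)
    t <- sort(t)
    t <- t[c(TRUE, diff(t) > 0)]
    s <- tibble::tibble(time_s = t, frequency_hz = a * t)
    u <- gaussian_interpolate(s, period = T)
    expect_lt(max(abs(u$frequency_hz - a * u$time_s)), abs(a) * T)
  })
})

test_that("grid points with an empty neighbourhood come back as NA", {
  s <- tibble::tibble(time_s = c(0, 0.01, 0.02, 2, 2.01), frequency_hz = 1)
  expect_warning(
    u <- gaussian_interpolate(s, period = 0.01, half_width = 3),
    "no samples"
  )
  expect_true(anyNA(u$frequency_hz))
  expect_error(bandpass(u), "NA")
})

test_that("the band-pass preserves in-band tones and rejects out-of-band ones", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  mid <- t > 15 & t < 45 # steady-state region
  rms <- function(x) sqrt(mean(x^2))
  tone <- function(f) tibble::tibble(time_s = t, frequency_hz = sin(2 * pi * f * t))

  expect_equal(
    bandpass(tone(0))$frequency_hz,
    rep(0, length(t))
  )
  in_band <- bandpass(tone(3.5))
  expect_gt(rms(in_band$frequency_hz[mid]) / rms(sin(2 * pi * 3.5 * t[mid])), 0.9)
  expect_lt(rms(in_band$frequency_hz[mid]) / rms(sin(2 * pi * 3.5 * t[mid])), 1.1)

  lo <- bandpass(tone(0.1))
  expect_lt(rms(lo$frequency_hz[mid]) / rms(sin(2 * pi * 0.1 * t[mid])), 1e-2)
})

test_that("response rolls off monotonically and steepens with order", {
  fs <- 100
  gains1hz <- vapply(c(4, 8, 16), function(ord) {
    sos <- butter_bandpass_sos(ord, 2, 5.5, fs)
    # monotone roll-off on each side of the passband
    below <- sos_response(sos, seq(0.2, 1.8, by = 0.2), fs)
    above <- sos_response(sos, seq(6.5, 30, by = 1.5), fs)
    expect_true(all(diff(below) > 0))
    expect_true(all(diff(above) < 0))
    sos_response(sos, 1, fs)
  }, numeric(1))
  expect_true(all(diff(gains1hz) < 0))
})

test_that("the section cascade matches an established filter design at low order", {
  skip_if_not_installed("signal")
  fs <- 100
  bf <- signal::butter(2, c(2, 5.5) / (fs / 2), type = "pass")
  f <- c(0.5, 1, 2, 3.5, 5.5, 8, 20)
  h_ref <- Mod(signal::freqz(bf$b, bf$a, 2 * pi * f / fs)$h)
  h_sos <- sos_response(butter_bandpass_sos(4, 2, 5.5, fs), f, fs)
  expect_equal(h_sos, h_ref, tolerance = 1e-8)
})

test_that("filtering a ten-blink bench recording localizes energy at the blinks", {
  rec <- generate_recording(ten_blink_schedule(), noise = "bench", seed = 5)
  filt <- rec$series |>
    gaussian_interpolate(period = 1 / rec$fs) |>
    bandpass()
  x <- abs(filt$frequency_hz)
  # the sharp filter rings for about a second either side of each blink,
  # so judge localization against samples clear of that ring
  near <- rep(FALSE, length(x))
  for (o in rec$labels$onset_s) {
    near <- near | (filt$time_s >= o - 1 & filt$time_s <= o + 1.5)
  }
  # every blink involves a large excursion...
  peaks <- vapply(rec$labels$onset_s, function(o) {
    max(x[filt$time_s >= o - 0.2 & filt$time_s <= o + 0.8])
  }, numeric(1))
  # ...and all of them dominate everything away from the blinks
  away <- !near & filt$time_s > 1 & filt$time_s < 39
  expect_gt(min(peaks), 3 * max(x[away]))
})

test_that("filter and interpolation inputs are validated", {
  expect_error(filter_spec(order = 3), "even")
  expect_error(filter_spec(band = c(5, 2)), "low < high")
  t <- seq(0, 1, by = 0.1)
  expect_error(
    bandpass(tibble::tibble(time_s = t, frequency_hz = 0), filter_spec(4, c(2, 5.5))),
    "Nyquist"
  )
  expect_error(gaussian_interpolate(tibble::tibble(
    time_s = numeric(),
    frequency_hz = numeric()
  ), 0.01), "empty")
  # the analytical first-order reference peaks inside the band
  f <- seq(0.1, 20, by = 0.1)
  h <- first_order_band_response(f)
  expect_true(f[which.max(h)] > 2 && f[which.max(h)] < 5.5)
})
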