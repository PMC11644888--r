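# shared fixtures built in code

# the ten-blink benchmark scenario: blinks every 4 s in a 40 s recording
ten_blink_schedule <- function() {
  blink_schedule(seq(2, 38, by = 4),
    closing = 0.15, hold = 0.08,
    opening = 0.25, duration = 40
  )
}

# full chain: recording -> uniform grid -> blink band -> detector units -> events
run_detection_chain <- function(rec, order = 128, band = c(2, 5.5),
                                config = detector_config()) {
  rec$series |>
    gaussian_interpolate(period = 1 / rec$fs) |>
    bandpass(filter_spec(order, band)) |>
    differentiate() |>
    detect_blinks(config)
}

# match detected events to scheduled onsets within a tolerance; returns
# c(true_positives, false_positives)
match_events <- function(events, schedule, tol = 0.3) {
  hits <- vapply(
    schedule$onset_s,
    function(o) any(abs(events$onset_s - o) <= tol),
    logical(1)
  )
  spurious <- vapply(
    events$onset_s,
    function(o) all(abs(schedule$onset_s - o) > tol),
    logical(1)
  )
  c(tp = sum(hits), fp = sum(spurious))
}
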