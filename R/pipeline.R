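#' Run the full blink-to-fatigue pipeline
#'
#' Simulate (or load) a recording, interpolate it onto a uniform grid,
#' band-pass it to the blink band, differentiate, detect blink events,
#' aggregate per-window features, and - when a training block is configured
#' - fit the fatigue network on a labelled synthetic feature dataset and
#' score each detected window. One master seed fans out to independent
#' per-stage sub-seeds, so every run with the same configuration and seed
#' produces an identical report.
#'
#' @param config A `capblink_config` (see [default_config()],
#'   [read_config()]); partial lists are completed via [validate_config()].
#' @param seed Master seed; overrides `config$seed` when given.
#' @param input Optional series data frame or CSV path; when supplied the
#'   synthesis stage is skipped and the recording is taken as-is.
#' @return A `capblink_report` list: resolved `config`, `events`,
#'   `features` (per window), `fatigue` (per-window predicted scale plus
#'   hold-out accuracy, if trained), and per-stage `log` entries.
#' @examples
#' \donttest{
#' rep <- run_pipeline(default_config())
#' nrow(rep$events)
#' }
#' @export
run_pipeline <- function(config = default_config(), seed = NULL, input = NULL) {
  config <- validate_config(config)
  seed <- seed %||% config$seed
  seeds <- derive_seeds(seed, 3) # synth, train-data, train
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- sprintf(...)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  cc <- config$capacitance
  model <- eye_model(eps = cc$eps, d = cc$d, S = cc$S, k = cc$k)
  circuit <- circuit_params(L = cc$L, C = cc$C)

  if (is.null(input)) {
    sy <- config$synth
    rec <- stage("simulate", {
      sched <- blink_schedule(sy$onsets,
        closing = sy$closing, hold = sy$hold,
        opening = sy$opening, duration = sy$duration
      )
      generate_recording(sched,
        model = model, circuit = circuit, fs = sy$fs,
        noise = sy$noise, seed = seeds[1]
      )
    })
    series <- rec$series
    note(
      "simulate", "%d samples, %d scheduled blinks, noise '%s'",
      nrow(series), nrow(rec$labels),
      if (is.character(sy$noise)) sy$noise else "custom"
    )
  } else {
    series <- stage("load", if (is.character(input)) read_series(input) else as_series(input))
    rec <- NULL
    note("load", "%d samples", nrow(series))
  }

  ip <- config$interp
  uniform <- stage("interpolate", gaussian_interpolate(series,
    period = ip$period,
    sigma = ip$sigma, half_width = ip$half_width, normalize = ip$normalize
  ))
  note("interpolate", "grid period %g s, %d points", ip$period, nrow(uniform))

  filtered <- stage("bandpass", bandpass(uniform, filter_spec(
    order = config$filter$order,
    band = config$filter$band
  )))
  note(
    "bandpass", "order %d, band [%g, %g] Hz", config$filter$order,
    config$filter$band[1], config$filter$band[2]
  )

  dt <- config$detector
  events <- stage("detect", detect_blinks(
    differentiate(filtered),
    detector_config(dt$threshold, dt$min_exceed, dt$refractory)
  ))
  note("detect", "%d events above threshold %g", nrow(events), dt$threshold)

  feats <- stage("features", window_features(events, filtered,
    window = config$window$length, step = config$window$step
  ))
  note("features", "%d windows of %g s", nrow(feats), config$window$length)

  fatigue <- NULL
  if (!is.null(config$train)) {
    tr <- config$train
    fatigue <- stage("fatigue", {
      dset <- generate_feature_dataset(tr$n, noise_sd = tr$noise_sd, seed = seeds[2])
      ev <- evaluate_fatigue(dset,
        train_fraction = tr$train_fraction, seed = seeds[3],
        hidden = tr$hidden, iterations = tr$iterations,
        learning_rate = tr$learning_rate, momentum = tr$momentum
      )
      per_window <- if (nrow(feats)) {
        tibble::tibble(
          window_start_s = feats$window_start_s,
          scale = predict(ev$network, feats)
        )
      } else {
        tibble::tibble(window_start_s = numeric(), scale = numeric())
      }
      list(
        per_window = per_window,
        holdout_accuracy = ev$accuracy, network = ev$network
      )
    })
    note("fatigue", "hold-out accuracy %.2f%%", fatigue$holdout_accuracy)
  }

  structure(list(
    config = config, seed = seed, events = events, features = feats,
    fatigue = fatigue, log = log
  ), class = "capblink_report")
}

#' @export
print.capblink_report <- function(x, ...) {
  cat("<capblink_report>\n")
  for (s in names(x$log)) cat(sprintf("  %-12s %s\n", s, x$log[[s]]))
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' Serializes events, per-window features, per-window fatigue scale, the
#' hold-out accuracy, the resolved configuration, and the stage log.
#'
#' @param report A `capblink_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "capblink_report"))
  out <- list(
    seed = report$seed,
    config = unclass(report$config),
    events = report$events,
    features = report$features,
    fatigue = if (!is.null(report$fatigue)) {
      list(
        per_window = report$fatigue$per_window,
        holdout_accuracy = report$fatigue$holdout_accuracy
      )
    },
    log = report$log
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
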