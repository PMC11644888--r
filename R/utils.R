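# internal validation + seeding helpers

check_number <- function(x, name, lower = -Inf, strict = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric vector of length %d.", name, len))
  }
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad) {
    abort(sprintf(
      "`%s` must be %s %s.", name, if (strict) "greater than" else "at least",
      format(lower)
    ))
  }
  invisible(x)
}

#' Derive reproducible sub-seeds from one master seed
#'
#' A single pipeline seed fans out to one independent sub-seed per stage, so
#' that re-ordering or skipping stages does not silently shift the random
#' stream consumed by another stage.
#'
#' @param seed Master seed (single integer).
#' @param n Number of sub-seeds to derive.
#' @return An integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @examples
#' derive_seeds(42, 3)
#' @export
derive_seeds <- function(seed, n) {
  check_number(seed, "seed")
  check_number(n, "n", lower = 1)
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# run code under a seed if one is given, otherwise use the ambient RNG state
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# strictly-increasing uniform-grid check; returns the sampling interval
uniform_dt <- function(time_s, tol = 1e-6) {
  dt <- diff(time_s)
  if (length(dt) < 1 || any(dt <= 0)) {
    abort("`time_s` must be strictly increasing.")
  }
  dt0 <- median(dt)
  if (max(abs(dt - dt0)) > tol * dt0) {
    abort("series must be uniformly sampled; run gaussian_interpolate() first.")
  }
  dt0
}

as_series <- function(x, arg = "series") {
  if (!is.data.frame(x) || !all(c("time_s", "frequency_hz") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns time_s, frequency_hz.", arg))
  }
  tibble::as_tibble(x[c("time_s", "frequency_hz")])
}
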