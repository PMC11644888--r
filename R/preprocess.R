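#' Gaussian interpolation weight
#'
#' The raw weight given to a sample at lag `dt` seconds from a grid point:
#' `exp(-dt^2 / (2 sigma_s^2)) / sqrt(2 pi)`. [gaussian_interpolate()]
#' renormalizes these per grid point by default.
#'
#' @param dt Time lag in seconds (vectorized).
#' @param sigma_s Kernel width in seconds.
#' @return Numeric weights; `1/sqrt(2*pi)` at `dt = 0`.
#' @export
gaussian_weight <- function(dt, sigma_s) {
  check_number(sigma_s, "sigma_s", lower = 0, strict = TRUE)
  exp(-dt^2 / (2 * sigma_s^2)) / sqrt(2 * pi)
}

#' Interpolate an irregular series onto a uniform grid
#'
#' Capacitance-to-frequency front ends deliver samples at slightly jittered
#' times. Each output value at grid time `n * period` is the
#' Gaussian-weighted sum of the measured values nearby. Weights are
#' renormalized to sum to one per grid point, so a constant signal is a
#' fixed point regardless of the local sample density; `normalize = FALSE`
#' gives the plain (unnormalized) weighted sum.
#'
#' Grid points with no sample inside the truncated support yield `NA` and a
#' warning.
#'
#' @param series Data frame with columns `time_s`, `frequency_hz`; times
#'   strictly increasing.
#' @param period Target sampling period `T` in seconds.
#' @param sigma Kernel width in units of `period` (default 1).
#' @param half_width Kernel truncation: samples further than
#'   `half_width * period` from a grid point are ignored (default 3).
#' @param normalize Renormalize weights per grid point (default `TRUE`).
#' @return A uniform tibble with columns `time_s`, `frequency_hz`.
#' @examples
#' s <- tibble::tibble(time_s = sort(runif(50, 0, 5)), frequency_hz = 7)
#' all.equal(unique(gaussian_interpolate(s, 0.1)$frequency_hz), 7)
#' @export
gaussian_interpolate <- function(series, period = 0.01, sigma = 1,
                                 half_width = 3, normalize = TRUE) {
  series <- as_series(series)
  if (nrow(series) == 0) abort("`series` is empty.")
  check_number(period, "period", lower = 0, strict = TRUE)
  check_number(sigma, "sigma", lower = 0, strict = TRUE)
  check_number(half_width, "half_width", lower = 0, strict = TRUE)
  t_in <- series$time_s
  if (is.unsorted(t_in, strictly = TRUE)) {
    abort("`series$time_s` must be strictly increasing.")
  }
  x <- series$frequency_hz
  w_s <- half_width * period
  # snap the grid to the sampled span: keep every grid point within half a
  # period of it, so jitter at the ends cannot shave off boundary points
  n0 <- ceiling((min(t_in) - period / 2) / period)
  n1 <- floor((max(t_in) + period / 2) / period)
  if (n1 < n0) abort("series span is shorter than one grid period.")
  ngrid <- n1 - n0 + 1

  # scatter each sample onto the grid points inside its support
  lo <- pmax(ceiling((t_in - w_s) / period), n0)
  hi <- pmin(floor((t_in + w_s) / period), n1)
  keep <- hi >= lo
  cnt <- hi[keep] - lo[keep] + 1
  gidx <- sequence(cnt) - 1 + rep(lo[keep], cnt) # grid index n
  ts <- rep(t_in[keep], cnt)
  xs <- rep(x[keep], cnt)
  w <- gaussian_weight(ts - gidx * period, sigma * period)
  pos <- gidx - n0 + 1
  num <- numeric(ngrid)
  den <- numeric(ngrid)
  agg <- rowsum(cbind(w * xs, w), pos)
  at <- as.integer(rownames(agg))
  num[at] <- agg[, 1]
  den[at] <- agg[, 2]
  empty <- den == 0
  if (any(empty)) {
    warn(sprintf(
      "%d grid point(s) had no samples within +/-%g s; returned NA.",
      sum(empty), w_s
    ))
  }
  val <- if (normalize) num / den else num
  val[empty] <- NA_real_
  tibble::tibble(time_s = (n0:n1) * period, frequency_hz = val)
}

#' Band-pass filter specification
#'
#' Defaults to the blink band: passband \[2.0, 5.5\] Hz, order 128. Human
#' blinks last roughly 0.2 s to 0.4 s, i.e. 2.5-5 Hz; the band-pass removes
#' both slow baseline drift and broadband sensor noise.
#'
#' @param order Filter order (even, >= 2). The filter is realized as
#'   `order / 2` second-order sections, which stays numerically stable at
#'   high orders where a direct-form recursion would not.
#' @param band Passband edges `c(low, high)` in Hz.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 128, band = c(2, 5.5)) {
  check_number(order, "order", lower = 2)
  if (order %% 2 != 0) abort("`order` must be even.")
  check_number(band, "band", lower = 0, strict = TRUE, len = 2L)
  if (band[1] >= band[2]) abort("`band` must satisfy low < high.")
  structure(list(order = order, band = band), class = "filter_spec")
}

#' Design a Butterworth band-pass as second-order sections
#'
#' Analog Butterworth prototype, low-pass-to-band-pass transform, bilinear
#' transform with prewarping, then factorization into biquads: poles are
#' processed from closest to the unit circle outward, each conjugate pair
#' paired with the nearest available zeros (the band-pass places `order/2`
#' zeros at z = 1 and `order/2` at z = -1), and sections are ordered by
#' ascending pole radius with each section scaled to unit gain at the band
#' centre. This pairing/ordering keeps round-off noise bounded even at
#' order 128.
#'
#' @param order Total band-pass order (even).
#' @param low,high Passband edges in Hz; `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @return A numeric matrix with `order/2` rows and columns
#'   `b0, b1, b2, a0, a1, a2`.
#' @export
butter_bandpass_sos <- function(order, low, high, fs) {
  check_number(order, "order", lower = 2)
  if (order %% 2 != 0) abort("`order` must be even.")
  if (!(low > 0 && high > low && high < fs / 2)) {
    abort("need 0 < low < high < fs / 2.")
  }
  N <- order / 2
  theta <- pi * (2 * seq_len(N) - 1) / (2 * N)
  p_lp <- complex(real = -sin(theta), imaginary = cos(theta))
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  p_bp <- unlist(lapply(p_lp, function(p) {
    b <- p * bw / 2
    r <- sqrt(b^2 - w0^2)
    c(b + r, b - r)
  }))
  z_p <- (fs2 + p_bp) / (fs2 - p_bp)
  pos <- z_p[Im(z_p) >= 0] # one pole per conjugate pair
  avail <- c(p1 = N, m1 = N) # pools of zeros at +1 / -1
  sos <- matrix(0, nrow = N, ncol = 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  for (i in order(-Mod(pos))) {
    p <- pos[i]
    pick <- function() {
      near <- if (Mod(p - 1) <= Mod(p + 1)) "p1" else "m1"
      if (avail[near] == 0) near <- setdiff(c("p1", "m1"), near)
      avail[near] <<- avail[near] - 1
      if (near == "p1") 1 else -1
    }
    z1 <- pick()
    z2 <- pick()
    sos[i, ] <- c(1, -(z1 + z2), z1 * z2, 1, -2 * Re(p), Mod(p)^2)
  }
  sos <- sos[order(Mod(pos)), , drop = FALSE]
  f0 <- fs / pi * atan(w0 / fs2) # band centre, unwarped
  z0 <- exp(2i * pi * f0 / fs)
  for (i in seq_len(N)) {
    g <- Mod((sos[i, 1] + sos[i, 2] / z0 + sos[i, 3] / z0^2) /
      (sos[i, 4] + sos[i, 5] / z0 + sos[i, 6] / z0^2))
    sos[i, 1:3] <- sos[i, 1:3] / g
  }
  sos
}

#' Magnitude response of a second-order-section cascade
#'
#' @param sos Section matrix from [butter_bandpass_sos()].
#' @param f Frequencies in Hz (vectorized).
#' @param fs Sampling rate in Hz.
#' @return `|H(f)|` for a single (one-way) pass; a zero-phase
#'   forward-backward application squares this.
#' @export
sos_response <- function(sos, f, fs) {
  z <- exp(2i * pi * f / fs)
  H <- rep(1 + 0i, length(z))
  for (i in seq_len(nrow(sos))) {
    H <- H * (sos[i, 1] + sos[i, 2] / z + sos[i, 3] / z^2) /
      (sos[i, 4] + sos[i, 5] / z + sos[i, 6] / z^2)
  }
  Mod(H)
}

# one biquad, forward pass (FIR part vectorized, AR part via stats::filter)
biquad_filter <- function(b, a, x) {
  n <- length(x)
  v <- b[1] * x + b[2] * c(0, x[-n]) + b[3] * c(0, 0, x[-c(n - 1, n)])
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

sos_filtfilt <- function(sos, x, pad = NULL) {
  n <- length(x)
  pad <- pad %||% min(n - 1, 30 * nrow(sos))
  run <- function(y) {
    for (i in seq_len(nrow(sos))) y <- biquad_filter(sos[i, 1:3], sos[i, 4:6], y)
    y
  }
  ext <- c(
    2 * x[1] - x[seq(pad + 1, 2)], x,
    2 * x[n] - x[seq(n - 1, n - pad)]
  )
  y <- rev(run(rev(run(ext))))
  y[seq(pad + 1, pad + n)]
}

#' Zero-phase band-pass filtering to the blink band
#'
#' Applies the second-order-section Butterworth design forward and backward
#' (cancelling phase delay) to a uniformly sampled series. The input mean is
#' removed first; the output is zero-mean by construction since the passband
#' excludes DC. Edge transients are controlled by odd-symmetric reflection
#' padding.
#'
#' @param series Uniform data frame with `time_s`, `frequency_hz` (from
#'   [gaussian_interpolate()] or [generate_recording()] without jitter).
#' @param spec A [filter_spec()].
#' @param pad Reflection pad length in samples (default `30 * order / 2`,
#'   capped at the series length).
#' @return A tibble with `time_s` and the filtered `frequency_hz`.
#' @export
bandpass <- function(series, spec = filter_spec(), pad = NULL) {
  series <- as_series(series)
  stopifnot(inherits(spec, "filter_spec"))
  dt <- uniform_dt(series$time_s)
  fs <- 1 / dt
  if (anyNA(series$frequency_hz)) {
    abort("series contains NA values; fill or drop them before filtering.")
  }
  if (spec$band[2] >= fs / 2) {
    abort(sprintf(
      "passband edge %g Hz is not below Nyquist (%g Hz).",
      spec$band[2], fs / 2
    ))
  }
  sos <- butter_bandpass_sos(spec$order, spec$band[1], spec$band[2], fs)
  x <- series$frequency_hz - mean(series$frequency_hz)
  tibble::tibble(time_s = series$time_s, frequency_hz = sos_filtfilt(sos, x, pad))
}

#' First-order band-pass magnitude response (reference)
#'
#' The textbook single-pole high-pass/low-pass cascade
#' `|H| = (f/low) / sqrt(1 + (f/low)^2) / sqrt(1 + (f/high)^2)` with corner
#' frequencies at the band edges. Provided as an analytical reference only;
#' the pipeline filters with the Butterworth design in [bandpass()].
#'
#' @param f Frequencies in Hz.
#' @param band Corner frequencies `c(low, high)` in Hz.
#' @return `|H(f)|`.
#' @export
first_order_band_response <- function(f, band = c(2, 5.5)) {
  r <- f / band[1]
  (r / sqrt(1 + r^2)) / sqrt(1 + (f / band[2])^2)
}
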