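#' RLC tank circuit parameters
#'
#' The sensing electrode sits in parallel with a fixed inductor `L` and
#' capacitor `C`; the eye contributes a variable capacitance on top of `C`.
#' Defaults follow a typical capacitance-to-digital front-end tank
#' (18 uH, 33 pF).
#'
#' @param L Inductance in henry (> 0).
#' @param C Fixed capacitance in farad (>= 0).
#' @return A `circuit_params` list with elements `L` and `C`.
#' @examples
#' circuit_params()
#' @export
circuit_params <- function(L = 18e-6, C = 33e-12) {
  check_number(L, "L", lower = 0, strict = TRUE)
  check_number(C, "C", lower = 0)
  structure(list(L = L, C = C), class = "circuit_params")
}

#' Dielectric stack model of the electrode-eye capacitor
#'
#' The space between the electrode plate and the effective ground plate is
#' modelled as up to three dielectric layers in series: the air gap in front
#' of the lid, the eyelid itself (present only while the eye is closed), and
#' the remaining tissue. Water-rich tissue has a relative permittivity close
#' to 100, air close to 1, which is what makes a lid passage measurable.
#'
#' @param eps Relative dielectric constants `c(air, eyelid, tissue)`, all >= 1.
#' @param d Layer thicknesses in metres `c(air gap, eyelid, tissue)`, all > 0.
#' @param S Plate area in square metres (> 0). Default: a 25 mm x 8 mm
#'   copper-foil electrode.
#' @param k Electrostatic constant in N m^2 / C^2.
#' @return An `eye_model` list.
#' @examples
#' m <- eye_model()
#' capacitance_closed(m) / capacitance_open(m)
#' @export
eye_model <- function(eps = c(1, 100, 100), d = c(5e-3, 1e-3, 50e-3),
                      S = 25e-3 * 8e-3, k = 8.99e9) {
  check_number(eps, "eps", lower = 1, len = 3L)
  check_number(d, "d", lower = 0, strict = TRUE, len = 3L)
  check_number(S, "S", lower = 0, strict = TRUE)
  check_number(k, "k", lower = 0, strict = TRUE)
  structure(list(eps = eps, d = d, S = S, k = k), class = "eye_model")
}

#' Resonance frequency of the RLC tank
#'
#' `f = 1 / (2 pi sqrt(L (C + cx)))`. The frequency is strictly decreasing in
#' the sensed capacitance `cx`, so a lid passage (which raises `cx`) shows up
#' as a frequency dip.
#'
#' @param circuit A [circuit_params()] object.
#' @param cx Sensed capacitance in farad (vectorized); `C + cx` must be > 0.
#' @return Frequency in Hz.
#' @examples
#' resonance_frequency(circuit_params(1 / (4 * pi^2), 1), 0) # 1 Hz
#' @export
resonance_frequency <- function(circuit, cx) {
  stopifnot(inherits(circuit, "circuit_params"))
  if (!is.numeric(cx) || anyNA(cx)) abort("`cx` must be numeric.")
  ct <- circuit$C + cx
  if (any(ct <= 0)) abort("total capacitance C + cx must be positive.")
  1 / (2 * pi * sqrt(circuit$L * ct))
}

# series combination of parallel-plate layers: C = S / (4 pi k sum(d_i/eps_i))
layer_series_capacitance <- function(model, d, eps) {
  model$S / (4 * pi * model$k * sum(d / eps))
}

#' Equivalent capacitance with the eye closed
#'
#' With the lid in front of the plate the gap holds three layers in series
#' (air, eyelid, tissue): `Cx = S / (4 pi k (d1/e1 + d2/e2 + d3/e3))`.
#'
#' @param model An [eye_model()] object.
#' @return Capacitance in farad.
#' @export
capacitance_closed <- function(model) {
  stopifnot(inherits(model, "eye_model"))
  layer_series_capacitance(model, model$d, model$eps)
}

#' Equivalent capacitance with the eye open
#'
#' With the lid out of the way, air fills its former position, leaving two
#' layers: `Cx' = S / (4 pi k ((d1 + d2)/e1 + d3/e3))`.
#'
#' @inheritParams capacitance_closed
#' @return Capacitance in farad.
#' @export
capacitance_open <- function(model) {
  stopifnot(inherits(model, "eye_model"))
  layer_series_capacitance(
    model,
    c(model$d[1] + model$d[2], model$d[3]),
    model$eps[c(1, 3)]
  )
}

#' Closed/open capacitance ratio
#'
#' Closed form
#' `(d1/e1 + d2/e1 + d3/e3) / (d1/e1 + d2/e2 + d3/e3)`; always >= 1 when the
#' eyelid permittivity exceeds that of air, i.e. closing the eye raises the
#' sensed capacitance and lowers the resonance frequency.
#'
#' @inheritParams capacitance_closed
#' @return Dimensionless ratio.
#' @export
capacitance_ratio <- function(model) {
  stopifnot(inherits(model, "eye_model"))
  e <- model$eps
  d <- model$d
  (d[1] / e[1] + d[2] / e[1] + d[3] / e[3]) /
    (d[1] / e[1] + d[2] / e[2] + d[3] / e[3])
}
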