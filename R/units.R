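# Internal unit system: time ms, length um, diffusivity um^2/ms, gradient mT/m,
# q um^-1 (cycles). 1 um^2/ms == 1e-3 mm^2/s; user-facing b-values are s/mm^2.

#' Physical and protocol constants
#'
#' `GAMMA_PROTON` is the proton gyromagnetic ratio, rad s^-1 T^-1.
#' `STEAM_TM_OFFSET` is the constant `Delta - TM` offset (ms) of the STEAM
#' protocols built by [steam_scheme()], inferred from the protocol's
#' gradient-spacing and mixing-time lists (sequence dead time around the
#' pulses).
#'
#' @name axontime-constants
#' @aliases GAMMA_PROTON STEAM_TM_OFFSET
#' @export GAMMA_PROTON STEAM_TM_OFFSET
NULL

GAMMA_PROTON <- 2.6752218744e8

# Same constant in internal units: rad ms^-1 T^-1.
.gamma_ms <- GAMMA_PROTON * 1e-3

STEAM_TM_OFFSET <- 33.6

#' Convert between gradient amplitude, q-value and b-value
#'
#' Rectangular-pulse conventions for a pulsed-gradient (or STEAM) experiment:
#' `q = gamma * delta * g / (2 pi)` and `b = 4 pi^2 q^2 (Delta - delta/3)`.
#'
#' @param g Gradient amplitude, mT/m.
#' @param b b-value, s/mm^2.
#' @param q q-value, um^-1.
#' @param delta Gradient pulse duration, ms.
#' @param Delta Gradient pulse spacing, ms.
#'
#' @return `q_from_gradient()` returns q in um^-1; `b_from_gradient()` returns
#'   b in s/mm^2; `gradient_from_b()` returns g in mT/m.
#'
#' @examples
#' b_from_gradient(70, delta = 17, Delta = 48)
#' gradient_from_b(4000, delta = 17, Delta = 48)
#' @export
q_from_gradient <- function(g, delta) {
  # g [mT/m] = g * 1e-9 T/um
  .gamma_ms * delta * (g * 1e-9) / (2 * pi)
}

#' @rdname q_from_gradient
#' @export
b_from_gradient <- function(g, delta, Delta) {
  stopifnot(all(delta > 0), all(Delta >= delta))
  q <- q_from_gradient(g, delta)
  # internal b in ms/um^2 -> s/mm^2
  1000 * 4 * pi^2 * q^2 * (Delta - delta / 3)
}

#' @rdname q_from_gradient
#' @export
gradient_from_b <- function(b, delta, Delta) {
  if (any(delta <= 0) || any(Delta < delta)) {
    stop("require Delta >= delta > 0", call. = FALSE)
  }
  if (any(b < 0)) stop("b must be >= 0", call. = FALSE)
  q <- sqrt((b / 1000) / (4 * pi^2 * (Delta - delta / 3)))
  q * 2 * pi / (.gamma_ms * delta) / 1e-9
}

# b in internal units ms/um^2 from a q in um^-1
.b_internal <- function(q, delta, Delta) {
  4 * pi^2 * q^2 * (Delta - delta / 3)
}
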