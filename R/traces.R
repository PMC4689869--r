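#' Difference-of-exponentials trace kernel
#'
#' `psi(t) = (exp(-t / tau_psi) - exp(-t / nu_psi)) / (tau_psi - nu_psi)`,
#' the unit-area causal kernel used to turn a spike train into a smooth
#' firing-rate estimate. It vanishes at `t = 0`, peaks after a few `nu_psi`,
#' and integrates to exactly 1 (per ms), so convolving a spike train with it
#' yields an unbiased instantaneous-rate estimate in spikes/ms.
#'
#' @param t lag (ms), vectorized, non-negative.
#' @param p a [trace_params()] object.
#' @return Kernel values (1/ms).
#' @export
psi_kernel <- function(t, p) {
  stopifnot(all(t >= 0),
            "tau_psi must differ from nu_psi" = p$tau_psi != p$nu_psi)
  (exp(-t / p$tau_psi) - exp(-t / p$nu_psi)) / (p$tau_psi - p$nu_psi)
}

#' Advance a spike-activity trace one step
#'
#' State-space form of the convolution with [psi_kernel()]: two exponential
#' accumulators (`e_tau`, `e_nu`), each decaying with its time constant and
#' incremented by 1 on a spike, whose scaled difference equals the
#' convolution exactly on the time grid. The convolution (spikes/ms) is
#' scaled by 1000 to a firing-rate trace in Hz, truncated at `f_max`, and
#' then normalized, giving the activity trace `x_bar` in `[0, 1]` used by
#' the plasticity rule.
#'
#' @param state list with `e_tau` and `e_nu`.
#' @param p a [trace_params()] object.
#' @param spiked logical: did the neuron spike this step?
#' @param dt step (ms).
#' @return Updated state with `rate_hz` (non-normalized firing-rate trace,
#'   not truncated) and `x_bar` (normalized, truncated) elements.
#' @export
trace_step <- function(state, p, spiked, dt) {
  stopifnot(dt > 0)
  state$e_tau <- state$e_tau * exp(-dt / p$tau_psi)
  state$e_nu <- state$e_nu * exp(-dt / p$nu_psi)
  if (isTRUE(spiked)) {
    state$e_tau <- state$e_tau + 1
    state$e_nu <- state$e_nu + 1
  }
  conv <- (state$e_tau - state$e_nu) / (p$tau_psi - p$nu_psi)
  state$rate_hz <- 1000 * conv
  state$x_bar <- min(state$rate_hz, p$f_max) / p$f_max
  state
}

#' Initial (empty) trace state
#' @return A trace state list with zeroed accumulators.
#' @keywords internal
trace_state <- function() {
  list(e_tau = 0, e_nu = 0, rate_hz = 0, x_bar = 0)
}
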