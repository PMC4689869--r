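#' Gated steepest descent weight derivative
#'
#' `d w_hat / dt = eta * pf_bar * (mli_bar - gamma * w_hat)` (1/ms).
#' The presynaptic trace gates plasticity — with `pf_bar = 0` nothing
#' changes — and `gamma * w_hat` is a dynamic threshold: activity above it
#' potentiates (LTP), below it depresses (LTD). The rule is self-stabilizing;
#' with constant inputs the weight relaxes exponentially to
#' `mli_bar / gamma` at rate `eta * pf_bar * gamma`.
#'
#' @param pf_bar presynaptic (PF) activity trace, in \[0, 1\].
#' @param mli_bar postsynaptic (MLI) activity trace, in \[0, 1\].
#' @param w_hat variable weight component, in \[0, 1\].
#' @param p a [plasticity_params()] object (only `eta` and the first gamma
#'   value are used here), or a list with `eta` and scalar `gamma`.
#' @param gamma optional scalar overriding the parameter object's gamma.
#' @return Derivative (1/ms). Vectorized over the trace/weight arguments.
#' @export
weight_derivative <- function(pf_bar, mli_bar, w_hat, p, gamma = NULL) {
  g <- gamma %||% if (inherits(p$gamma, "gamma_schedule"))
    p$gamma$gamma[1] else p$gamma
  p$eta * pf_bar * (mli_bar - g * w_hat)
}

#' Advance the variable weight component one Euler step
#'
#' One forward-Euler step of [weight_derivative()], with the result clipped
#' to `[0, 1]`. Applied every integration step (the traces already carry the
#' spike timing), not per presynaptic spike.
#'
#' @inheritParams weight_derivative
#' @param dt step (ms).
#' @return Updated `w_hat`, in `[0, 1]`.
#' @export
weight_step <- function(w_hat, pf_bar, mli_bar, p, dt, gamma = NULL) {
  stopifnot(dt > 0)
  w <- w_hat + dt * weight_derivative(pf_bar, mli_bar, w_hat, p, gamma)
  pmin(1, pmax(0, w))
}

#' Fixed point of the plasticity rule
#'
#' With sustained presynaptic activity the weight converges to
#' `clip(mli_bar / gamma, 0, 1)`. Used to initialize weights "near
#' equilibrium" for a given baseline postsynaptic activity level.
#'
#' @param mli_bar postsynaptic activity trace, in \[0, 1\].
#' @param gamma threshold scale (> 0).
#' @return Equilibrium `w_hat` in `[0, 1]`.
#' @examples
#' equilibrium_weight(0.2, 1)    # baseline: 30 Hz / 150 Hz = 0.2
#' equilibrium_weight(0.2, 0.5)  # lowered threshold -> higher equilibrium
#' @export
equilibrium_weight <- function(mli_bar, gamma) {
  stopifnot("gamma must be > 0" = all(gamma > 0))
  pmin(1, pmax(0, mli_bar / gamma))
}
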