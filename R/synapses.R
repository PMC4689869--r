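#' Effective synaptic weight
#'
#' Maps the variable weight component `w_hat` in `[0, 1]` onto the effective
#' weight `w = w0 + (1 - w0) * w_hat`, which is confined to `[w0, 1]`:
#' the synapse never weakens below its fixed minimal efficacy `w0`.
#'
#' @param w0 minimal weight, in (0, 1).
#' @param w_hat variable component, in \[0, 1\] (vectorized).
#' @return Effective weight(s) in `[w0, 1]`.
#' @examples
#' effective_weight(0.2, c(0, 0.2, 1))
#' @export
effective_weight <- function(w0, w_hat) {
  stopifnot("w0 must lie in (0, 1)" = all(w0 > 0 & w0 < 1),
            "w_hat must lie in [0, 1]" = all(w_hat >= -1e-12 & w_hat <= 1 + 1e-12))
  w0 + (1 - w0) * w_hat
}

#' Advance the AMPA kinetic state of one synapse
#'
#' The AMPA conductance kernel is a double exponential with instantaneous
#' rise: each component decays with its own time constant and jumps by its
#' amplitude (`alpha_fast` = 0.8, `alpha_slow` = 0.2) when the presynaptic
#' fiber spikes. Summing the two components reproduces, exactly on the time
#' grid, the convolution of the spike train with
#' `alpha_fast exp(-t/tau_fast) + alpha_slow exp(-t/tau_slow)`.
#' The per-synapse conductance contribution is
#' `g_ampa_max * w * (a_fast + a_slow)`.
#'
#' @param state list with `a_fast`, `a_slow` (kernel states) and `w_hat`.
#' @param p a [synapse_params()] object.
#' @param spiked logical: did the presynaptic fiber spike this step?
#' @param dt step (ms).
#' @return Updated state with element `g` (nS), the conductance contribution
#'   evaluated after the update.
#' @export
ampa_step <- function(state, p, spiked, dt) {
  stopifnot(dt > 0)
  state$a_fast <- state$a_fast * exp(-dt / p$tau_fast)
  state$a_slow <- state$a_slow * exp(-dt / p$tau_slow)
  if (isTRUE(spiked)) {
    state$a_fast <- state$a_fast + p$alpha_fast
    state$a_slow <- state$a_slow + p$alpha_slow
  }
  w <- effective_weight(p$w0, state$w_hat)
  state$g <- p$g_ampa_max * w * (state$a_fast + state$a_slow)
  state
}

#' Advance the pooled NMDA receptor state
#'
#' MLI NMDA receptors are extrasynaptic and activated by glutamate spillover,
#' so a single receptor pool serves all PF inputs and its conductance is not
#' scaled by synaptic weight. The glutamate availability accumulator `n`
#' decays with `tau_n` and increments by one per PF spike (pooled over
#' fibers); the open-channel fraction `R` follows one Euler step of
#' `dR/dt = log(n + 1) (1 - R) / tau_rise - R / tau_decay`
#' (the logarithm keeps the drive numerically tame), clipped to `[0, 1]`
#' to guard against Euler overshoot.
#'
#' @param state list with `n` and `r`.
#' @param p a [synapse_params()] object.
#' @param n_spikes number of PF spikes this step, pooled over all fibers.
#' @param dt step (ms).
#' @return Updated state.
#' @export
nmda_step <- function(state, p, n_spikes, dt) {
  stopifnot(dt > 0, n_spikes >= 0)
  state$n <- state$n * exp(-dt / p$tau_n) + n_spikes
  dr <- log(state$n + 1) * (1 - state$r) / p$tau_rise - state$r / p$tau_decay
  state$r <- min(1, max(0, state$r + dt * dr))
  state
}

#' Voltage-dependent NMDA conductance
#'
#' `g_nmda_max * R / (1 + rho * mg_out * exp(sigma * V))`: the classic
#' extracellular-magnesium block, relieved with depolarization (`sigma` < 0,
#' so the block factor increases monotonically with V).
#'
#' @param state list with open-channel fraction `r` in `[0, 1]`.
#' @param p a [synapse_params()] object.
#' @param v membrane potential (mV), vectorized.
#' @return Conductance (nS).
#' @examples
#' p <- synapse_params()
#' nmda_conductance(list(r = 1), p, 0)    # ~0.75 nS, block mostly relieved
#' nmda_conductance(list(r = 1), p, -68)  # ~0.04 nS, blocked at rest
#' @export
nmda_conductance <- function(state, p, v) {
  stopifnot(state$r >= 0, state$r <= 1)
  p$g_nmda_max * state$r / (1 + p$rho * p$mg_out * exp(p$sigma * v))
}
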