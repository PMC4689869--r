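#' Draw the intrinsic spontaneous-firing current
#'
#' One gamma-distributed sample per integration step provides the stochastic
#' depolarizing drive that makes the isolated MLI fire tonically. Uses R's
#' global random number stream, so runs are reproducible under `set.seed()`.
#'
#' @param n number of draws.
#' @param p a [neuron_params()] object.
#' @return Numeric vector of currents (nA), all non-negative.
#' @export
draw_intrinsic_current <- function(n, p) {
  stats::rgamma(n, shape = p$kappa, scale = p$beta)
}

#' After-hyperpolarization conductance
#'
#' The AHP conductance activated by the most recent spike:
#' `g_ahp_max * exp(-(t - t_spiked) / tau_ahp)`. Only the last spike counts;
#' a fresh spike resets the envelope to its peak. There is no hard voltage
#' reset in this model — the AHP conductance (50 nS pulling toward -82 mV)
#' carries repolarization on its own.
#'
#' @param t current time (ms).
#' @param t_spiked time of the most recent spike (ms), or `-Inf`/`NA` if the
#'   neuron has never spiked.
#' @param p a [neuron_params()] object.
#' @return Conductance (nS).
#' @examples
#' p <- neuron_params()
#' ahp_conductance(2.5, 0, p)  # one tau later: 50 / e
#' @export
ahp_conductance <- function(t, t_spiked, p) {
  if (is.na(t_spiked) || is.infinite(t_spiked)) return(0)
  stopifnot("t must be >= t_spiked" = t >= t_spiked)
  p$g_ahp_max * exp(-(t - t_spiked) / p$tau_ahp)
}

#' Create a clamp mode
#'
#' Experimental clamp configuration for a protocol phase: `"free"` (no
#' intervention), `"voltage_clamp"` (membrane pinned at `level` mV, no
#' spikes ever emitted) or `"current_inject"` (constant `level` nA added to
#' the membrane equation).
#'
#' @param mode one of `"free"`, `"voltage_clamp"`, `"current_inject"`.
#' @param level hold potential (mV) for voltage clamp, injected current (nA)
#'   for current injection; ignored for `"free"`.
#' @return An object of class `clamp_mode`.
#' @export
clamp_mode <- function(mode = c("free", "voltage_clamp", "current_inject"),
                       level = 0) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(level), length(level) == 1, is.finite(level))
  structure(list(mode = mode, level = level), class = "clamp_mode")
}

#' Constant current holding the membrane at a target potential
#'
#' The injection (nA) that, on average, holds the free membrane at `v_hold`:
#' it balances the leak at `v_hold` and cancels the mean intrinsic drive
#' `kappa * beta`. Used to realize "current clamped near -80 mV" phases.
#'
#' @param v_hold target potential (mV).
#' @param p a [neuron_params()] object.
#' @return Current (nA).
#' @export
hold_current <- function(v_hold, p) {
  (p$g_leak * (v_hold - p$e_leak)) / 1000 - p$kappa * p$beta
}

#' Advance the membrane potential one Euler step
#'
#' Forward-Euler update of the conductance-based membrane equation
#' `C dV/dt = -g_leak (V - E_leak) - g_ahp(t) (V - E_ahp)
#'  - (g_AMPA + g_NMDA) (V - E_exc) + I_spont + I_inject`,
#' with conductances in nS, potentials in mV, currents in nA (converted to pA
#' internally so that `pA / pF = mV / ms`) and C in pF. A fresh intrinsic
#' current is drawn each call. If the updated potential reaches threshold, a
#' spike is flagged (at most one per step) and `t_spiked` is set to the end
#' of the step; there is no voltage reset. Under voltage clamp the potential
#' is pinned and no spike is ever emitted.
#'
#' This scalar version is the reference implementation of one step of the
#' simulation loop; full protocols run through the compiled loop in
#' [run_protocol()].
#'
#' @param state list with `v` (mV), `t_spiked` (ms or `-Inf`), and `clamp`
#'   (a [clamp_mode()]).
#' @param p a [neuron_params()] object.
#' @param g_ampa_total,g_nmda_total total synaptic conductances (nS).
#' @param t time at the start of the step (ms).
#' @param dt step (ms).
#' @param i_spont optional intrinsic current (nA); drawn from the gamma
#'   distribution when `NULL`.
#' @return The updated state list, with a logical `spiked` element added.
#' @export
membrane_step <- function(state, p, g_ampa_total, g_nmda_total, t, dt,
                          i_spont = NULL) {
  stopifnot(dt > 0, g_ampa_total >= 0, g_nmda_total >= 0)
  if (is.null(i_spont)) i_spont <- draw_intrinsic_current(1, p)
  cl <- state$clamp %||% clamp_mode("free")
  if (cl$mode == "voltage_clamp") {
    state$v <- cl$level
    state$spiked <- FALSE
    return(state)
  }
  i_inject <- if (cl$mode == "current_inject") cl$level else 0
  v <- state$v
  g_ahp <- ahp_conductance(t, state$t_spiked %||% -Inf, p)
  dv <- (dt / p$c_m) * (
    -p$g_leak * (v - p$e_leak) -
      g_ahp * (v - p$e_ahp) -
      (g_ampa_total + g_nmda_total) * (v - p$e_exc) +
      1000 * (i_spont + i_inject))
  v <- v + dv
  if (!is.finite(v)) {
    stop("membrane potential became non-finite at t = ", t,
         " ms (numerical blow-up); reduce dt or check parameters")
  }
  spiked <- v >= p$v_threshold
  state$v <- v
  state$spiked <- spiked
  if (spiked) state$t_spiked <- t + dt
  state
}
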