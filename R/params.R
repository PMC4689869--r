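#' Membrane parameters of the model MLI
#'
#' Constructs the parameter set of the conductance-based leaky
#' integrate-and-fire molecular layer interneuron (MLI). Defaults are the
#' published constants for this cell type. The intrinsic depolarizing current
#' is redrawn every integration step from a gamma distribution with shape
#' `kappa` and scale `beta` (nA); its mean `kappa * beta` (about 26.4 pA) is
#' what makes the isolated cell fire spontaneously at roughly 30 Hz.
#'
#' @param c_m membrane capacitance (pF).
#' @param v_threshold spike threshold (mV). On crossing, a spike is emitted
#'   and the after-hyperpolarization (AHP) conductance is activated; there is
#'   no hard voltage reset.
#' @param g_leak leak conductance (nS).
#' @param e_leak leak reversal potential (mV).
#' @param e_exc excitatory (AMPA/NMDA) reversal potential (mV).
#' @param g_ahp_max peak AHP conductance (nS).
#' @param e_ahp AHP reversal potential (mV).
#' @param tau_ahp AHP decay time constant (ms).
#' @param kappa shape of the gamma-distributed intrinsic current.
#' @param beta scale of the gamma-distributed intrinsic current (nA).
#'
#' @return An object of class `neuron_params` (a named list).
#' @examples
#' p <- neuron_params()
#' p$kappa * p$beta  # mean intrinsic current, nA
#' @export
neuron_params <- function(c_m = 14.6, v_threshold = -53, g_leak = 1.6,
                          e_leak = -68, e_exc = 0, g_ahp_max = 50,
                          e_ahp = -82, tau_ahp = 2.5,
                          kappa = 3.966333, beta = 0.006653) {
  p <- list(c_m = c_m, v_threshold = v_threshold, g_leak = g_leak,
            e_leak = e_leak, e_exc = e_exc, g_ahp_max = g_ahp_max,
            e_ahp = e_ahp, tau_ahp = tau_ahp, kappa = kappa, beta = beta)
  stopifnot(
    "c_m, g_leak, g_ahp_max, tau_ahp, kappa, beta must be > 0" =
      all(unlist(p[c("c_m", "g_leak", "g_ahp_max", "tau_ahp",
                     "kappa", "beta")]) > 0),
    "require e_ahp < v_threshold < e_exc" =
      e_ahp < v_threshold && v_threshold < e_exc
  )
  structure(p, class = "neuron_params")
}

#' PF-MLI synapse parameters
#'
#' Kinetic and weight parameters of the parallel fiber (PF) to MLI synapse.
#' AMPA conductances rise instantaneously on a presynaptic spike and decay as
#' a double exponential (`alpha_fast`/`tau_fast`, `alpha_slow`/`tau_slow`).
#' NMDA receptors are extrasynaptic and spillover-activated: their state is
#' pooled over all PF inputs, driven by `log(n + 1)` of a glutamate
#' availability accumulator `n`, and gated by the standard voltage-dependent
#' magnesium block `1 / (1 + rho * mg_out * exp(sigma * V))`.
#'
#' @param g_ampa_max maximal AMPA conductance (nS).
#' @param tau_fast,tau_slow fast/slow AMPA decay constants (ms);
#'   `tau_fast < tau_slow`.
#' @param alpha_fast,alpha_slow kernel amplitudes (sum to 1).
#' @param g_nmda_max maximal NMDA conductance (nS).
#' @param tau_rise,tau_decay NMDA opening/closing time constants (ms).
#' @param tau_n decay constant of the glutamate accumulator (ms).
#' @param rho inverse magnesium affinity (1/mM).
#' @param mg_out extracellular magnesium concentration (mM).
#' @param sigma voltage sensitivity of the block (1/mV, negative).
#' @param w0 fixed minimum weight, in (0, 1). The effective weight is
#'   `w0 + (1 - w0) * w_hat` and so lives in `[w0, 1]`.
#'
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(g_ampa_max = 3, tau_fast = 0.8, tau_slow = 18,
                           alpha_fast = 0.8, alpha_slow = 0.2,
                           g_nmda_max = 1, tau_rise = 3, tau_decay = 40,
                           tau_n = 10, rho = 1 / 3.57, mg_out = 1.2,
                           sigma = -0.062, w0 = 0.2) {
  stopifnot(
    "tau_fast must be < tau_slow" = tau_fast < tau_slow,
    "time constants must be > 0" =
      all(c(tau_fast, tau_slow, tau_rise, tau_decay, tau_n) > 0),
    "alpha_fast + alpha_slow must equal 1" =
      isTRUE(all.equal(alpha_fast + alpha_slow, 1)),
    "w0 must lie in (0, 1)" = w0 > 0 && w0 < 1,
    "conductances must be > 0" = g_ampa_max > 0 && g_nmda_max > 0
  )
  structure(list(g_ampa_max = g_ampa_max, tau_fast = tau_fast,
                 tau_slow = tau_slow, alpha_fast = alpha_fast,
                 alpha_slow = alpha_slow, g_nmda_max = g_nmda_max,
                 tau_rise = tau_rise, tau_decay = tau_decay, tau_n = tau_n,
                 rho = rho, mg_out = mg_out, sigma = sigma, w0 = w0),
            class = "synapse_params")
}

#' Activity-trace parameters
#'
#' Parameters of the normalized spike-activity trace: the spike train is
#' convolved with the unit-area difference-of-exponentials kernel
#' `psi(t) = (exp(-t/tau_psi) - exp(-t/nu_psi)) / (tau_psi - nu_psi)`,
#' scaled to Hz, truncated at `f_max`, and divided by `f_max` so the trace
#' lies in `[0, 1]`. Presets exist for the two populations: MLI
#' (`tau_psi = 60`, `nu_psi = 15`, `f_max = 150`) and PF
#' (`tau_psi = 10`, `nu_psi = 2`, `f_max = 300`).
#'
#' @param cell `"mli"` or `"pf"`, selecting the published preset; ignored
#'   when all three values are given.
#' @param tau_psi slow kernel time constant (ms).
#' @param nu_psi fast kernel time constant (ms); `nu_psi < tau_psi`.
#' @param f_max normalizing maximum firing rate (Hz).
#'
#' @return An object of class `trace_params`.
#' @examples
#' trace_params("pf")$f_max  # 300
#' @export
trace_params <- function(cell = c("mli", "pf"), tau_psi = NULL,
                         nu_psi = NULL, f_max = NULL) {
  cell <- match.arg(cell)
  preset <- switch(cell,
    mli = list(tau_psi = 60, nu_psi = 15, f_max = 150),
    pf  = list(tau_psi = 10, nu_psi = 2,  f_max = 300))
  p <- list(tau_psi = tau_psi %||% preset$tau_psi,
            nu_psi = nu_psi %||% preset$nu_psi,
            f_max = f_max %||% preset$f_max)
  stopifnot("require tau_psi > nu_psi > 0" =
              p$tau_psi > p$nu_psi && p$nu_psi > 0,
            "f_max must be > 0" = p$f_max > 0)
  structure(p, class = "trace_params")
}

#' Gated steepest descent parameters
#'
#' The weight update is `d w_hat / dt = eta * PF_bar * (MLI_bar -
#' gamma * w_hat)`: the presynaptic trace gates learning and
#' `gamma * w_hat` is the dynamic threshold separating LTP from LTD.
#' `gamma` may be a piecewise-constant schedule (see [gamma_schedule()]) to
#' emulate pharmacological modulation of the synapse's basal tone.
#'
#' @param eta learning rate (1/ms).
#' @param gamma threshold scale (dimensionless), or a schedule created by
#'   [gamma_schedule()].
#'
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(eta = 0.001, gamma = 1) {
  gam <- if (inherits(gamma, "gamma_schedule")) gamma else
    gamma_schedule(0, gamma)
  stopifnot("eta must be > 0" = eta > 0,
            "gamma values must be > 0" = all(gam$gamma > 0))
  structure(list(eta = eta, gamma = gam), class = "plasticity_params")
}

#' Piecewise-constant schedule for the threshold scale gamma
#'
#' @param t_start times (ms) at which each value takes effect; the first
#'   must be 0.
#' @param gamma the value in force from the corresponding `t_start` until
#'   the next one.
#' @return An object of class `gamma_schedule`.
#' @examples
#' gamma_schedule(c(0, 5000), c(1, 1.5))  # raise gamma at 5 s
#' @export
gamma_schedule <- function(t_start, gamma) {
  stopifnot(length(t_start) == length(gamma),
            "schedule must start at t = 0" = t_start[1] == 0,
            "t_start must be strictly increasing" =
              all(diff(t_start) > 0) || length(t_start) == 1,
            "gamma values must be > 0" = all(gamma > 0))
  structure(list(t_start = as.numeric(t_start), gamma = as.numeric(gamma)),
            class = "gamma_schedule")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("MLI neuron parameters (leaky integrate-and-fire):\n")
  cat(sprintf("  C = %g pF, g_leak = %g nS, E_leak = %g mV, V_th = %g mV\n",
              x$c_m, x$g_leak, x$e_leak, x$v_threshold))
  cat(sprintf("  AHP: g_max = %g nS, E = %g mV, tau = %g ms\n",
              x$g_ahp_max, x$e_ahp, x$tau_ahp))
  cat(sprintf("  I_spont ~ Gamma(shape %g, scale %g nA); mean %.4g nA\n",
              x$kappa, x$beta, x$kappa * x$beta))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
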