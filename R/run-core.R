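#' Low-level simulation loop
#'
#' Thin wrapper around the compiled Euler loop. Most users should go through
#' [build_protocol()] / [run_protocol()]; this entry point exists for custom
#' phase schedules and for calibration runs.
#'
#' @param duration_ms total simulated time (ms).
#' @param dt integration step (ms).
#' @param np,sp,pp parameter objects ([neuron_params()], [synapse_params()],
#'   [plasticity_params()]).
#' @param n_pf number of parallel fibers (0 for an isolated neuron).
#' @param rate_seg data frame of rate segments (`t_start`, `t_end`, `rate`,
#'   `burst_rate`, `burst_len`, `period`); the same schedule drives every
#'   fiber, with independent Poisson draws per fiber.
#' @param clamp_seg data frame (`t_start`, `mode`, `level`) with mode codes
#'   0 = free, 1 = voltage clamp (level in mV), 2 = current injection
#'   (level in nA); piecewise from each `t_start`.
#' @param gamma_seg data frame (`t_start`, `gamma`).
#' @param trace_mli,trace_pf [trace_params()] for the two populations.
#' @param w_hat_init initial variable weight per fiber.
#' @param record_stride_ms sampling stride of the recorded series (ms).
#' @param trial_times times (ms) at which weights are sampled exactly.
#' @param seed RNG seed (`set.seed` is called when non-NULL).
#' @return Raw list of recorded vectors; see [run_protocol()] for the
#'   packaged form.
#' @export
run_core <- function(duration_ms, dt, np, sp, n_pf, rate_seg, clamp_seg,
                     gamma_seg, pp, w_hat_init,
                     record_stride_ms = 1, trial_times = numeric(0),
                     trace_mli = trace_params("mli"),
                     trace_pf = trace_params("pf"), seed = NULL) {
  stopifnot(duration_ms > 0, dt > 0, n_pf >= 0,
            length(w_hat_init) == n_pf)
  max_rate <- max(rate_seg$rate, rate_seg$burst_rate, 0)
  stopifnot("rate * dt must not exceed 1000 (one spike per step)" =
              max_rate * dt / 1000 <= 1)
  record_stride <- max(1L, as.integer(round(record_stride_ms / dt)))
  trial_steps <- as.integer(round(trial_times / dt))
  stopifnot(all(abs(trial_times / dt - trial_steps) < 1e-6))
  if (!is.null(seed)) set.seed(seed)
  sim_loop_cpp(duration_ms, dt, unclass(np), unclass(sp), as.integer(n_pf),
               as.matrix(rate_seg[, c("t_start", "t_end", "rate",
                                      "burst_rate", "burst_len", "period")]),
               as.matrix(clamp_seg[, c("t_start", "mode", "level")]),
               as.matrix(gamma_seg[, c("t_start", "gamma")]),
               pp$eta, w_hat_init, unclass(trace_mli), unclass(trace_pf),
               record_stride, trial_steps)
}
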