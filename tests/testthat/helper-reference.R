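# Pure-R reference simulation loop, composed from the exported single-step
# operations. Draws randomness in the same order as the compiled loop
# (per step: one uniform per PF fiber, then one gamma), so that with the
# same seed the two implementations can be compared trajectory by
# trajectory.
reference_run <- function(duration_ms, dt = 0.25, n_pf = 1, pf_rate = 20,
                          np = neuron_params(), sp = synapse_params(),
                          pp = plasticity_params(), w_hat_init = 0.2,
                          clamp = clamp_mode("free"), seed = 1) {
  set.seed(seed)
  n_steps <- round(duration_ms / dt)
  neuron <- list(v = np$e_leak, t_spiked = -Inf, clamp = clamp)
  syn <- lapply(seq_len(n_pf), function(i)
    list(a_fast = 0, a_slow = 0, w_hat = w_hat_init, g = 0))
  nmda <- list(n = 0, r = 0)
  tr_mli <- trace_state()
  tr_pf <- lapply(seq_len(n_pf), function(i) trace_state())
  tp_mli <- trace_params("mli")
  tp_pf <- trace_params("pf")
  p_spike <- pf_rate * dt / 1000
  gamma <- pp$gamma$gamma[1]

  v <- numeric(n_steps)
  what <- matrix(NA_real_, n_steps, n_pf)
  mli_spikes <- numeric(0)
  for (k in seq_len(n_steps)) {
    t <- (k - 1) * dt
    sp_now <- stats::runif(n_pf) < p_spike
    i_spont <- draw_intrinsic_current(1, np)
    g_ampa <- 0
    for (i in seq_len(n_pf)) {
      syn[[i]] <- ampa_step(syn[[i]], sp, sp_now[i], dt)
      g_ampa <- g_ampa + syn[[i]]$g
    }
    nmda <- nmda_step(nmda, sp, sum(sp_now), dt)
    g_nmda <- nmda_conductance(nmda, sp, neuron$v)
    neuron <- membrane_step(neuron, np, g_ampa, g_nmda, t, dt,
                            i_spont = i_spont)
    if (isTRUE(neuron$spiked)) mli_spikes <- c(mli_spikes, t + dt)
    tr_mli <- trace_step(tr_mli, tp_mli, neuron$spiked, dt)
    for (i in seq_len(n_pf)) {
      tr_pf[[i]] <- trace_step(tr_pf[[i]], tp_pf, sp_now[i], dt)
      syn[[i]]$w_hat <- weight_step(syn[[i]]$w_hat, tr_pf[[i]]$x_bar,
                                    tr_mli$x_bar, pp, dt, gamma = gamma)
    }
    v[k] <- neuron$v
    what[k, ] <- vapply(syn, function(s) s$w_hat, numeric(1))
  }
  list(time = seq_len(n_steps) * dt, v = v, w_hat = what,
       mli_spikes = mli_spikes)
}

# Brute-force convolution of a spike train with a kernel, evaluated at
# given times: the direct-sum oracle the state-space updates are checked
# against.
convolve_spikes <- function(eval_t, spike_t, kernel_fn) {
  vapply(eval_t, function(tt) {
    lag <- tt - spike_t
    sum(kernel_fn(lag[lag >= 0]))
  }, numeric(1))
}

# Run the compiled loop with a constant-rate free-running configuration
# matching reference_run's assumptions.
core_run_constant <- function(duration_ms, dt = 0.25, n_pf = 1,
                              pf_rate = 20, w_hat_init = 0.2, seed = 1,
                              np = neuron_params(), sp = synapse_params(),
                              pp = plasticity_params(),
                              clamp = data.frame(t_start = 0, mode = 0,
                                                 level = 0),
                              record_stride_ms = dt) {
  run_core(
    duration_ms = duration_ms, dt = dt, np = np, sp = sp, n_pf = n_pf,
    rate_seg = data.frame(t_start = 0, t_end = duration_ms, rate = pf_rate,
                          burst_rate = 0, burst_len = 0, period = 0),
    clamp_seg = clamp,
    gamma_seg = data.frame(t_start = 0, gamma = pp$gamma$gamma[1]),
    pp = pp,
    w_hat_init = if (n_pf == 0) numeric(0) else rep(w_hat_init, n_pf),
    record_stride_ms = record_stride_ms, trial_times = numeric(0),
    seed = seed)
}
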