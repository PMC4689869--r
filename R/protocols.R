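#' Build one of the registered stimulation protocols
#'
#' Returns the fully specified phase schedule for one of the ten in silico
#' electrophysiology protocols (identified by Roman numerals I-X):
#'
#' * **I** — single PF, 100 Hz Poisson bursts (100 ms every 1 s) onto a
#'   spontaneously firing MLI; 60 one-second trials; LTP.
#' * **II** — single PF at 10 Hz, MLI hyperpolarized by calibrated current
#'   injection to ~10 Hz; LTD.
#' * **III** — as II but depolarized to ~40 Hz; LTP.
#' * **IV** — single PF at 2 Hz, MLI spontaneous; no remarkable change.
#' * **V** — 8 PFs at 50 Hz, MLI voltage-clamped to -60 mV; weights decay
#'   to the floor `w0` (LTD).
#' * **VI** — 8 PFs bursting at 100 Hz (100 ms/s), MLI current-clamped near
#'   -80 mV; bursts still depolarize the cell, so LTP.
#' * **VII** — as VI but continuous 2 Hz PF firing; LTD.
#' * **VIII** — MLI voltage-clamped at -60 mV with PFs at 0.33 Hz for 5 s
#'   and the weight started below equilibrium, then depolarized to ~50 Hz
#'   with PFs at 2 Hz for 60 s; LTP.
#' * **IX** / **X** — 8 PFs at 1 Hz, MLI spontaneous; the threshold scale
#'   gamma steps from 1.0 to 1.5 (IX, LTD) or 0.5 (X, LTP) at 5 s for
#'   10 min, emulating basal-tone modulation. Weights are summarized per
#'   minute.
#'
#' Published sources disagree on two PF rates. For VII the protocol
#' description (2 Hz) wins over the summary table (1 Hz). For IX/X the
#' summary table's 1 Hz is used: at 0.33 Hz the presynaptic gate is open so
#' rarely that the weight cannot approach its new equilibrium within the
#' 10 simulated minutes. Use `pf_rate` to override either choice.
#'
#' @param id protocol id, `"I"` to `"X"`.
#' @param n_repeats number of independent repeats (defaults: 10 for I-IV,
#'   1 for V-X).
#' @param base_seed base RNG seed; repeat `r` runs with `base_seed + r`.
#' @param w_hat_init `"equilibrium"` (measure the baseline MLI activity and
#'   start at the rule's fixed point) or a numeric value in \[0, 1\].
#' @param pf_rate optional override of the protocol's stimulation-phase PF
#'   rate (Hz).
#' @param dt integration step (ms).
#' @param record_stride_ms sampling stride for recorded time series (ms).
#' @return An object of class `protocol_spec`.
#' @examples
#' build_protocol("I")
#' @export
build_protocol <- function(id, n_repeats = NULL, base_seed = 1000,
                           w_hat_init = NULL, pf_rate = NULL, dt = 0.25,
                           record_stride_ms = NULL) {
  id <- toupper(as.character(id))
  ids <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")
  if (!id %in% ids) stop("unknown protocol id: ", id)
  baseline <- 0.33
  free_ <- function(t0) data.frame(t_start = t0, mode = "free",
                                   level = 0, target_rate = NA)
  vclamp <- function(t0, mv) data.frame(t_start = t0, mode = "voltage_clamp",
                                        level = mv, target_rate = NA)
  itarget <- function(t0, hz) data.frame(t_start = t0,
                                         mode = "current_target",
                                         level = NA, target_rate = hz)
  ihold <- function(t0, mv, np) data.frame(t_start = t0,
                                           mode = "current_inject",
                                           level = hold_current(mv, np),
                                           target_rate = NA)
  np <- neuron_params()

  cfg <- switch(id,
    I = list(n_pf = 1, dur = 65000, clamp = free_(0), gamma = c(`0` = 1),
             rate = rate_schedule(c(0, 5000), c(5000, 65000),
                                  c(baseline, baseline),
                                  burst_rate = c(NA, 100),
                                  burst_len = c(0, 100), period = c(0, 1000)),
             trial_period = 1000, n_rep = 10),
    II = list(n_pf = 1, dur = 65000,
              clamp = rbind(free_(0), itarget(2500, 10)), gamma = c(`0` = 1),
              rate = rate_schedule(c(0, 5000), c(5000, 65000),
                                   c(baseline, pf_rate %||% 10)),
              trial_period = 1000, n_rep = 10),
    III = list(n_pf = 1, dur = 65000,
               clamp = rbind(free_(0), itarget(2500, 40)), gamma = c(`0` = 1),
               rate = rate_schedule(c(0, 5000), c(5000, 65000),
                                    c(baseline, pf_rate %||% 10)),
               trial_period = 1000, n_rep = 10),
    IV = list(n_pf = 1, dur = 65000, clamp = free_(0), gamma = c(`0` = 1),
              rate = rate_schedule(c(0, 5000), c(5000, 65000),
                                   c(baseline, pf_rate %||% 2)),
              trial_period = 1000, n_rep = 10),
    V = list(n_pf = 8, dur = 65000,
             clamp = rbind(free_(0), vclamp(2500, -60)), gamma = c(`0` = 1),
             rate = rate_schedule(c(0, 5000), c(5000, 65000),
                                  c(baseline, pf_rate %||% 50)),
             trial_period = 1000, n_rep = 1),
    VI = list(n_pf = 8, dur = 65000,
              clamp = rbind(free_(0), ihold(2500, -80, np)),
              gamma = c(`0` = 1),
              rate = rate_schedule(c(0, 5000), c(5000, 65000),
                                   c(baseline, baseline),
                                   burst_rate = c(NA, pf_rate %||% 100),
                                   burst_len = c(0, 100),
                                   period = c(0, 1000)),
              trial_period = 1000, n_rep = 1),
    VII = list(n_pf = 8, dur = 65000,
               clamp = rbind(free_(0), ihold(2500, -80, np)),
               gamma = c(`0` = 1),
               rate = rate_schedule(c(0, 5000), c(5000, 65000),
                                    c(baseline, pf_rate %||% 2)),
               trial_period = 1000, n_rep = 1),
    VIII = list(n_pf = 8, dur = 65000,
                clamp = rbind(vclamp(0, -60), itarget(5000, 50)),
                gamma = c(`0` = 1),
                rate = rate_schedule(c(0, 5000), c(5000, 65000),
                                     c(baseline, pf_rate %||% 2)),
                trial_period = 1000, n_rep = 1, w_init = 0.1),
    IX = list(n_pf = 8, dur = 605000, clamp = free_(0),
              gamma = c(`0` = 1, `5000` = 1.5),
              rate = rate_schedule(0, 605000, pf_rate %||% 1),
              trial_period = 60000, n_rep = 1),
    X = list(n_pf = 8, dur = 605000, clamp = free_(0),
             gamma = c(`0` = 1, `5000` = 0.5),
             rate = rate_schedule(0, 605000, pf_rate %||% 1),
             trial_period = 60000, n_rep = 1))

  trial_onset <- 5000
  n_trials <- (cfg$dur - trial_onset) / cfg$trial_period
  structure(list(
    id = id, n_pf = cfg$n_pf, duration_ms = cfg$dur, dt = dt,
    rate_schedule = cfg$rate, clamp_phases = cfg$clamp,
    gamma = gamma_schedule(as.numeric(names(cfg$gamma)),
                           unname(cfg$gamma)),
    trial_onset = trial_onset, trial_period = cfg$trial_period,
    n_trials = n_trials,
    n_repeats = n_repeats %||% cfg$n_rep, base_seed = base_seed,
    w_hat_init = w_hat_init %||% cfg$w_init %||% "equilibrium",
    record_stride_ms = record_stride_ms %||%
      (if (cfg$dur > 100000) 10 else 1),
    neuron = np, synapse = synapse_params(),
    plasticity = plasticity_params(),
    resolved = FALSE), class = "protocol_spec")
}

#' Registry of the ten protocols
#'
#' @return A tibble with one row per protocol: id, inputs, manipulation,
#'   and the expected direction of the weight change.
#' @export
list_protocols <- function() {
  tibble::tibble(
    id = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X"),
    n_pf = c(1, 1, 1, 1, 8, 8, 8, 8, 8, 8),
    pf_input = c("100 Hz bursts, 100 ms every 1 s", "10 Hz continuous",
                 "10 Hz continuous", "2 Hz continuous", "50 Hz continuous",
                 "100 Hz bursts, 100 ms every 1 s", "2 Hz continuous",
                 "0.33 Hz then 2 Hz", "1 Hz continuous", "1 Hz continuous"),
    mli = c("spontaneous", "hyperpolarized to ~10 Hz",
            "depolarized to ~40 Hz", "spontaneous",
            "voltage clamp -60 mV", "current clamp near -80 mV",
            "current clamp near -80 mV",
            "voltage clamp -60 mV, then depolarized to ~50 Hz",
            "spontaneous, gamma -> 1.5", "spontaneous, gamma -> 0.5"),
    expected = c("LTP", "LTD", "LTP", "none", "LTD", "LTP", "LTD", "LTP",
                 "LTD", "LTP"))
}

#' Measure the baseline MLI activity trace
#'
#' Mean of the normalized MLI activity trace over the second half of a
#' free-running simulation with no synaptic input — the level the rule's
#' equilibrium initialization is computed from (about 0.2 = 30 Hz / 150 Hz).
#'
#' @param np a [neuron_params()] object.
#' @param duration_s run length (s).
#' @param seed dedicated calibration seed.
#' @return Mean normalized activity (dimensionless).
#' @export
baseline_activity <- function(np = neuron_params(), duration_s = 5,
                              seed = 20151) {
  res <- run_core(
    duration_ms = duration_s * 1000, dt = 0.25, np = np,
    sp = synapse_params(), n_pf = 0,
    rate_seg = data.frame(t_start = 0, t_end = duration_s * 1000, rate = 0,
                          burst_rate = 0, burst_len = 0, period = 0),
    clamp_seg = data.frame(t_start = 0, mode = 0, level = 0),
    gamma_seg = data.frame(t_start = 0, gamma = 1),
    pp = plasticity_params(), w_hat_init = numeric(0),
    record_stride_ms = 1, trial_times = numeric(0), seed = seed)
  keep <- res$rec_time >= duration_s * 500
  mean(res$rec_mli_xbar[keep])
}

#' Resolve calibrated quantities of a protocol
#'
#' Replaces target-rate clamp phases with calibrated constant currents
#' (dedicated seed, so calibration noise never leaks into repeats) and an
#' `"equilibrium"` weight initialization with the fixed point of the
#' measured baseline activity. Idempotent.
#'
#' @param spec a `protocol_spec`.
#' @return The spec with `resolved = TRUE`.
#' @export
resolve_protocol <- function(spec) {
  if (isTRUE(spec$resolved)) return(spec)
  if (identical(spec$w_hat_init, "equilibrium")) {
    mli_bar0 <- baseline_activity(spec$neuron)
    spec$w_hat_init <- equilibrium_weight(mli_bar0, spec$gamma$gamma[1])
  }
  cp <- spec$clamp_phases
  for (i in seq_len(nrow(cp))) {
    if (cp$mode[i] == "current_target") {
      # calibrate under the stimulation-phase synaptic drive
      stim_rate <- spec$rate_schedule$rate[nrow(spec$rate_schedule)]
      cp$level[i] <- calibrate_injection(
        cp$target_rate[i], np = spec$neuron, sp = spec$synapse,
        n_pf = spec$n_pf, pf_rate = stim_rate,
        w_hat = mean(spec$w_hat_init), seed = 20152)
      cp$mode[i] <- "current_inject"
    }
  }
  spec$clamp_phases <- cp
  spec$resolved <- TRUE
  spec
}

clamp_mode_code <- c(free = 0, voltage_clamp = 1, current_inject = 2)

#' Run one repeat of a protocol
#'
#' Executes the coupled simulation loop — PF Poisson draws, AMPA/NMDA
#' kinetics, membrane update with spike detection, activity traces, gated
#' steepest descent weight update — for one independent repeat. Repeat `r`
#' is seeded with `base_seed + r`, so results are deterministic given
#' `(spec, repeat_index)`.
#'
#' @param spec a `protocol_spec` from [build_protocol()] (resolved
#'   automatically if needed).
#' @param repeat_index which independent repeat to run (1-based).
#' @return An object of class `mli_sim`: a list with `series` (sampled time
#'   series: membrane potential, MLI rate and activity traces, mean PF
#'   trace, mean weights), `trials` (exact weight samples at trial
#'   boundaries), `spikes` (MLI and PF spike times), the resolved `spec`,
#'   `repeat_index` and `seed`.
#' @export
run_protocol <- function(spec, repeat_index = 1) {
  stopifnot(inherits(spec, "protocol_spec"), repeat_index >= 1)
  spec <- resolve_protocol(spec)
  seed <- spec$base_seed + repeat_index
  w_init <- spec$w_hat_init
  if (length(w_init) == 1) w_init <- rep(w_init, spec$n_pf)
  stopifnot(length(w_init) == spec$n_pf,
            all(w_init >= 0 & w_init <= 1))
  clamp_seg <- data.frame(
    t_start = spec$clamp_phases$t_start,
    mode = unname(clamp_mode_code[spec$clamp_phases$mode]),
    level = spec$clamp_phases$level)
  trial_times <- spec$trial_onset +
    seq(0, spec$n_trials) * spec$trial_period
  res <- run_core(
    duration_ms = spec$duration_ms, dt = spec$dt, np = spec$neuron,
    sp = spec$synapse, n_pf = spec$n_pf,
    rate_seg = as.data.frame(spec$rate_schedule),
    clamp_seg = clamp_seg,
    gamma_seg = data.frame(t_start = spec$gamma$t_start,
                           gamma = spec$gamma$gamma),
    pp = spec$plasticity, w_hat_init = w_init,
    record_stride_ms = spec$record_stride_ms,
    trial_times = trial_times, seed = seed)
  structure(list(
    series = tibble::tibble(
      time_ms = res$rec_time, v_mv = res$rec_v,
      mli_rate_hz = res$rec_mli_rate, mli_xbar = res$rec_mli_xbar,
      pf_xbar = res$rec_pf_xbar, mean_w_hat = res$rec_mean_w_hat,
      mean_w = res$rec_mean_w),
    trials = tibble::tibble(
      trial = seq(0, spec$n_trials), time_ms = res$trial_time,
      mean_w_hat = res$trial_mean_w_hat, mean_w = res$trial_mean_w),
    w_hat_fiber = res$trial_w_hat_fiber,
    spikes = list(mli = res$mli_spikes,
                  pf = tibble::tibble(fiber = res$pf_spike_fiber,
                                      time_ms = res$pf_spike_time)),
    final_w_hat = res$final_w_hat,
    spec = spec, repeat_index = repeat_index, seed = seed),
    class = "mli_sim")
}

#' Run all repeats of a protocol
#'
#' @param spec a `protocol_spec`.
#' @param n_repeats number of repeats; defaults to the spec's.
#' @return List of `mli_sim` objects (one per repeat).
#' @export
run_protocol_set <- function(spec, n_repeats = NULL) {
  spec <- resolve_protocol(spec)
  n <- n_repeats %||% spec$n_repeats
  lapply(seq_len(n), function(r) run_protocol(spec, r))
}

#' Per-repeat trial table
#'
#' Weight values at every trial boundary for every repeat, with percent
#' change from the starting value (the weight at trial onset), for both the
#' effective weight `w` and the variable component `w_hat`.
#'
#' @param results an `mli_sim` or a list of them.
#' @return A tibble with columns `repeat_index`, `trial`, `time_ms`,
#'   `mean_w_hat`, `mean_w`, `pct_change_w_hat`, `pct_change_w`.
#' @export
trial_table <- function(results) {
  if (inherits(results, "mli_sim")) results <- list(results)
  stopifnot(length(results) >= 1)
  dplyr::bind_rows(lapply(results, function(r) {
    tr <- r$trials
    tibble::tibble(
      repeat_index = r$repeat_index, trial = tr$trial, time_ms = tr$time_ms,
      mean_w_hat = tr$mean_w_hat, mean_w = tr$mean_w,
      pct_change_w_hat = 100 * (tr$mean_w_hat / tr$mean_w_hat[1] - 1),
      pct_change_w = 100 * (tr$mean_w / tr$mean_w[1] - 1))
  }))
}

#' Summarize weight changes across repeats
#'
#' Per-trial percent change of the across-synapse mean weight relative to
#' its value at trial onset, aggregated across repeats as mean and min-max
#' range (the published summary format). Both the effective weight `w` and
#' the variable component `w_hat` are reported.
#'
#' @param results an `mli_sim` or list of them (from [run_protocol_set()]).
#' @return A tibble with one row per trial boundary: `trial`, `time_ms`,
#'   `n_repeats`, and for each measure the across-repeat `mean`/`min`/`max`
#'   percent change plus the mean absolute weights.
#' @export
summarize_trials <- function(results) {
  tt <- trial_table(results)
  out <- dplyr::summarise(
    dplyr::group_by(tt, .data$trial, .data$time_ms),
    n_repeats = dplyr::n(),
    mean_w = mean(.data$mean_w),
    mean_w_hat = mean(.data$mean_w_hat),
    pct_w_mean = mean(.data$pct_change_w),
    pct_w_min = min(.data$pct_change_w),
    pct_w_max = max(.data$pct_change_w),
    pct_w_hat_mean = mean(.data$pct_change_w_hat),
    pct_w_hat_min = min(.data$pct_change_w_hat),
    pct_w_hat_max = max(.data$pct_change_w_hat),
    .groups = "drop")
  dplyr::arrange(out, .data$trial)
}

#' Classify the outcome of a completed protocol
#'
#' LTP if the final across-repeat mean percent change of the effective
#' weight exceeds `+threshold`, LTD if below `-threshold`, otherwise
#' `"none"`. The default 5% dead band separates "no remarkable change"
#' from a real direction.
#'
#' @param summary output of [summarize_trials()] (or a list of `mli_sim`
#'   objects, which is summarized first).
#' @param measure `"w"` (effective weight, default) or `"w_hat"`.
#' @param threshold dead-band half-width (percent).
#' @return `"LTP"`, `"LTD"` or `"none"`.
#' @export
classify_outcome <- function(summary, measure = c("w", "w_hat"),
                             threshold = 5) {
  measure <- match.arg(measure)
  if (!is.data.frame(summary)) summary <- summarize_trials(summary)
  final <- summary[which.max(summary$trial), ]
  pct <- if (measure == "w") final$pct_w_mean else final$pct_w_hat_mean
  if (pct > threshold) "LTP" else if (pct < -threshold) "LTD" else "none"
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("Protocol %s: %d PF(s), %.0f s, dt = %g ms, %d trial(s) of %g s\n",
              x$id, x$n_pf, x$duration_ms / 1000, x$dt, x$n_trials,
              x$trial_period / 1000))
  cat(sprintf("  repeats: %d (base seed %d); w_hat init: %s; resolved: %s\n",
              x$n_repeats, x$base_seed,
              paste(format(x$w_hat_init, digits = 3), collapse = ","),
              x$resolved))
  invisible(x)
}

#' @export
print.mli_sim <- function(x, ...) {
  cat(sprintf("Protocol %s, repeat %d (seed %d): %d MLI spikes, %d PF spikes\n",
              x$spec$id, x$repeat_index, x$seed, length(x$spikes$mli),
              nrow(x$spikes$pf)))
  n <- nrow(x$trials)
  cat(sprintf("  mean w: %.3f at trial onset -> %.3f at end (%+.1f%%)\n",
              x$trials$mean_w[1], x$trials$mean_w[n],
              100 * (x$trials$mean_w[n] / x$trials$mean_w[1] - 1)))
  invisible(x)
}
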