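#' Piecewise PF rate schedule
#'
#' Describes the Poisson firing rate of a parallel fiber over time as
#' non-overlapping segments, each with a base rate and an optional periodic
#' burst pattern: within a segment with `period > 0`, the first `burst_len`
#' ms of every `period` ms window fire at `burst_rate`, the remainder at
#' `rate`. Bursts start at the beginning of each window, which makes trial
#' alignment deterministic.
#'
#' @param t_start,t_end segment boundaries (ms); segments must tile the
#'   simulated interval without overlap.
#' @param rate base Poisson rate (Hz).
#' @param burst_rate rate during bursts (Hz); `NA` or with `period = 0`
#'   disables bursting for the segment.
#' @param burst_len burst duration (ms).
#' @param period burst repetition period (ms).
#' @return An object of class `rate_schedule` (a data frame of segments).
#' @examples
#' # 5 s baseline at 0.33 Hz, then 100 Hz/100 ms bursts every second:
#' rate_schedule(c(0, 5000), c(5000, 65000), c(0.33, 0.33),
#'               burst_rate = c(NA, 100), burst_len = c(0, 100),
#'               period = c(0, 1000))
#' @export
rate_schedule <- function(t_start, t_end, rate, burst_rate = NA,
                          burst_len = 0, period = 0) {
  seg <- data.frame(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                    rate = as.numeric(rate),
                    burst_rate = as.numeric(burst_rate),
                    burst_len = as.numeric(burst_len),
                    period = as.numeric(period))
  seg$burst_rate[is.na(seg$burst_rate)] <- 0
  seg <- seg[order(seg$t_start), , drop = FALSE]
  stopifnot("rates must be >= 0" = all(seg$rate >= 0 & seg$burst_rate >= 0),
            "segments must not overlap" =
              all(seg$t_end[-nrow(seg)] <= seg$t_start[-1]),
            "segment ends must exceed starts" = all(seg$t_end > seg$t_start))
  structure(seg, class = c("rate_schedule", "data.frame"))
}

#' Instantaneous rate of a schedule
#'
#' @param schedule a [rate_schedule()].
#' @param t times (ms), vectorized.
#' @return Rates (Hz); 0 outside all segments.
#' @export
schedule_rate <- function(schedule, t) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(schedule))) {
    t0 <- schedule$t_start[i]
    m <- t >= t0 & t < schedule$t_end[i]
    if (!any(m)) next
    r <- rep(schedule$rate[i], sum(m))
    if (schedule$period[i] > 0) {
      local <- (t[m] - t0) %% schedule$period[i]
      r[local < schedule$burst_len[i]] <- schedule$burst_rate[i]
    }
    out[m] <- r
  }
  out
}

#' Generate a Poisson spike train on the integration grid
#'
#' Bernoulli thinning: each step of length `dt` spikes with probability
#' `rate(t) * dt / 1000`, so at most one spike lands per step and spike
#' times are aligned to the grid. Valid while `rate * dt / 1000 <= 1`
#' (satisfied for all protocol rates at the default 0.25 ms step).
#' Reproducible under `set.seed()`.
#'
#' @param schedule a [rate_schedule()].
#' @param t_end simulate from 0 to this time (ms); defaults to the last
#'   segment end.
#' @param dt step (ms).
#' @return Numeric vector of spike times (ms, start-of-step convention).
#' @export
poisson_spikes <- function(schedule, t_end = max(schedule$t_end), dt = 0.25) {
  stopifnot(dt > 0)
  n <- floor(t_end / dt)
  t <- (seq_len(n) - 1) * dt
  rates <- schedule_rate(schedule, t)
  p <- rates * dt / 1000
  stopifnot("rate * dt must not exceed 1000 (thinning validity)" =
              all(p <= 1))
  t[stats::runif(n) < p]
}

#' Calibrate a constant injected current to a target firing rate
#'
#' Finds, by bisection, the constant current that makes the model MLI fire
#' at `target_rate` over a `duration_s`-second simulation. The MLI firing
#' rate is monotone non-decreasing in injected current, which makes
#' bisection sound. Calibration runs use their own seed so the returned
#' current can be frozen into a protocol without perturbing the protocol's
#' random streams.
#'
#' Calibration is performed in the synaptic context the current will be
#' used in: `n_pf` fibers firing Poisson at `pf_rate` with weights fixed at
#' `w_hat` (plasticity frozen), so that the target rate is met under the
#' protocol's actual synaptic drive, not in isolation.
#'
#' @param target_rate target firing rate (Hz).
#' @param np a [neuron_params()] object.
#' @param sp a [synapse_params()] object.
#' @param n_pf number of PF inputs active during calibration.
#' @param pf_rate their Poisson rate (Hz).
#' @param w_hat the (frozen) variable weight component during calibration.
#' @param tolerance acceptable rate error (Hz).
#' @param duration_s calibration run length (s).
#' @param seed RNG seed for the calibration runs.
#' @param bracket initial current interval (nA), widened if needed.
#' @return Current (nA) such that re-simulation fires within `tolerance`
#'   of `target_rate`.
#' @export
calibrate_injection <- function(target_rate, np = neuron_params(),
                                sp = synapse_params(), n_pf = 0,
                                pf_rate = 0, w_hat = 0, tolerance = 1,
                                duration_s = 30, seed = 12345,
                                bracket = c(-0.5, 1)) {
  rate_at <- function(i_nA) {
    res <- run_core(
      duration_ms = duration_s * 1000, dt = 0.25, np = np, sp = sp,
      n_pf = n_pf,
      rate_seg = data.frame(t_start = 0, t_end = duration_s * 1000,
                            rate = pf_rate, burst_rate = 0, burst_len = 0,
                            period = 0),
      clamp_seg = data.frame(t_start = 0, mode = 2, level = i_nA),
      gamma_seg = data.frame(t_start = 0, gamma = 1),
      pp = list(eta = 0),  # weights frozen while calibrating
      w_hat_init = rep(w_hat, n_pf),
      record_stride_ms = duration_s * 1000, trial_times = numeric(0),
      seed = seed)
    length(res$mli_spikes) / duration_s
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- rate_at(lo); r_hi <- rate_at(hi)
  tries <- 0
  while (r_lo > target_rate && tries < 5) {
    lo <- lo - 0.5; r_lo <- rate_at(lo); tries <- tries + 1
  }
  while (r_hi < target_rate && tries < 10) {
    hi <- hi + 0.5; r_hi <- rate_at(hi); tries <- tries + 1
  }
  if (r_lo > target_rate || r_hi < target_rate) {
    stop(sprintf(
      "no current in [%.2f, %.2f] nA brackets target %.1f Hz (rates %.1f-%.1f Hz)",
      lo, hi, target_rate, r_lo, r_hi))
  }
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target_rate) <= tolerance) return(mid)
    if (r < target_rate) lo <- mid else hi <- mid
  }
  stop(sprintf("bisection did not reach %.1f +/- %.1f Hz in 40 iterations",
               target_rate, tolerance))
}

#' Firing rate of the isolated model MLI
#'
#' Simulates the MLI with no synaptic input (optionally with a constant
#' injected current) and returns its mean firing rate. This is the
#' spontaneous-rate calibration used throughout: with default parameters
#' the cell fires at about 30 Hz.
#'
#' @param duration_s simulated time (s).
#' @param seed RNG seed.
#' @param np a [neuron_params()] object.
#' @param i_inject constant injected current (nA).
#' @param dt step (ms).
#' @return Firing rate (Hz).
#' @examples
#' \donttest{
#' isolated_mli_rate(10, seed = 1)
#' }
#' @export
isolated_mli_rate <- function(duration_s, seed = 1, np = neuron_params(),
                              i_inject = 0, dt = 0.25) {
  clamp <- if (i_inject != 0) {
    data.frame(t_start = 0, mode = 2, level = i_inject)
  } else {
    data.frame(t_start = 0, mode = 0, level = 0)
  }
  res <- run_core(
    duration_ms = duration_s * 1000, dt = dt, np = np,
    sp = synapse_params(), n_pf = 0,
    rate_seg = data.frame(t_start = 0, t_end = duration_s * 1000, rate = 0,
                          burst_rate = 0, burst_len = 0, period = 0),
    clamp_seg = clamp,
    gamma_seg = data.frame(t_start = 0, gamma = 1),
    pp = plasticity_params(), w_hat_init = numeric(0),
    record_stride_ms = duration_s * 1000, trial_times = numeric(0),
    seed = seed)
  length(res$mli_spikes) / duration_s
}
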