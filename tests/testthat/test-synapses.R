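test_that("effective weight maps [0,1] onto [w0,1]", {
  expect_equal(effective_weight(0.2, 0), 0.2)
  expect_equal(effective_weight(0.2, 1), 1)
  expect_equal(effective_weight(0.2, 0.2), 0.36)
  expect_error(effective_weight(1.5, 0.5), "w0")
  expect_error(effective_weight(0.2, 2), "w_hat")
})

test_that("AMPA kinetics reproduce the double-exponential kernel", {
  p <- synapse_params()
  s <- list(a_fast = 0, a_slow = 0, w_hat = 1)
  # spike at t = 0 (instantaneous rise): amplitudes sum to one
  s <- ampa_step(s, p, spiked = TRUE, dt = 0.25)
  expect_equal(s$a_fast + s$a_slow, 1)
  expect_equal(s$g, p$g_ampa_max)  # w_hat = 1 -> w = 1
  # closed form at 18 ms after the spike
  for (k in 1:72) s <- ampa_step(s, p, spiked = FALSE, dt = 0.25)
  expect_equal(s$a_fast + s$a_slow,
               0.8 * exp(-18 / 0.8) + 0.2 * exp(-1), tolerance = 1e-12)
  expect_equal(s$a_fast + s$a_slow, 0.0736, tolerance = 1e-3)
  # no spikes ever -> zero contribution
  s0 <- list(a_fast = 0, a_slow = 0, w_hat = 0.5)
  for (k in 1:100) {
    s0 <- ampa_step(s0, p, spiked = FALSE, dt = 0.25)
    expect_identical(s0$g, 0)
  }
})

test_that("state-space AMPA equals direct convolution of the spike train", {
  p <- synapse_params()
  set.seed(5)
  dt <- 0.25
  spike_steps <- sort(sample(1:2000, 60))
  kernel <- function(t) {
    p$alpha_fast * exp(-t / p$tau_fast) + p$alpha_slow * exp(-t / p$tau_slow)
  }
  s <- list(a_fast = 0, a_slow = 0, w_hat = 0.3)
  w <- effective_weight(p$w0, 0.3)
  got <- numeric(2000)
  for (k in 1:2000) {
    s <- ampa_step(s, p, spiked = k %in% spike_steps, dt = dt)
    got[k] <- s$g
  }
  want <- p$g_ampa_max * w *
    convolve_spikes(1:2000 * dt, spike_steps * dt, kernel)
  # the two-state form is exact on the grid, not an Euler approximation
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("NMDA accumulator and channel kinetics behave as specified", {
  p <- synapse_params()
  # unit increment of the glutamate accumulator
  s <- nmda_step(list(n = 0, r = 0), p, n_spikes = 1, dt = 0.25)
  expect_equal(s$n, 1)
  # with no glutamate, R decays e-fold in tau_decay = 40 ms
  s <- list(n = 0, r = 0.8)
  for (k in 1:160) s <- nmda_step(s, p, 0, dt = 0.25)
  expect_equal(s$r, 0.8 * exp(-1), tolerance = 5e-3)  # Euler error only
  # saturation: the rise term vanishes at R = 1
  s1 <- nmda_step(list(n = 1e6, r = 1), p, 0, dt = 0.25)
  expect_lte(s1$r, 1)
  expect_equal(s1$r, 1 - 0.25 / p$tau_decay, tolerance = 1e-12)
})

test_that("NMDA conductance shows the voltage-dependent magnesium block", {
  p <- synapse_params()
  expect_equal(nmda_conductance(list(r = 1), p, 0),
               1 / (1 + 1.2 / 3.57), tolerance = 1e-6)
  expect_equal(nmda_conductance(list(r = 1), p, -68), 0.042,
               tolerance = 2e-2)
  expect_equal(nmda_conductance(list(r = 0), p, -30), 0)
  # block relief is monotone in V
  v <- seq(-100, 40, by = 1)
  g <- nmda_conductance(list(r = 1), p, v)
  expect_true(all(diff(g) > 0))
})

test_that("total synaptic conductance is non-negative throughout a run", {
  res <- core_run_constant(3000, n_pf = 4, pf_rate = 60, seed = 9,
                           record_stride_ms = 1)
  # conductances are internal; verify via the recorded trace bounds and
  # the membrane staying within reversal-potential bounds
  expect_true(all(res$rec_v <= 0.1))
  expect_true(all(res$rec_v >= -90))
})
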