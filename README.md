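# mliplast

Simulation of bidirectional plasticity at cerebellar parallel fiber (PF) →
molecular layer interneuron (MLI) synapses.

MLIs — the stellate and basket cells of the cerebellar molecular layer —
shape Purkinje-cell output through feedforward inhibition, and their PF
inputs express calcium-dependent LTP and LTD in vitro without any
climbing-fiber involvement. This package implements a phenomenological
model of that plasticity for computational neuroscientists who want to
test it against stimulation protocols: a conductance-based leaky
integrate-and-fire MLI with double-exponential AMPA and
magnesium-blocked, spillover-pooled NMDA conductances, spike-activity
traces, and the **gated steepest descent** learning rule

    d w_hat / dt = eta * PF_bar(t) * [ MLI_bar(t) - gamma * w_hat ]

where `PF_bar`, `MLI_bar` ∈ [0, 1] are the pre- and postsynaptic spike
trains convolved with a unit-area difference-of-exponentials kernel and
normalized by each population's maximum rate, `eta = 0.001 /ms`, and
`gamma * w_hat` is a dynamic threshold: presynaptic activity *gates*
learning, activity above the threshold potentiates, below it depresses,
and the rule is self-stabilizing (weights chase `MLI_bar / gamma` instead
of blowing up). The effective weight `w = w0 + (1 - w0) * w_hat` is
bounded in `[w0, 1]` with floor `w0 = 0.2` and scales the AMPA
conductance.

Ten registered protocols (`I`–`X`) reproduce in silico the classic
induction paradigms: PF bursts onto a spontaneously firing MLI,
continuous PF firing paired with hyper-/depolarizing current injection,
PF bundle stimulation under voltage clamp (weights decay to the floor) or
current clamp, and modulation of the synapse's "basal tone" via steps in
`gamma`. Everything integrates by forward Euler at 0.25 ms with a
compiled (Rcpp) inner loop; runs are bit-reproducible under a seed.

## Worked example

Protocol I: a single PF fires 100 Hz Poisson bursts for 100 ms at the
start of each of 60 one-second trials, onto an MLI firing spontaneously
at ~29 Hz; weights start at the baseline equilibrium.

```r
library(mliplast)

isolated_mli_rate(duration_s = 60, seed = 1)
#> [1] 29.13333

spec <- build_protocol("I")          # n = 10 repeats, base seed 1000
res  <- run_protocol_set(spec)
s    <- summarize_trials(res)
tail(s[, c("trial", "time_ms", "mean_w", "pct_w_mean", "pct_w_min", "pct_w_max")], 1)
#> # A tibble: 1 × 6
#>   trial time_ms mean_w pct_w_mean pct_w_min pct_w_max
#>   <int>   <dbl>  <dbl>      <dbl>     <dbl>     <dbl>
#> 1    60   65000  0.440       23.7      21.7      25.1
classify_outcome(res)
#> [1] "LTP"
```

The burst-driven rise in MLI firing exceeds the weight's threshold while
the PF gate is open, so the mean effective weight climbs from 0.36 to
0.44 — a ~+20–24% potentiation that plateaus as the weight catches up to
the MLI activity. `run_protocol()` returns the full sampled series
(membrane potential, rate traces, weights) and spike times;
`write_results()` serializes them as CSV plus a JSON manifest, and
`exec/mliplast` wraps the same functions as a command line
(`simulate`, `list-protocols`, `summarize`, `calibrate`).

See `vignettes/pf-mli-plasticity-model.Rmd` for the model's assumptions,
parameter tables, numerical choices, and the design decisions behind each
protocol.

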