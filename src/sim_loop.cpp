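#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Coupled Euler loop: PF Poisson draws -> AMPA/NMDA kinetics -> membrane
// update + spike detection -> PF/MLI activity traces -> gated steepest
// descent weight update. Time is in ms, potentials in mV, conductances in
// nS, currents in nA (converted to pA so pA/pF = mV/ms), capacitance in pF.
//
// RNG contract (must match the R reference stepper in the test suite):
// per step, first one uniform per PF fiber (spike draw), then one gamma
// (intrinsic current, drawn in every mode to keep streams aligned).
//
// Schedules are piecewise from t_start (last row whose t_start <= t wins).
// rate_seg additionally has t_end plus a periodic burst pattern.

static inline int seg_index(const NumericVector& starts, double t, int cur) {
  int i = cur;
  while (i + 1 < starts.size() && starts[i + 1] <= t + 1e-9) ++i;
  return i;
}

// [[Rcpp::export]]
List sim_loop_cpp(double duration_ms, double dt, List np, List sp,
                  int n_pf, NumericMatrix rate_seg, NumericMatrix clamp_seg,
                  NumericMatrix gamma_seg, double eta,
                  NumericVector w_hat_init, List trace_mli, List trace_pf,
                  int record_stride, IntegerVector trial_steps) {
  // neuron
  const double c_m = np["c_m"], v_th = np["v_threshold"],
    g_leak = np["g_leak"], e_leak = np["e_leak"], e_exc = np["e_exc"],
    g_ahp_max = np["g_ahp_max"], e_ahp = np["e_ahp"],
    tau_ahp = np["tau_ahp"], kappa = np["kappa"], beta = np["beta"];
  // synapse
  const double g_ampa_max = sp["g_ampa_max"], tau_fast = sp["tau_fast"],
    tau_slow = sp["tau_slow"], alpha_fast = sp["alpha_fast"],
    alpha_slow = sp["alpha_slow"], g_nmda_max = sp["g_nmda_max"],
    tau_rise = sp["tau_rise"], tau_decay = sp["tau_decay"],
    tau_n = sp["tau_n"], rho = sp["rho"], mg_out = sp["mg_out"],
    sigma = sp["sigma"], w0 = sp["w0"];
  // traces
  const double tau_m = trace_mli["tau_psi"], nu_m = trace_mli["nu_psi"],
    fmax_m = trace_mli["f_max"];
  const double tau_p = trace_pf["tau_psi"], nu_p = trace_pf["nu_psi"],
    fmax_p = trace_pf["f_max"];

  const int n_steps = (int)std::floor(duration_ms / dt + 0.5);
  const double d_fast = std::exp(-dt / tau_fast),
    d_slow = std::exp(-dt / tau_slow), d_n = std::exp(-dt / tau_n),
    d_tau_m = std::exp(-dt / tau_m), d_nu_m = std::exp(-dt / nu_m),
    d_tau_p = std::exp(-dt / tau_p), d_nu_p = std::exp(-dt / nu_p);

  // state
  double v = e_leak, t_spiked = -1e18;
  std::vector<double> af(n_pf, 0.0), as(n_pf, 0.0);
  std::vector<double> what(w_hat_init.begin(), w_hat_init.end());
  double nmda_n = 0.0, nmda_r = 0.0;
  double m_etau = 0.0, m_enu = 0.0;           // MLI trace accumulators
  std::vector<double> p_etau(n_pf, 0.0), p_enu(n_pf, 0.0);
  double mli_xbar = 0.0, mli_rate = 0.0;
  std::vector<double> pf_xbar(n_pf, 0.0);

  // outputs
  std::vector<double> mli_spikes;
  std::vector<double> pf_spike_t; std::vector<int> pf_spike_id;
  int n_rec = n_steps / record_stride + 1;
  NumericVector rec_t(n_rec), rec_v(n_rec), rec_rate(n_rec),
    rec_xbar(n_rec), rec_pf_xbar(n_rec), rec_what(n_rec), rec_w(n_rec);
  int i_rec = 0;
  int n_tr = trial_steps.size();
  NumericVector tr_t(n_tr), tr_what(n_tr), tr_w(n_tr);
  NumericMatrix tr_what_fiber(n_tr, n_pf);
  int i_tr = 0;

  auto mean_what = [&]() {
    if (n_pf == 0) return 0.0;
    double s = 0; for (double x : what) s += x; return s / n_pf;
  };
  auto mean_pf_xbar = [&]() {
    if (n_pf == 0) return 0.0;
    double s = 0; for (double x : pf_xbar) s += x; return s / n_pf;
  };

  // initial sample at t = 0
  rec_t[0] = 0; rec_v[0] = v; rec_rate[0] = 0; rec_xbar[0] = 0;
  rec_pf_xbar[0] = 0; rec_what[0] = mean_what();
  rec_w[0] = w0 + (1 - w0) * rec_what[0];
  i_rec = 1;

  RNGScope rng;
  int i_rate = 0, i_clamp = 0, i_gamma = 0;
  NumericVector rate_starts = rate_seg(_, 0);
  NumericVector clamp_starts = clamp_seg(_, 0);
  NumericVector gamma_starts = gamma_seg(_, 0);
  std::vector<char> sp_now(n_pf > 0 ? n_pf : 1);

  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    i_rate = seg_index(rate_starts, t, i_rate);
    i_clamp = seg_index(clamp_starts, t, i_clamp);
    i_gamma = seg_index(gamma_starts, t, i_gamma);

    // PF rate for this step
    double rate = 0.0;
    if (t < rate_seg(i_rate, 1) && t >= rate_seg(i_rate, 0)) {
      rate = rate_seg(i_rate, 2);
      const double period = rate_seg(i_rate, 5);
      if (period > 0) {
        const double since = t - rate_seg(i_rate, 0);
        const double local = since - period * std::floor(since / period);
        if (local < rate_seg(i_rate, 4)) rate = rate_seg(i_rate, 3);
      }
    }
    const double p_spike = rate * dt / 1000.0;

    // PF spike draws (one uniform per fiber, every step)
    int n_sp = 0;
    for (int i = 0; i < n_pf; ++i) {
      const bool s = unif_rand() < p_spike;
      sp_now[i] = s;
      if (s) { ++n_sp; pf_spike_t.push_back(t); pf_spike_id.push_back(i + 1); }
    }
    // intrinsic current (drawn in every mode to keep streams aligned)
    const double i_spont = R::rgamma(kappa, beta);

    // AMPA kinetics and total conductance
    double g_ampa = 0.0;
    for (int i = 0; i < n_pf; ++i) {
      af[i] *= d_fast; as[i] *= d_slow;
      if (sp_now[i]) { af[i] += alpha_fast; as[i] += alpha_slow; }
      g_ampa += g_ampa_max * (w0 + (1 - w0) * what[i]) * (af[i] + as[i]);
    }

    // pooled NMDA kinetics (conductance uses pre-update V)
    nmda_n = nmda_n * d_n + n_sp;
    double dr = std::log(nmda_n + 1.0) * (1.0 - nmda_r) / tau_rise -
      nmda_r / tau_decay;
    nmda_r += dt * dr;
    if (nmda_r < 0) nmda_r = 0; else if (nmda_r > 1) nmda_r = 1;
    const double g_nmda =
      g_nmda_max * nmda_r / (1.0 + rho * mg_out * std::exp(sigma * v));

    // membrane update
    const int mode = (int)clamp_seg(i_clamp, 1);
    bool spiked = false;
    if (mode == 1) {                       // voltage clamp
      v = clamp_seg(i_clamp, 2);
    } else {
      const double i_inject = (mode == 2) ? clamp_seg(i_clamp, 2) : 0.0;
      const double g_ahp = (t_spiked > -1e17)
        ? g_ahp_max * std::exp(-(t - t_spiked) / tau_ahp) : 0.0;
      const double dv = (dt / c_m) * (
        -g_leak * (v - e_leak) - g_ahp * (v - e_ahp) -
        (g_ampa + g_nmda) * (v - e_exc) + 1000.0 * (i_spont + i_inject));
      v += dv;
      if (!std::isfinite(v))
        stop("membrane potential became non-finite at t = %f ms", t);
      if (v >= v_th) {
        spiked = true;
        t_spiked = t + dt;
        mli_spikes.push_back(t + dt);
      }
    }

    // traces
    m_etau *= d_tau_m; m_enu *= d_nu_m;
    if (spiked) { m_etau += 1.0; m_enu += 1.0; }
    mli_rate = 1000.0 * (m_etau - m_enu) / (tau_m - nu_m);
    mli_xbar = std::min(mli_rate, fmax_m) / fmax_m;
    for (int i = 0; i < n_pf; ++i) {
      p_etau[i] *= d_tau_p; p_enu[i] *= d_nu_p;
      if (sp_now[i]) { p_etau[i] += 1.0; p_enu[i] += 1.0; }
      const double r_hz = 1000.0 * (p_etau[i] - p_enu[i]) / (tau_p - nu_p);
      pf_xbar[i] = std::min(r_hz, fmax_p) / fmax_p;
    }

    // weight update (every step; gamma from schedule)
    const double gamma = gamma_seg(i_gamma, 1);
    for (int i = 0; i < n_pf; ++i) {
      const double dw = eta * pf_xbar[i] * (mli_xbar - gamma * what[i]);
      double w = what[i] + dt * dw;
      if (w < 0) w = 0; else if (w > 1) w = 1;
      what[i] = w;
    }

    // recording
    if ((k + 1) % record_stride == 0 && i_rec < n_rec) {
      rec_t[i_rec] = t + dt; rec_v[i_rec] = v; rec_rate[i_rec] = mli_rate;
      rec_xbar[i_rec] = mli_xbar; rec_pf_xbar[i_rec] = mean_pf_xbar();
      rec_what[i_rec] = mean_what();
      rec_w[i_rec] = w0 + (1 - w0) * rec_what[i_rec];
      ++i_rec;
    }
    if (i_tr < n_tr && (k + 1) == trial_steps[i_tr]) {
      tr_t[i_tr] = t + dt;
      tr_what[i_tr] = mean_what();
      tr_w[i_tr] = w0 + (1 - w0) * tr_what[i_tr];
      for (int i = 0; i < n_pf; ++i) tr_what_fiber(i_tr, i) = what[i];
      ++i_tr;
    }
  }

  return List::create(
    _["mli_spikes"] = NumericVector(mli_spikes.begin(), mli_spikes.end()),
    _["pf_spike_time"] = NumericVector(pf_spike_t.begin(), pf_spike_t.end()),
    _["pf_spike_fiber"] = IntegerVector(pf_spike_id.begin(), pf_spike_id.end()),
    _["rec_time"] = rec_t, _["rec_v"] = rec_v, _["rec_mli_rate"] = rec_rate,
    _["rec_mli_xbar"] = rec_xbar, _["rec_pf_xbar"] = rec_pf_xbar,
    _["rec_mean_w_hat"] = rec_what, _["rec_mean_w"] = rec_w,
    _["trial_time"] = tr_t, _["trial_mean_w_hat"] = tr_what,
    _["trial_mean_w"] = tr_w, _["trial_w_hat_fiber"] = tr_what_fiber,
    _["final_w_hat"] = NumericVector(what.begin(), what.end()),
    _["final_v"] = v);
}
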