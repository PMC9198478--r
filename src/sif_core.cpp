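#include <Rcpp.h>
using namespace Rcpp;

// Units: time ms, voltage mV, resistance MOhm, conductance pS.
// R [MOhm] * g [pS] is dimensionless after scaling by 1e-6.
static const double RG_UNIT = 1e-6;

// Time-stepped integration of the grouped-conductance neuron.
//
// Per step k (sample time k*dt): every group decays by exp(-dt/tau_s)
// (exact solution of the decay ODE), arrivals binned into (t in
// [(k-1)*dt, k*dt)) are applied in the given order (set-to-max groups jump
// to their ceiling, additive groups increment), then the membrane is
// advanced by the exact solution of the affine ODE
//   tau dv/dt = -(v - v_rest) + R * sum_j g_j * (E_s_j - v)
// with g frozen over the step (exponential Euler). Threshold crossings at
// step boundaries record a spike and reset v; conductances persist.
//
// arr_step / arr_group are parallel, 1-based, sorted by (step, source).
// [[Rcpp::export(name = ".sif_run_core")]]
List sif_run_core(int n_steps, double dt,
                  double tau, double v_rest, double R,
                  double v_threshold, double v_reset,
                  NumericVector E_s, NumericVector tau_s,
                  NumericVector g_jump, LogicalVector additive,
                  IntegerVector arr_step, IntegerVector arr_group,
                  bool spiking) {
  const int n_groups = E_s.size();
  NumericVector v_trace(n_steps);
  NumericMatrix g_trace(n_steps, n_groups);
  std::vector<double> spikes;
  std::vector<double> g(n_groups, 0.0), decay(n_groups);
  for (int j = 0; j < n_groups; ++j) decay[j] = std::exp(-dt / tau_s[j]);

  double v = v_rest;
  int a = 0;
  const int n_arr = arr_step.size();

  for (int k = 1; k <= n_steps; ++k) {
    for (int j = 0; j < n_groups; ++j) g[j] *= decay[j];
    while (a < n_arr && arr_step[a] == k) {
      int j = arr_group[a] - 1;
      if (additive[j]) g[j] += g_jump[j]; else g[j] = g_jump[j];
      ++a;
    }
    double sum_g = 0.0, sum_gE = 0.0;
    for (int j = 0; j < n_groups; ++j) {
      sum_g += g[j];
      sum_gE += g[j] * E_s[j];
    }
    const double A = 1.0 + R * RG_UNIT * sum_g;
    const double v_inf = (v_rest + R * RG_UNIT * sum_gE) / A;
    v = v_inf + (v - v_inf) * std::exp(-A * dt / tau);
    if (spiking && v >= v_threshold) {
      spikes.push_back(k * dt);
      v = v_reset;
    }
    v_trace[k - 1] = v;
    for (int j = 0; j < n_groups; ++j) g_trace(k - 1, j) = g[j];
  }

  return List::create(_["voltage_mV"] = v_trace,
                      _["conductance_pS"] = g_trace,
                      _["spike_times_ms"] = NumericVector(spikes.begin(), spikes.end()));
}
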