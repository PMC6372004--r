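#include <Rcpp.h>
using namespace Rcpp;

// Clock-based LIF with instantaneous synapses, forward Euler.
// V(t + dt) = V(t) * (1 - dt/tau) + sum of weights of spikes in the bin.
// Threshold crossing (V >= theta) emits an output spike at the bin edge and
// resets V to 0; no refractory period. Events must be sorted by time and
// all lie in [0, duration).
// [[Rcpp::export]]
List lif_sim_cpp(NumericVector spike_time, IntegerVector spike_aff,
                 NumericVector weights, double tau, double theta,
                 double dt_bin, double duration, bool record_v,
                 double v0) {
  const R_xlen_t n_ev = spike_time.size();
  const R_xlen_t n_bins = (R_xlen_t) std::ceil(duration / dt_bin - 1e-9);
  const double decay = 1.0 - dt_bin / tau;

  NumericVector V;
  if (record_v) V = NumericVector(n_bins + 1);
  std::vector<double> out_spikes;
  double v = v0;
  if (record_v) V[0] = v;

  R_xlen_t e = 0;
  for (R_xlen_t b = 0; b < n_bins; ++b) {
    const double t_end = (b + 1) * dt_bin;
    v *= decay;
    while (e < n_ev && spike_time[e] < t_end) {
      v += weights[spike_aff[e]];
      ++e;
    }
    if (R_finite(theta) && v >= theta) {
      out_spikes.push_back(t_end);
      if (record_v) V[b + 1] = v;  // record the crossing value, then reset
      v = 0.0;
      continue;
    }
    if (record_v) V[b + 1] = v;
  }

  return List::create(_["V"] = V,
                      _["out_spikes"] = NumericVector(out_spikes.begin(),
                                                      out_spikes.end()),
                      _["n_bins"] = (double) n_bins);
}

// Additive all-to-all STDP with LTP only: each synapse carries a presynaptic
// trace Apre_i with exact exponential decay (time constant tau_pre),
// incremented by d_apre at each presynaptic spike. At each postsynaptic
// spike every weight receives Apre_i + w_out and is clipped to [0, 1].
// Membrane integration is forward Euler as in lif_sim_cpp. Traces are kept
// lazily: (value at last update, last update time) per synapse.
// If no postsynaptic spike has occurred by dead_time (> 0), the run aborts
// early and is flagged dead.
// [[Rcpp::export]]
List stdp_sim_cpp(NumericVector spike_time, IntegerVector spike_aff,
                  int n_aff, double tau, double theta, double dt_bin,
                  double duration, NumericVector w_init, double d_apre,
                  double tau_pre, double w_out, double dead_time) {
  const R_xlen_t n_ev = spike_time.size();
  const R_xlen_t n_bins = (R_xlen_t) std::ceil(duration / dt_bin - 1e-9);
  const double decay = 1.0 - dt_bin / tau;

  std::vector<double> w(w_init.begin(), w_init.end());
  std::vector<double> apre(n_aff, 0.0), last(n_aff, 0.0);
  std::vector<double> out_spikes;
  double v = 0.0;
  bool dead = false;

  R_xlen_t e = 0;
  for (R_xlen_t b = 0; b < n_bins; ++b) {
    const double t_end = (b + 1) * dt_bin;
    v *= decay;
    while (e < n_ev && spike_time[e] < t_end) {
      const int a = spike_aff[e];
      apre[a] = apre[a] * std::exp(-(spike_time[e] - last[a]) / tau_pre)
                + d_apre;
      last[a] = spike_time[e];
      v += w[a];
      ++e;
    }
    if (v >= theta) {
      out_spikes.push_back(t_end);
      for (int i = 0; i < n_aff; ++i) {
        double wi = w[i]
          + apre[i] * std::exp(-(t_end - last[i]) / tau_pre) + w_out;
        w[i] = wi < 0.0 ? 0.0 : (wi > 1.0 ? 1.0 : wi);
      }
      v = 0.0;
    }
    if (dead_time > 0.0 && out_spikes.empty() && t_end >= dead_time) {
      dead = true;
      break;
    }
  }

  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["post_spikes"] = NumericVector(out_spikes.begin(),
                                                       out_spikes.end()),
                      _["dead"] = dead);
}
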