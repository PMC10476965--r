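#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli spike generation of the spike response model.
//
// exponent_base: (v_stim(t) - v_th) / delta_v at every bin, with
//   v_stim = v_b + k * i precomputed in R (no spike-history terms).
// hv_over_dv:  h_v(u * dt) / delta_v for lags u = 1..length (post-spike
//   membrane kick, applied from the bin after the spike).
// hth_over_dv: h_th(u * dt) / delta_v for lags u = 1..length.
// dt: bin width in ms; lambda is in 1/ms so lambda * dt is dimensionless.
// clip: exponent cap guarding exp() overflow; clip events are counted.
//
// Returns spike bin indices (1-based), the exponent trace (from which the
// voltage can be reconstructed), and the clip count. Uses R's RNG so results
// are reproducible via set.seed().
// [[Rcpp::export]]
List srm_simulate_cpp(NumericVector exponent_base,
                      NumericVector hv_over_dv,
                      NumericVector hth_over_dv,
                      double dt,
                      double clip = 20.0) {
  const int n = exponent_base.size();
  const int nhv = hv_over_dv.size();
  const int nhth = hth_over_dv.size();
  std::vector<double> ex(exponent_base.begin(), exponent_base.end());
  std::vector<double> hv_acc(n, 0.0); // h_v / delta_v history, for voltage
  std::vector<int> spikes;
  int clipped = 0;
  for (int t = 0; t < n; ++t) {
    double e = ex[t];
    if (e > clip) { e = clip; ++clipped; }
    double lambda = std::exp(e);          // 1/ms
    double p = 1.0 - std::exp(-lambda * dt);
    if (unif_rand() < p) {
      spikes.push_back(t + 1);
      int lim = std::min(n - t - 1, std::max(nhv, nhth));
      for (int u = 1; u <= lim; ++u) {
        double add = 0.0;
        if (u <= nhv) { add += hv_over_dv[u - 1]; hv_acc[t + u] += hv_over_dv[u - 1]; }
        if (u <= nhth) add -= hth_over_dv[u - 1];
        ex[t + u] += add;
      }
    }
  }
  return List::create(_["spike_bins"] = wrap(spikes),
                      _["exponent"] = wrap(ex),
                      _["hv_acc"] = wrap(hv_acc),
                      _["n_clipped"] = clipped);
}

// Spike-history accumulator: sum of kernel(u) over past spikes at lag
// u = t - t_s >= 1 (in bins). kernel[u-1] is the value at lag u.
// spike_bins are 1-based. Returns a length-n vector.
// [[Rcpp::export]]
NumericVector spike_history_cpp(IntegerVector spike_bins,
                                NumericVector kernel,
                                int n) {
  NumericVector out(n);
  const int K = kernel.size();
  for (int s = 0; s < spike_bins.size(); ++s) {
    int t0 = spike_bins[s] - 1;
    int lim = std::min(n - t0 - 1, K);
    for (int u = 1; u <= lim; ++u) out[t0 + u] += kernel[u - 1];
  }
  return out;
}
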