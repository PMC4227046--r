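#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire motoneuron with a slowly inactivating potassium
// conductance (the current responsible for the delayed-firing phenotype).
//
//   C dV/dt = -G (V - V_rest) - gK h (V - E_K) + I(t)
//   dh/dt   = -h / tau_h                 (inactivation, during depolarization)
//
// Units: V mV, I nA, G and gK nS, C = G * tau_m (pF with tau_m in ms),
// time step dt in seconds. When V crosses v_th the sample index is recorded
// and V is reset to v_reset with an absolute refractory period.
// [[Rcpp::export]]
List lif_integrate(NumericVector current, double dt, double v_rest,
                   double g_ns, double tau_m_ms, double v_th, double v_reset,
                   double g_k, double e_k, double tau_h_s,
                   double refrac_s = 0.002) {
  int n = current.size();
  NumericVector v(n);
  std::vector<int> spikes;
  double cap = g_ns * tau_m_ms;      // pF
  double dt_ms = dt * 1000.0;
  double vv = v_rest, h = 1.0;
  int refrac_until = -1;
  for (int i = 0; i < n; ++i) {
    double inj = current[i];
    // inactivation runs while the membrane is driven above rest
    if (inj != 0.0 || vv > v_rest + 0.5) h += -h / tau_h_s * dt;
    if (h < 0) h = 0;
    if (i > refrac_until) {
      double ionic = -g_ns * (vv - v_rest) - g_k * h * (vv - e_k);
      vv += dt_ms * (ionic + 1000.0 * inj) / cap;
      if (vv >= v_th) {
        spikes.push_back(i);
        vv = v_reset;
        refrac_until = i + (int)(refrac_s / dt);
      }
    }
    v[i] = vv;
  }
  return List::create(_["voltage"] = v,
                      _["spike_idx"] = wrap(spikes));
}
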