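#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Leaky integrate-and-fire neuron driven by independent Poisson inputs
// through depressing synapses (utilization/recovery short-term plasticity):
//   on a presynaptic spike at synapse i:  I += w * U * R_i / tau_syn;
//                                         R_i -= U * R_i
//   between spikes:  dR_i/dt = (1 - R_i) / tau_rec
//   dI/dt = -I / tau_syn ;  tau_m dV/dt = -V + I ; spike when V >= v_th.
// Each input channel is delivered through `n_contacts` independent contacts
// (independent Poisson trains at the channel rate, each with its own
// depression resource), emulating the multiple synaptic contacts a
// third-order neuron receives from one glomerular channel. Poisson inputs
// are simulated per time step with R's RNG so the caller's seed applies.
// Returns the output rate over the second half of the run.
// [[Rcpp::export]]
double lif_stp_sim(NumericVector rates, double tau_m, double v_th,
                   double v_reset, double t_ref, double U, double tau_rec,
                   double tau_syn, double w, double duration, double dt,
                   int n_contacts) {
  const int n = rates.size() * n_contacts;
  std::vector<double> R(n, 1.0), pspike(n);
  for (int i = 0; i < n; ++i) pspike[i] = rates[i / n_contacts] * dt;
  const int steps = (int)std::ceil(duration / dt);
  const double decay_syn = std::exp(-dt / tau_syn);
  const double rec = std::exp(-dt / tau_rec);
  double V = 0.0, I = 0.0, refr = 0.0;
  int count = 0;
  const double t_half = duration / 2.0;
  RNGScope scope;
  for (int k = 0; k < steps; ++k) {
    double t = k * dt;
    for (int i = 0; i < n; ++i) {
      R[i] = 1.0 - (1.0 - R[i]) * rec;
      if (pspike[i] > 0.0 && unif_rand() < pspike[i]) {
        I += w * U * R[i] / tau_syn;
        R[i] -= U * R[i];
      }
    }
    I *= decay_syn;
    if (refr > 0.0) {
      refr -= dt;
      V = v_reset;
    } else {
      V += dt * (-V + I) / tau_m;
      if (V >= v_th) {
        if (t >= t_half) ++count;
        V = v_reset;
        refr = t_ref;
      }
    }
  }
  return count / (duration - t_half);
}
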