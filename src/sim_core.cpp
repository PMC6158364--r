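#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Time-stepped integration of a network of Izhikevich neurons with
// delta synapses (instantaneous charge delivery after a fixed delay),
// per-neuron Gaussian background drive, and a shared injected stimulus
// current applied to a masked subset of neurons.
//
// Conventions:
//  - forward Euler, one full step for v and u per dt; u update uses the
//    pre-step v
//  - spike detected when the updated v reaches v_peak; reset v <- c,
//    u <- u_updated + d in the same step
//  - a spike at step t (0-based) is reported at time (t + 1) * dt
//  - synaptic weights are delivered charge: each presynaptic
//    spike adds w to the target's membrane potential at t + delay
//    (delta kinetics, syn_kin = 0) or feeds an exponential-decay current
//    channel (time constant tau_inh, syn_kin = 1) whose integrated
//    charge equals w, so slow inhibition outlasts a volley
//  - v is floored at v_floor: the quadratic voltage equation is not a
//    valid model far below rest and would otherwise rebound unphysically
//    under strong hyperpolarization
//  - uses R's RNG (norm_rand), so results are reproducible under set.seed
//
// [[Rcpp::export]]
List sim_core(NumericVector pa, NumericVector pb, NumericVector pc,
              NumericVector pd, NumericVector pvpeak,
              NumericVector v0, NumericVector u0,
              IntegerVector syn_ptr, IntegerVector syn_tgt,
              NumericVector syn_w, IntegerVector syn_kin,
              int n_steps, double dt,
              NumericVector bias, NumericVector noise_sd,
              int drive_end_step,
              NumericVector stim_current, LogicalVector stim_mask,
              int delay_steps,
              int volley_step, LogicalVector volley_mask,
              double v_floor, double tau_inh)
{
  const int N = v0.size();
  if (delay_steps < 1) stop("delay must be at least one time step");
  if (tau_inh <= 0) stop("tau_inh must be positive");
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> u(u0.begin(), u0.end());
  const int B = delay_steps + 1;
  std::vector<double> buf((size_t)B * N, 0.0);  // pending exc charge (mV)
  std::vector<double> ibuf((size_t)B * N, 0.0); // pending inh charge (mV)
  std::vector<double> I_inh(N, 0.0);            // inhibitory current state
  const double decay = std::exp(-dt / tau_inh);

  std::vector<int> sp_step, sp_neuron;
  sp_step.reserve(1 << 16);
  sp_neuron.reserve(1 << 16);

  RNGScope scope;

  for (int t = 0; t < n_steps; ++t) {
    const int row = t % B;
    const int drow = (t + delay_steps) % B;
    const double stim_t = stim_current[t];
    const bool drive_on = t < drive_end_step;
    double *pending = &buf[(size_t)row * N];
    double *deliver = &buf[(size_t)drow * N];
    double *ipending = &ibuf[(size_t)row * N];
    double *ideliver = &ibuf[(size_t)drow * N];

    for (int i = 0; i < N; ++i) {
      I_inh[i] = I_inh[i] * decay + ipending[i] / tau_inh;
      ipending[i] = 0.0;
      double I = pending[i] / dt + I_inh[i];
      pending[i] = 0.0;
      if (drive_on) {
        I += bias[i];
        if (noise_sd[i] > 0.0) I += norm_rand() * noise_sd[i];
      }
      if (stim_t != 0.0 && stim_mask[i]) I += stim_t;
      if (t == volley_step && volley_mask[i]) I += 1e4;

      const double vi = v[i], ui = u[i];
      double vn = vi + dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      double un = ui + dt * pa[i] * (pb[i] * vi - ui);
      if (!std::isfinite(vn) || !std::isfinite(un))
        stop("numeric blow-up at step %d (t = %.3f ms), neuron %d",
             t, t * dt, i + 1);

      if (vn >= pvpeak[i]) {
        sp_step.push_back(t);
        sp_neuron.push_back(i + 1);
        vn = pc[i];
        un += pd[i];
        for (int k = syn_ptr[i]; k < syn_ptr[i + 1]; ++k) {
          if (syn_kin[k] == 0) deliver[syn_tgt[k]] += syn_w[k];
          else ideliver[syn_tgt[k]] += syn_w[k];
        }
      }
      if (vn < v_floor) vn = v_floor;
      v[i] = vn;
      u[i] = un;
    }
  }

  return List::create(_["step"] = wrap(sp_step),
                      _["neuron"] = wrap(sp_neuron),
                      _["v"] = wrap(v),
                      _["u"] = wrap(u));
}

// FNV-1a 64-bit hash of a raw vector, reported as a hex string; used to
// fingerprint serialized configurations.
// [[Rcpp::export]]
std::string fnv1a64(RawVector bytes)
{
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= 1099511628211ULL;
  }
  char out[17];
  snprintf(out, sizeof(out), "%016llx", (unsigned long long)h);
  return std::string(out);
}
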