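// Forward-Euler integration of the conductance-based leaky
// integrate-and-fire network:
//   dv/dt  = -(v - V_L)/tau_m - g_E (v - V_E) - g_I (v - V_I) + I_ex
//   dg_X/dt = -g_X/tau_s + sum_j G_{X,j} sum_s delta(t - s_j - d_j)
// with threshold/reset, a 1 ms absolute refractory period (v clamped at V_r,
// conductances keep evolving), per-synapse conduction delays and independent
// Bernoulli transmission failure on EE deliveries.
//
// Per-step update order: (1) conductance decay, (2) arriving synaptic
// increments, (3) stimulus jumps (lost while refractory), (4) Euler voltage
// update, (5) threshold/reset + delivery scheduling. Delta inputs are exact
// increments under Euler (g += G, v += amplitude). Deliveries are scheduled
// at least one grid step ahead so the within-step order stays well defined.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

struct Delivery {
  int target;
  double w;
  bool exc;  // presynaptic class decides which conductance is incremented
};

// [[Rcpp::export]]
List simulate_trial_cpp(IntegerVector pre, IntegerVector post,
                        NumericVector weight, IntegerVector delay_steps,
                        NumericVector pfail, int n_e, int n_i,
                        IntegerVector stim_step, IntegerVector stim_neuron,
                        double stim_amp, double tau_m_e, double tau_m_i,
                        double v_leak, double v_exc, double v_inh,
                        double v_reset, double v_thr, double tau_s,
                        double refractory_ms, double dt, double duration_ms,
                        NumericVector v0, int failure_seed,
                        IntegerVector record_ids) {
  const int n = n_e + n_i;
  const long n_steps = (long)std::llround(duration_ms / dt);
  const int n_syn = pre.size();
  if (v0.size() != n) stop("simulate_trial_cpp: v0 length must equal n_e + n_i");

  // CSR adjacency keyed by presynaptic neuron (counting sort)
  std::vector<int> offs(n + 1, 0);
  for (int k = 0; k < n_syn; ++k) {
    int i = pre[k];
    if (i < 0 || i >= n) stop("simulate_trial_cpp: pre_id out of range");
    offs[i + 1]++;
  }
  for (int i = 0; i < n; ++i) offs[i + 1] += offs[i];
  std::vector<int> s_post(n_syn), s_delay(n_syn);
  std::vector<double> s_w(n_syn), s_pf(n_syn);
  {
    std::vector<int> cur(offs.begin(), offs.end() - 1);
    for (int k = 0; k < n_syn; ++k) {
      if (post[k] < 0 || post[k] >= n)
        stop("simulate_trial_cpp: post_id out of range");
      int c = cur[pre[k]]++;
      s_post[c] = post[k];
      s_delay[c] = delay_steps[k] < 1 ? 1 : delay_steps[k];
      s_w[c] = weight[k];
      s_pf[c] = pfail[k];
    }
  }

  int max_delay = 1;
  for (int k = 0; k < n_syn; ++k)
    if (s_delay[k] > max_delay) max_delay = s_delay[k];
  const int n_slots = max_delay + 1;
  std::vector<std::vector<Delivery>> ring(n_slots);

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> gE(n, 0.0), gI(n, 0.0);
  std::vector<long> refr_until(n, -1);
  const double decay = 1.0 - dt / tau_s;
  const long refr_steps = (long)std::llround(refractory_ms / dt);

  std::mt19937_64 rng((uint64_t)(uint32_t)failure_seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> sp_t;
  std::vector<int> sp_i;
  int stim_ptr = 0;
  const int n_stim = stim_step.size();
  const int n_rec = record_ids.size();
  NumericMatrix vtrace(n_rec > 0 ? (int)n_steps : 0, n_rec);

  for (long t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      gE[i] *= decay;
      gI[i] *= decay;
    }
    std::vector<Delivery>& slot = ring[t % n_slots];
    for (size_t k = 0; k < slot.size(); ++k) {
      const Delivery& d = slot[k];
      if (d.exc) gE[d.target] += d.w; else gI[d.target] += d.w;
    }
    slot.clear();
    while (stim_ptr < n_stim && stim_step[stim_ptr] == t) {
      int i = stim_neuron[stim_ptr++];
      if (i < 0 || i >= n) stop("simulate_trial_cpp: stimulus neuron id out of range");
      if (t >= refr_until[i]) v[i] += stim_amp;
    }
    for (int i = 0; i < n; ++i) {
      if (t < refr_until[i]) {
        v[i] = v_reset;
        continue;
      }
      const double tau_m = (i < n_e) ? tau_m_e : tau_m_i;
      double vi = v[i];
      vi += dt * (-(vi - v_leak) / tau_m - gE[i] * (vi - v_exc) -
                  gI[i] * (vi - v_inh));
      if (!std::isfinite(vi))
        stop("membrane potential diverged at t = %.2f ms (neuron %d)",
             t * dt, i);
      if (vi >= v_thr) {
        sp_t.push_back(t * dt);
        sp_i.push_back(i);
        vi = v_reset;
        refr_until[i] = t + refr_steps;
        const bool exc = i < n_e;
        for (int k = offs[i]; k < offs[i + 1]; ++k) {
          if (s_pf[k] > 0.0 && unif(rng) < s_pf[k]) continue;
          Delivery d;
          d.target = s_post[k];
          d.w = s_w[k];
          d.exc = exc;
          ring[(t + s_delay[k]) % n_slots].push_back(d);
        }
      }
      v[i] = vi;
    }
    for (int r = 0; r < n_rec; ++r) vtrace(t, r) = v[record_ids[r]];
  }

  return List::create(_["time_ms"] = NumericVector(sp_t.begin(), sp_t.end()),
                      _["neuron_id"] = IntegerVector(sp_i.begin(), sp_i.end()),
                      _["v_trace"] = vtrace);
}
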