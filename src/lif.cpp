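#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Leaky integrate-and-fire network stepper.
//
// Euler integration of dV/dt = (-(V - v_rest) + I_const) / tau_m per
// neuron.  Each spike of neuron i at step t delivers an instantaneous
// voltage kick w(i->j) to every neighbour j at step t+1 (w already
// includes the distance damping zeta(d) * J).  The stimulated node is a
// spike generator: it fires at the prescribed stimulus times (subject to
// its refractory period).  Optional Gaussian voltage noise uses R's RNG
// so seeding from R controls reproducibility.
//
// [[Rcpp::export]]
List lif_core(int n, IntegerVector edge_i, IntegerVector edge_j,
              NumericVector edge_w, int stim_node, NumericVector stim_times,
              double tau_m, double v_rest, double v_reset, double v_th,
              double t_ref, double dt, double T, double i_const,
              double noise_sd) {
  std::vector<std::vector<std::pair<int, double>>> adj(n);
  for (int k = 0; k < edge_i.size(); ++k) {
    int a = edge_i[k], b = edge_j[k];
    double w = edge_w[k];
    adj[a].push_back(std::make_pair(b, w));
    adj[b].push_back(std::make_pair(a, w));
  }
  int n_steps = (int)std::floor(T / dt);
  std::vector<double> V(n, v_rest), kick(n, 0.0), kick_next(n, 0.0);
  std::vector<double> ref_until(n, -1.0);
  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  int si = 0;  // next stimulus spike index (stim_times must be sorted)
  bool use_noise = noise_sd > 0;
  double noise_scale = noise_sd * std::sqrt(dt);
  for (int s = 0; s < n_steps; ++s) {
    double t = (s + 1) * dt;
    std::swap(kick, kick_next);
    std::fill(kick_next.begin(), kick_next.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      if (t < ref_until[i]) { V[i] = v_reset; continue; }
      V[i] += dt * (-(V[i] - v_rest) + i_const) / tau_m + kick[i];
      if (use_noise) V[i] += noise_scale * R::norm_rand();
    }
    // stimulus-driven firing of the source node
    bool stim_fire = false;
    while (si < stim_times.size() && stim_times[si] <= t) {
      stim_fire = true;
      ++si;
    }
    for (int i = 0; i < n; ++i) {
      bool fire = (V[i] >= v_th) && (t >= ref_until[i]);
      if (i == stim_node && stim_fire && t >= ref_until[i]) fire = true;
      if (fire) {
        sp_neuron.push_back(i + 1);
        sp_time.push_back(t);
        V[i] = v_reset;
        ref_until[i] = t + t_ref;
        for (size_t k = 0; k < adj[i].size(); ++k)
          kick_next[adj[i][k].first] += adj[i][k].second;
      }
    }
  }
  return List::create(_["neuron"] = wrap(sp_neuron), _["t"] = wrap(sp_time));
}
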