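// Conductance-based LIF network with a homeostatic bias current.
//
//   tau_mem dV/dt = -(V - V_rest) + R * I(t)
//   I(t) = g_e(t) (E_e - V) + I_ext(t) + noise - h * r3(t)
//
// Excitatory synapses are exponentially decaying conductances incremented
// by g_step on each presynaptic spike.  The population rate is filtered
// (tau2) into r2 and the rate error integrated (tau3, perfect integrator)
// into r3, which sets a bias current -h*r3 shared by all neurons.
// Units: time ms, voltage mV, current pA, conductance nS, R in MOhm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List spiking_sim_cpp(int N, double p_conn,
                     double tau_mem, double V_rest, double R_mohm,
                     double V_thr, double V_reset, double t_ref,
                     double tau_syn, double E_e, double g_step,
                     double h, double r_goal, double noise_sigma,
                     const arma::vec& u_times, const arma::vec& u_vals,
                     double tau2, double tau3, bool homeostasis,
                     double r3_init, double dt, double duration,
                     int record_stride, bool record_spikes,
                     double rate_cap) {
  const int nsteps = (int)std::round(duration / dt);
  const double rm = R_mohm * 1e-3;             // mV per pA
  const double syn_decay = std::exp(-dt / tau_syn);
  const int ref_steps = (int)std::round(t_ref / dt);
  // white current noise: per-step sample std equals noise_sigma at the
  // 0.5 ms reference step and scales as 1/sqrt(dt), so the resulting
  // voltage diffusion is independent of the integration step
  const double sig_step = noise_sigma * std::sqrt(0.5 / dt);

  arma::vec V(N), ge(N, arma::fill::zeros);
  std::vector<int> refr(N, 0);
  for (int i = 0; i < N; ++i) V[i] = V_rest + (V_thr - V_rest) * unif_rand();

  // adjacency list (presynaptic -> targets)
  std::vector<std::vector<int>> targets(N);
  if (g_step != 0.0 && p_conn > 0.0) {
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j) {
        if (i != j && unif_rand() < p_conn) targets[i].push_back(j);
      }
    }
  }

  double r2 = 0.0, r3 = r3_init;
  const int nrec = nsteps / record_stride + 1;
  arma::vec rec_t(nrec), rec_r2(nrec), rec_r3(nrec), rec_inst(nrec);
  int rec = 0;
  rec_t[0] = 0.0; rec_r2[0] = r2; rec_r3[0] = r3; rec_inst[0] = 0.0; rec = 1;

  std::vector<double> sp_t;
  std::vector<int> sp_id;
  bool capped = false;

  double u_cur = 0.0;
  arma::uword u_idx = 0;

  for (int s = 0; s < nsteps; ++s) {
    double t = s * dt;
    while (u_idx < u_times.n_elem && u_times[u_idx] <= t) {
      u_cur = u_vals[u_idx];
      ++u_idx;
    }
    double bias = homeostasis ? -h * r3 : 0.0;
    int nsp = 0;
    for (int i = 0; i < N; ++i) {
      ge[i] *= syn_decay;
      if (refr[i] > 0) { --refr[i]; V[i] = V_reset; continue; }
      double I = ge[i] * (E_e - V[i]) + u_cur + bias;
      if (noise_sigma > 0.0) I += sig_step * norm_rand();
      V[i] += dt / tau_mem * (-(V[i] - V_rest) + rm * I);
      if (V[i] >= V_thr) {
        V[i] = V_reset;
        refr[i] = ref_steps;
        ++nsp;
        if (record_spikes) { sp_t.push_back(t); sp_id.push_back(i + 1); }
        const std::vector<int>& tg = targets[i];
        for (size_t k = 0; k < tg.size(); ++k) ge[tg[k]] += g_step;
      }
    }
    double inst = nsp / (N * dt * 1e-3);       // Hz
    r2 += dt / tau2 * (-r2 + inst);
    if (homeostasis) r3 += dt / tau3 * (r2 - r_goal);
    if (r2 > rate_cap) { capped = true; break; }

    if ((s + 1) % record_stride == 0 && rec < nrec) {
      rec_t[rec] = (s + 1) * dt; rec_r2[rec] = r2; rec_r3[rec] = r3;
      rec_inst[rec] = inst; ++rec;
    }
  }

  if (rec < nrec) {
    rec_t = rec_t.subvec(0, rec - 1); rec_r2 = rec_r2.subvec(0, rec - 1);
    rec_r3 = rec_r3.subvec(0, rec - 1); rec_inst = rec_inst.subvec(0, rec - 1);
  }

  return List::create(_["time"] = rec_t, _["r2"] = rec_r2, _["r3"] = rec_r3,
                      _["inst_rate"] = rec_inst,
                      _["spike_time"] = sp_t, _["spike_id"] = sp_id,
                      _["truncated"] = capped);
}
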