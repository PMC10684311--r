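// Fixed-step integrator for the cholinergically modulated E-I network.
//
// All stochastic inputs (wiring, initial conditions, Poisson noise event
// times) are drawn on the R side; this translation unit is deterministic,
// so identical inputs give bit-identical outputs.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Gating kinetics of the cortical neuron model: fast Na+ (instantaneous
// activation m, inactivation h), delayed-rectifier K+ (n), and the slow,
// low-threshold M-type K+ current (z) whose maximal conductance gKs
// encodes ACh level (gKs = 0 <-> high ACh).
static inline double m_inf(double V) { return 1.0 / (1.0 + std::exp(-(V + 30.0) / 9.5)); }
static inline double h_inf(double V) { return 1.0 / (1.0 + std::exp((V + 53.0) / 7.0)); }
static inline double n_inf(double V) { return 1.0 / (1.0 + std::exp(-(V + 30.0) / 10.0)); }
static inline double z_inf(double V) { return 1.0 / (1.0 + std::exp(-(V + 39.0) / 5.0)); }
static inline double tau_h(double V) { return 0.37 + 2.78 / (1.0 + std::exp((V + 40.5) / 6.0)); }
static inline double tau_n(double V) { return 0.37 + 1.85 / (1.0 + std::exp((V + 27.0) / 15.0)); }
static const double TAU_Z = 75.0;

static inline double clipw(double w, double lo, double hi) {
  return w < lo ? lo : (w > hi ? hi : w);
}

// full-system derivatives (V, h, n, z) for a cell; g_e/g_i and the applied
// currents are held fixed across a step's RK4 stages
struct CellDeriv { double dV, dh, dn, dz; };
static inline CellDeriv cell_rhs(double V, double h, double n, double z,
                                 double gks, double C, double gNa,
                                 double gKdr, double gL, double VNa,
                                 double VK, double VL, double ge, double gi,
                                 double E_exc, double E_inh, double I_app) {
  const double mi = m_inf(V);
  const double n2 = n * n;
  CellDeriv d;
  d.dV = (-gNa * mi * mi * mi * h * (V - VNa)
          - (gKdr * n2 * n2 + gks * z) * (V - VK)
          - gL * (V - VL)
          - ge * (V - E_exc) - gi * (V - E_inh) + I_app) / C;
  d.dh = (h_inf(V) - h) / tau_h(V);
  d.dn = (n_inf(V) - n) / tau_n(V);
  d.dz = (z_inf(V) - z) / TAU_Z;
  return d;
}

// one classical RK4 step of the cell state in place
static inline void rk4_step(double &V, double &h, double &n, double &z,
                            double dt, double gks, double C, double gNa,
                            double gKdr, double gL, double VNa, double VK,
                            double VL, double ge, double gi, double E_exc,
                            double E_inh, double I_app) {
  const CellDeriv k1 = cell_rhs(V, h, n, z, gks, C, gNa, gKdr, gL, VNa, VK,
                                VL, ge, gi, E_exc, E_inh, I_app);
  const CellDeriv k2 = cell_rhs(V + 0.5 * dt * k1.dV, h + 0.5 * dt * k1.dh,
                                n + 0.5 * dt * k1.dn, z + 0.5 * dt * k1.dz,
                                gks, C, gNa, gKdr, gL, VNa, VK, VL, ge, gi,
                                E_exc, E_inh, I_app);
  const CellDeriv k3 = cell_rhs(V + 0.5 * dt * k2.dV, h + 0.5 * dt * k2.dh,
                                n + 0.5 * dt * k2.dn, z + 0.5 * dt * k2.dz,
                                gks, C, gNa, gKdr, gL, VNa, VK, VL, ge, gi,
                                E_exc, E_inh, I_app);
  const CellDeriv k4 = cell_rhs(V + dt * k3.dV, h + dt * k3.dh,
                                n + dt * k3.dn, z + dt * k3.dz,
                                gks, C, gNa, gKdr, gL, VNa, VK, VL, ge, gi,
                                E_exc, E_inh, I_app);
  V += dt / 6.0 * (k1.dV + 2 * k2.dV + 2 * k3.dV + k4.dV);
  h += dt / 6.0 * (k1.dh + 2 * k2.dh + 2 * k3.dh + k4.dh);
  n += dt / 6.0 * (k1.dn + 2 * k2.dn + 2 * k3.dn + k4.dn);
  z += dt / 6.0 * (k1.dz + 2 * k2.dz + 2 * k3.dz + k4.dz);
  if (h < 0) h = 0; else if (h > 1) h = 1;
  if (n < 0) n = 0; else if (n > 1) n = 1;
  if (z < 0) z = 0; else if (z > 1) z = 1;
}

// Single-neuron integration: classical RK4 on the full (V, h, n, z)
// system. Spikes are upward crossings of v_thresh with a lockout.
// Optionally records V(t) and z(t) on the integration grid.
// [[Rcpp::export]]
List run_neuron_cpp(double gks, double I_drive,
                    double C, double gNa, double gKdr, double gL,
                    double VNa, double VK, double VL,
                    double v0, double duration, double dt,
                    double v_thresh, double lockout,
                    bool record_traces) {
  const int n_steps = (int)std::lround(duration / dt);
  double V = v0, h = h_inf(v0), n = n_inf(v0), z = z_inf(v0);
  double last_spike = -1e9;
  std::vector<double> spikes;
  std::vector<double> v_tr, z_tr;
  if (record_traces) {
    v_tr.reserve(n_steps + 1);
    z_tr.reserve(n_steps + 1);
    v_tr.push_back(V);
    z_tr.push_back(z);
  }
  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    const double Vold = V;
    rk4_step(V, h, n, z, dt, gks, C, gNa, gKdr, gL, VNa, VK, VL,
             0.0, 0.0, 0.0, -75.0, I_drive);
    if (!std::isfinite(V) || std::fabs(V) > 200.0)
      stop("single-neuron integration diverged at t = %f ms", t);
    if (V >= v_thresh && Vold < v_thresh && (t + dt) - last_spike > lockout) {
      last_spike = t + dt;
      spikes.push_back(t + dt);
    }
    if (record_traces) {
      v_tr.push_back(V);
      z_tr.push_back(z);
    }
  }
  List out = List::create(_["spikes"] = NumericVector(spikes.begin(), spikes.end()));
  if (record_traces) {
    out["V"] = NumericVector(v_tr.begin(), v_tr.end());
    out["z"] = NumericVector(z_tr.begin(), z_tr.end());
  }
  return out;
}

// Full two-module network.
//
// Static (intra-module) synapses arrive in CSR-by-source form
// (s_ptr, s_tgt, s_w); plastic inter-module E->E synapses arrive as
// parallel arrays (p_src, p_tgt, p_w0) with CSR index lists both by
// source (psrc_*) and by target (ptgt_*) so pre- and post-triggered STDP
// updates touch the same weight storage. All indices 0-based.
//
// Poisson noise pulses are pre-drawn event times per cell (flattened via
// noise_ptr); an event sets the input current to `noise_amp` for
// `noise_width` ms; overlapping events saturate at one amplitude unless
// noise_stack extends the window (kept for the configurable variant --
// saturation simply takes the max "on until" time either way).
//
// Per-step event order: integrate membranes -> detect spikes -> decay
// conductances and plasticity traces to t+dt -> deliver spikes (conductance
// jumps using the weights in force at spike time) -> STDP updates
// (pre-triggered depression, then trace increments, then post-triggered
// potentiation; simultaneous pre/post pairs therefore take the
// delta_t = 0 potentiation branch).
// [[Rcpp::export]]
List run_network_cpp(NumericVector gks, NumericVector dc, LogicalVector is_exc,
                     double C, double gNa, double gKdr, double gL,
                     double VNa, double VK, double VL,
                     IntegerVector s_ptr, IntegerVector s_tgt, NumericVector s_w,
                     IntegerVector p_src, IntegerVector p_tgt, NumericVector p_w0,
                     IntegerVector psrc_ptr, IntegerVector psrc_idx,
                     IntegerVector ptgt_ptr, IntegerVector ptgt_idx,
                     bool stdp_on, double A_plus, double A_minus,
                     double tau_plus, double tau_minus,
                     double w_min, double w_max,
                     double tau_syn, double E_exc, double E_inh,
                     IntegerVector noise_ptr, NumericVector noise_times,
                     double noise_amp, double noise_width,
                     NumericVector v0, double dt, double duration,
                     double v_thresh, double lockout,
                     NumericVector snap_times) {
  const int nc = gks.size();
  const int n_steps = (int)std::lround(duration / dt);
  const int n_plastic = p_src.size();
  const int n_snaps = snap_times.size();
  NumericMatrix snaps(n_plastic, n_snaps);
  int snap_idx = 0;

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> h(nc), nn(nc), z(nc), ge(nc, 0.0), gi(nc, 0.0);
  for (int i = 0; i < nc; ++i) {
    h[i] = h_inf(V[i]);
    nn[i] = n_inf(V[i]);
    z[i] = z_inf(V[i]);
  }
  std::vector<double> w(p_w0.begin(), p_w0.end());
  std::vector<double> xp(nc, 0.0), xm(nc, 0.0);  // STDP eligibility traces
  std::vector<double> last_spike(nc, -1e9), noise_until(nc, -1e9);
  std::vector<int> noise_next(nc);
  for (int i = 0; i < nc; ++i) noise_next[i] = noise_ptr[i];

  const double dec_syn = std::exp(-dt / tau_syn);
  const double dec_z = std::exp(-dt / TAU_Z);
  const double dec_xp = std::exp(-dt / tau_plus);
  const double dec_xm = std::exp(-dt / tau_minus);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 16);
  spike_t.reserve(1 << 16);
  std::vector<int> spikers;
  spikers.reserve(nc);

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    spikers.clear();
    for (int i = 0; i < nc; ++i) {
      // noise pulse window bookkeeping
      int &k = noise_next[i];
      const int kend = noise_ptr[i + 1];
      while (k < kend && noise_times[k] <= t) {
        const double until = noise_times[k] + noise_width;
        if (until > noise_until[i]) noise_until[i] = until;
        ++k;
      }
      const double Ino = (t < noise_until[i]) ? noise_amp : 0.0;

      const double Vi = V[i];
      // RK4 on the full cell state; synaptic conductances and noise are
      // held fixed over the step (they decay/jump between steps)
      rk4_step(V[i], h[i], nn[i], z[i], dt, gks[i], C, gNa, gKdr, gL,
               VNa, VK, VL, ge[i], gi[i], E_exc, E_inh, dc[i] + Ino);
      const double Vnew = V[i];
      if (!std::isfinite(Vnew) || std::fabs(Vnew) > 200.0)
        stop("network integration diverged at t = %f ms (cell %d)", t, i + 1);
      if (Vnew >= v_thresh && Vi < v_thresh && (t + dt) - last_spike[i] > lockout) {
        last_spike[i] = t + dt;
        spikers.push_back(i);
        spike_id.push_back(i);
        spike_t.push_back(t + dt);
      }
    }

    // exponential decay of synaptic conductances and STDP traces to t+dt
    for (int i = 0; i < nc; ++i) {
      ge[i] *= dec_syn;
      gi[i] *= dec_syn;
    }
    if (stdp_on && n_plastic > 0) {
      for (int i = 0; i < nc; ++i) {
        xp[i] *= dec_xp;
        xm[i] *= dec_xm;
      }
    }

    // spike delivery: conductance jumps at t+dt using current weights
    for (size_t q = 0; q < spikers.size(); ++q) {
      const int j = spikers[q];
      const bool exc = is_exc[j];
      for (int a = s_ptr[j]; a < s_ptr[j + 1]; ++a) {
        if (exc) ge[s_tgt[a]] += s_w[a]; else gi[s_tgt[a]] += s_w[a];
      }
      for (int a = psrc_ptr[j]; a < psrc_ptr[j + 1]; ++a) {
        const int syn = psrc_idx[a];
        ge[p_tgt[syn]] += w[syn];
      }
    }

    if (stdp_on && n_plastic > 0 && !spikers.empty()) {
      // pre-triggered depression (uses x_minus from strictly earlier posts)
      for (size_t q = 0; q < spikers.size(); ++q) {
        const int j = spikers[q];
        if (!is_exc[j]) continue;
        for (int a = psrc_ptr[j]; a < psrc_ptr[j + 1]; ++a) {
          const int syn = psrc_idx[a];
          w[syn] = clipw(w[syn] - A_minus * xm[p_tgt[syn]], w_min, w_max);
        }
      }
      for (size_t q = 0; q < spikers.size(); ++q)
        if (is_exc[spikers[q]]) xp[spikers[q]] += 1.0;
      // post-triggered potentiation (x_plus now includes simultaneous pres)
      for (size_t q = 0; q < spikers.size(); ++q) {
        const int i = spikers[q];
        if (!is_exc[i]) continue;
        for (int a = ptgt_ptr[i]; a < ptgt_ptr[i + 1]; ++a) {
          const int syn = ptgt_idx[a];
          w[syn] = clipw(w[syn] + A_plus * xp[p_src[syn]], w_min, w_max);
        }
      }
      for (size_t q = 0; q < spikers.size(); ++q)
        if (is_exc[spikers[q]]) xm[spikers[q]] += 1.0;
    }

    while (snap_idx < n_snaps && snap_times[snap_idx] <= (t + dt) + 1e-9) {
      for (int a = 0; a < n_plastic; ++a) snaps(a, snap_idx) = w[a];
      ++snap_idx;
    }
  }

  return List::create(
    _["spike_cell"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["spike_time"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["w_final"] = NumericVector(w.begin(), w.end()),
    _["w_snapshots"] = snaps);
}
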