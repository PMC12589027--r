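// Fast inner loop of the escape-noise LIF network.
//
// The semantics (per-step phase order, refractory handling, delayed-event
// ring buffer, all-to-all STDP via exponential traces) are documented in the
// methods vignette; the pure-R single-step operations in R/model-core.R
// implement the same update rules and serve as the readable reference.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-free xoshiro256++ generator. The 256-bit state is carried inside
// the R-level network state (as 8 int32 words) so that a checkpointed run
// continues the exact same stream. std::mt19937 is avoided because its
// 2.5 kB state is awkward to serialize as plain text.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];

  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1) from the top 53 bits
  double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }
};

static uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static Xoshiro unpack_rng(const IntegerVector &st) {
  if (st.size() != 8) stop("rng state must have 8 words");
  Xoshiro g;
  for (int i = 0; i < 4; ++i) {
    uint32_t lo, hi;
    std::memcpy(&lo, &st[2 * i], 4);
    std::memcpy(&hi, &st[2 * i + 1], 4);
    g.s[i] = (uint64_t(hi) << 32) | uint64_t(lo);
  }
  return g;
}

static IntegerVector pack_rng(const Xoshiro &g) {
  IntegerVector st(8);
  for (int i = 0; i < 4; ++i) {
    uint32_t lo = uint32_t(g.s[i] & 0xFFFFFFFFULL);
    uint32_t hi = uint32_t(g.s[i] >> 32);
    std::memcpy(&st[2 * i], &lo, 4);
    std::memcpy(&st[2 * i + 1], &hi, 4);
  }
  return st;
}

// [[Rcpp::export]]
IntegerVector cpp_rng_seed(double seed) {
  uint64_t x = (uint64_t)(int64_t)seed;
  Xoshiro g;
  for (int i = 0; i < 4; ++i) g.s[i] = splitmix64(x);
  // xoshiro must not start from the all-zero state
  if ((g.s[0] | g.s[1] | g.s[2] | g.s[3]) == 0) g.s[0] = 1;
  return pack_rng(g);
}

// [[Rcpp::export]]
List cpp_rng_uniform(IntegerVector state, int n) {
  Xoshiro g = unpack_rng(state);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g.unif();
  return List::create(_["values"] = out, _["state"] = pack_rng(g));
}

static double getd(const List &l, const char *nm) {
  return as<double>(l[nm]);
}

static inline double clip01(double w) {
  if (w < 0.0) return 0.0;
  if (w > 1.0) return 1.0;
  return w;
}

// ---------------------------------------------------------------------------
// Main stepping loop.
//
// Per step, with t the clock at the step start and ts = t + dt the time
// stamped on spikes emitted during the step:
//   0. external stimulus pulses scheduled for this step are added to v
//   1. delayed synaptic events due this step are added to g_exc / g_inh
//   2. forward-Euler update of v (refractory neurons hold v = v_rest);
//      exact exponential decay of g_exc, g_inh, relaxation of x, decay of
//      the STDP traces; synaptic currents are sampled here when recording
//   3. one uniform draw per neuron; non-refractory neurons spike with
//      probability min(pref * exp((v - v_th)/b), 1)
//   4. for every spiker: all-to-all STDP weight updates from the traces
//      (traces exclude spikes of the current step, so simultaneous pairs do
//      not interact), then queueing of delayed releases U*x*w*g_max, the
//      depletion x <- x - U*x, reset v = v_rest, refractory timer, and
//      finally +1 on the spiker's own traces.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(List state, List prm, List sp, double duration_ms,
             NumericVector stim_times_ms, List stim_targets,
             double stim_amp, bool plasticity,
             bool record_spikes, bool record_currents,
             int weight_stride) {
  const double dt = getd(prm, "dt");
  const double tau_m = getd(prm, "tau_m");
  const double v_rest = getd(prm, "v_rest");
  const double v_th = getd(prm, "v_th");
  const double E_exc = getd(prm, "E_exc");
  const double E_inh = getd(prm, "E_inh");
  const double g_rest = getd(prm, "g_rest");
  const double f_rest = getd(prm, "f_rest");
  const double b = getd(prm, "b");
  const double U = getd(prm, "U");
  const double g_max_exc = getd(prm, "g_max_exc");
  const double g_max_inh = getd(prm, "g_max_inh");
  const double T_ref_exc = getd(prm, "T_ref_exc");
  const double T_ref_inh = getd(prm, "T_ref_inh");

  const int d_ee = (int)std::lround(getd(prm, "delay_EE") / dt);
  const int d_oo = (int)std::lround(getd(prm, "delay_other") / dt);

  const double dec_ampa = std::exp(-dt / getd(prm, "tau_AMPA"));
  const double dec_gaba = std::exp(-dt / getd(prm, "tau_GABA"));
  const double dec_rec = std::exp(-dt / getd(prm, "tau_rec"));

  // escape-noise prefactor Dt/tau calibrated so that v = v_rest fires at
  // f_rest (f_rest in Hz, dt in ms)
  const double pref = f_rest * dt * 1e-3 * std::exp((v_th - v_rest) / b);

  const double A_E = getd(sp, "A_E");
  const double A_I = getd(sp, "A_I");
  const double beta_E = getd(sp, "beta_E");
  const double beta_I = getd(sp, "beta_I");
  const double tau_E = getd(sp, "tau_E");
  const double tau_I1 = getd(sp, "tau_I1");
  const double tau_I2 = getd(sp, "tau_I2");
  const double rI = tau_I1 / tau_I2;
  const double KI = A_I / (1.0 - rI * beta_I);
  const double dec_trE = std::exp(-dt / tau_E);
  const double dec_tr1 = std::exp(-dt / tau_I1);
  const double dec_tr2 = std::exp(-dt / tau_I2);

  double t = getd(state, "t");
  NumericVector v = clone(as<NumericVector>(state["v"]));
  NumericVector g_exc = clone(as<NumericVector>(state["g_exc"]));
  NumericVector g_inh = clone(as<NumericVector>(state["g_inh"]));
  NumericVector x = clone(as<NumericVector>(state["x"]));
  NumericVector refrac = clone(as<NumericVector>(state["refrac_until"]));
  NumericMatrix w = clone(as<NumericMatrix>(state["w"]));
  NumericVector tr_e = clone(as<NumericVector>(state["tr_e"]));
  NumericVector tr_i1 = clone(as<NumericVector>(state["tr_i1"]));
  NumericVector tr_i2 = clone(as<NumericVector>(state["tr_i2"]));
  NumericMatrix pend_exc = clone(as<NumericMatrix>(state["pend_exc"]));
  NumericMatrix pend_inh = clone(as<NumericMatrix>(state["pend_inh"]));
  LogicalVector is_exc = as<LogicalVector>(state["is_exc"]);
  Xoshiro rng = unpack_rng(as<IntegerVector>(state["rng"]));

  const int n = v.size();
  const int max_d = pend_exc.nrow();
  if (d_ee > max_d || d_oo > max_d)
    stop("pending buffer too small for the synaptic delays");

  const long n_steps = std::lround(duration_ms / dt);

  // stimulus schedule -> step indices (times relative to current clock)
  const int n_stim = stim_times_ms.size();
  std::vector<long> stim_step(n_stim);
  for (int m = 0; m < n_stim; ++m) {
    stim_step[m] = std::lround((stim_times_ms[m] - t) / dt);
    if (stim_step[m] < 0 || stim_step[m] >= n_steps)
      stop("stimulus time outside the simulated interval");
    if (m > 0 && stim_step[m] < stim_step[m - 1])
      stop("stimulus times must be nondecreasing");
  }

  std::vector<double> spk_t;
  std::vector<int> spk_u;

  NumericMatrix curE, curI;
  if (record_currents) {
    curE = NumericMatrix(n, (int)n_steps);
    curI = NumericMatrix(n, (int)n_steps);
  }
  List w_snaps;
  std::vector<double> w_snap_t;

  std::vector<int> spikers(n);
  int cur = 0;  // ring-buffer row delivered at the next step

  int sptr = 0;
  for (long step = 0; step < n_steps; ++step) {
    const double ts = t + (step + 1) * dt;  // spike timestamp for this step

    // phase 0: stimulation
    while (sptr < n_stim && stim_step[sptr] == step) {
      IntegerVector tg = stim_targets[sptr];
      for (int k = 0; k < tg.size(); ++k) v[tg[k] - 1] += stim_amp;
      ++sptr;
    }

    // phase 1: deliver due synaptic events
    for (int j = 0; j < n; ++j) {
      g_exc[j] += pend_exc(cur, j);
      g_inh[j] += pend_inh(cur, j);
      pend_exc(cur, j) = 0.0;
      pend_inh(cur, j) = 0.0;
    }

    // phase 2: subthreshold dynamics and decays
    for (int i = 0; i < n; ++i) {
      const bool blocked = ts < refrac[i] - 1e-9;
      if (blocked) {
        v[i] = v_rest;
      } else {
        v[i] += dt / tau_m *
                ((v_rest - v[i]) * g_rest + (E_exc - v[i]) * g_exc[i] +
                 (E_inh - v[i]) * g_inh[i]);
      }
      if (record_currents) {
        curE(i, (int)step) = (E_exc - v[i]) * g_exc[i];
        curI(i, (int)step) = (E_inh - v[i]) * g_inh[i];
      }
      g_exc[i] *= dec_ampa;
      g_inh[i] *= dec_gaba;
      x[i] = 1.0 - (1.0 - x[i]) * dec_rec;
      tr_e[i] *= dec_trE;
      tr_i1[i] *= dec_tr1;
      tr_i2[i] *= dec_tr2;
    }

    // phase 3: escape-noise spike draws (one draw per neuron per step)
    int nspk = 0;
    for (int i = 0; i < n; ++i) {
      const double u = rng.unif();
      if (ts < refrac[i] - 1e-9) continue;
      double p = pref * std::exp((v[i] - v_th) / b);
      if (p > 1.0) p = 1.0;
      if (u < p) spikers[nspk++] = i;
    }

    // phase 4a: STDP updates (traces still exclude this step's spikes)
    if (plasticity && nspk > 0) {
      for (int s = 0; s < nspk; ++s) {
        const int k = spikers[s];
        const bool kexc = is_exc[k];
        // as presynaptic spike: pair with earlier postsynaptic spikes
        for (int j = 0; j < n; ++j) {
          if (j == k) continue;
          double dw;
          if (kexc)
            dw = -A_E * beta_E * tr_e[j];
          else
            dw = KI * (tr_i1[j] - rI * beta_I * tr_i2[j]);
          w(k, j) = clip01(w(k, j) + dw);
        }
        // as postsynaptic spike: pair with earlier presynaptic spikes
        for (int i = 0; i < n; ++i) {
          if (i == k) continue;
          double dw;
          if (is_exc[i])
            dw = A_E * tr_e[i];
          else
            dw = KI * (tr_i1[i] - rI * beta_I * tr_i2[i]);
          w(i, k) = clip01(w(i, k) + dw);
        }
      }
    }

    // phase 4b: releases, STP depletion, resets, trace increments
    for (int s = 0; s < nspk; ++s) {
      const int k = spikers[s];
      const bool kexc = is_exc[k];
      const double q = U * x[k];
      const double gmax = kexc ? g_max_exc : g_max_inh;
      for (int j = 0; j < n; ++j) {
        if (j == k) continue;
        const double amt = q * w(k, j) * gmax;
        if (amt == 0.0) continue;
        const int d = (kexc && is_exc[j]) ? d_ee : d_oo;
        const int row = (cur + d) % max_d;
        if (kexc)
          pend_exc(row, j) += amt;
        else
          pend_inh(row, j) += amt;
      }
      x[k] -= q;
      v[k] = v_rest;
      refrac[k] = ts + (kexc ? T_ref_exc : T_ref_inh);
      tr_e[k] += 1.0;
      tr_i1[k] += 1.0;
      tr_i2[k] += 1.0;
      if (record_spikes) {
        spk_t.push_back(ts);
        spk_u.push_back(k + 1);
      }
    }

    if (weight_stride > 0 && (step + 1) % weight_stride == 0) {
      w_snaps.push_back(clone(w));
      w_snap_t.push_back(ts);
    }

    cur = (cur + 1) % max_d;
  }

  // rotate the pending buffers so row 0 is again "next step"
  NumericMatrix pe(max_d, n), pi(max_d, n);
  for (int r = 0; r < max_d; ++r) {
    const int src = (cur + r) % max_d;
    for (int j = 0; j < n; ++j) {
      pe(r, j) = pend_exc(src, j);
      pi(r, j) = pend_inh(src, j);
    }
  }

  List new_state = clone(state);
  new_state["t"] = t + n_steps * dt;
  new_state["v"] = v;
  new_state["g_exc"] = g_exc;
  new_state["g_inh"] = g_inh;
  new_state["x"] = x;
  new_state["refrac_until"] = refrac;
  new_state["w"] = w;
  new_state["tr_e"] = tr_e;
  new_state["tr_i1"] = tr_i1;
  new_state["tr_i2"] = tr_i2;
  new_state["pend_exc"] = pe;
  new_state["pend_inh"] = pi;
  new_state["rng"] = pack_rng(rng);

  List out = List::create(
      _["state"] = new_state,
      _["spike_t_ms"] = NumericVector(spk_t.begin(), spk_t.end()),
      _["spike_unit"] = IntegerVector(spk_u.begin(), spk_u.end()));
  if (record_currents) {
    out["cur_E"] = curE;
    out["cur_I"] = curI;
  }
  if (weight_stride > 0) {
    out["w_snapshots"] = w_snaps;
    out["w_snapshot_t_ms"] = NumericVector(w_snap_t.begin(), w_snap_t.end());
  }
  return out;
}
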