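// Euler-Maruyama simulation of a recurrent network of exponential
// integrate-and-fire neurons with exponential current-based synapses,
// white-noise drive (optionally with a shared white or Ornstein-Uhlenbeck
// component) and optional online pair-based additive Hebbian STDP.
//
// The hot loop draws ~N/dt normal variates per simulated millisecond, so the
// simulator uses its own xoshiro256++ streams (seeded from the user seed via
// splitmix64) with Box-Muller normals; separate substreams drive private
// noise, the common input and the initial conditions, so that toggling one
// component does not shift the draws of another.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

namespace {

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0) +
           (0.5 / 9007199254740992.0);
  }
  bool has_spare = false;
  double spare = 0.0;
  inline double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u = unif(), v = unif();
    double rad = std::sqrt(-2.0 * std::log(u));
    double ang = 6.283185307179586476925286766559 * v;
    spare = rad * std::sin(ang);
    has_spare = true;
    return rad * std::cos(ang);
  }
};

}  // namespace

using namespace Rcpp;

// [[Rcpp::export(name = ".sim_eif_network")]]
List sim_eif_network(int N,
                     IntegerVector edge_pre,   // presynaptic j, 0-based
                     IntegerVector edge_post,  // postsynaptic i, 0-based
                     NumericVector edge_w0,    // initial weights (uA/cm^2)
                     List eif, List noise, List stdp, List cfg,
                     NumericVector record_times) {
  const double C = eif["C"], gL = eif["gL"], VL = eif["VL"],
               Delta = eif["Delta"], VT = eif["VT"], Vth = eif["Vth"],
               Vre = eif["Vre"], tau_ref = eif["tau_ref"];
  const double mu = noise["mu"], sigma = noise["sigma"], cfrac = noise["c"],
               ou_tau = noise["ou_tau"];
  const bool common_ou = as<std::string>(noise["common_kind"]) == "OU";
  const double f_plus = stdp["f_plus"], f_minus = stdp["f_minus"],
               tau_plus = stdp["tau_plus"], tau_minus = stdp["tau_minus"],
               wmax = stdp["wmax"];
  const double dt = cfg["dt"], Ttot = cfg["T"], tauS = cfg["tauS"],
               rate_cap = cfg["rate_cap"];
  const bool plastic = cfg["plasticity_on"], rec_spikes = cfg["record_spikes"];
  const uint64_t seed = (uint64_t)(double)cfg["seed"];

  const int nE = edge_pre.size();
  std::vector<double> w(edge_w0.begin(), edge_w0.end());

  // CSR-style indexing: edges grouped by presynaptic (for current injection
  // and depression) and by postsynaptic neuron (for potentiation)
  std::vector<int> out_count(N, 0), in_count(N, 0);
  for (int e = 0; e < nE; ++e) { out_count[edge_pre[e]]++; in_count[edge_post[e]]++; }
  std::vector<int> out_ptr(N + 1, 0), in_ptr(N + 1, 0);
  for (int i = 0; i < N; ++i) {
    out_ptr[i + 1] = out_ptr[i] + out_count[i];
    in_ptr[i + 1] = in_ptr[i] + in_count[i];
  }
  std::vector<int> out_eid(nE), in_eid(nE), pos_o(out_ptr.begin(), out_ptr.end() - 1),
      pos_i(in_ptr.begin(), in_ptr.end() - 1);
  for (int e = 0; e < nE; ++e) {
    out_eid[pos_o[edge_pre[e]]++] = e;
    in_eid[pos_i[edge_post[e]]++] = e;
  }

  Xoshiro256 rng_priv(seed * 6364136223846793005ULL + 1442695040888963407ULL);
  Xoshiro256 rng_comm(seed * 2862933555777941757ULL + 3037000493ULL);
  Xoshiro256 rng_init(seed + 0x9E3779B97f4A7C15ULL);

  const double tau_m = C / gL;
  const double noise_sd_priv = sigma * std::sqrt(2.0 * dt / tau_m) *
                               std::sqrt(1.0 - cfrac);
  const double D = std::sqrt(2.0 * C / gL);
  // common term: white uses a per-step shared normal with the same scaling as
  // the private noise; OU uses a unit-low-frequency-density process
  const double noise_sd_comm_white = sigma * std::sqrt(2.0 * dt / tau_m) *
                                     std::sqrt(cfrac);
  // OU common input: unit stationary variance, so the shared current is
  // sqrt(c) * gL * sigma * D * z(t) with z an OU process of timescale ou_tau
  const double ou_decay = std::exp(-dt / ou_tau);
  const double ou_sd = std::sqrt(1.0 - ou_decay * ou_decay);
  const double comm_ou_gain = std::sqrt(cfrac) * gL * sigma * D / C;  // * z * dt

  std::vector<double> V(N), syn(N, 0.0), refrac(N, 0.0),
      trace_pre(N, 0.0), trace_post(N, 0.0);
  for (int i = 0; i < N; ++i)
    V[i] = VL + (VT - VL) * rng_init.unif();

  const double syn_decay = std::exp(-dt / tauS);
  const double trp_decay = std::exp(-dt / tau_plus);
  const double trm_decay = std::exp(-dt / tau_minus);
  const long nsteps = (long)std::llround(Ttot / dt);

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  std::vector<int> spiking;
  spiking.reserve(N);

  // weight snapshots
  int n_rec = record_times.size(), next_rec = 0;
  NumericMatrix Wrec(n_rec > 0 ? nE : 0, n_rec);

  long spike_count_window = 0;
  const long cap_check = (long)std::llround(1000.0 / dt);  // every second
  bool aborted = false;
  double t = 0.0;
  double z_ou = 0.0;

  for (long step = 0; step < nsteps && !aborted; ++step) {
    t = step * dt;
    double comm = 0.0;
    if (cfrac > 0.0) {
      if (common_ou) {
        z_ou = z_ou * ou_decay + ou_sd * rng_comm.normal();
        comm = comm_ou_gain * z_ou * dt;
      } else {
        comm = noise_sd_comm_white * rng_comm.normal();
      }
    }
    spiking.clear();
    for (int i = 0; i < N; ++i) {
      if (refrac[i] > 0.0) {
        refrac[i] -= dt;
        syn[i] *= syn_decay;
        // keep the private stream aligned whether or not the neuron is
        // refractory, so spike times do not reshuffle the noise of others
        rng_priv.normal();
        continue;
      }
      double arg = (V[i] - VT) / Delta;
      double spike_term = (arg > -20.0)
          ? gL * Delta * std::exp(arg < 30.0 ? arg : 30.0) : 0.0;
      double drift = (gL * (VL - V[i]) + spike_term + mu + syn[i]) / C;
      V[i] += dt * drift + noise_sd_priv * rng_priv.normal() + comm;
      syn[i] *= syn_decay;
      if (V[i] >= Vth) {
        spiking.push_back(i);
        V[i] = Vre;
        refrac[i] = tau_ref;
      }
    }

    if (!spiking.empty()) {
      spike_count_window += (long)spiking.size();
      for (int i : spiking) {
        if (rec_spikes) { sp_id.push_back(i + 1); sp_t.push_back(t + dt); }
        // presynaptic role: trace increment first so that exactly coincident
        // pre/post pairs are credited to potentiation
        trace_pre[i] += 1.0;
      }
      for (int i : spiking) {
        // postsynaptic role: potentiate all incoming synapses
        if (plastic) {
          for (int k = in_ptr[i]; k < in_ptr[i + 1]; ++k) {
            int e = in_eid[k];
            double wn = w[e] + f_plus * trace_pre[edge_pre[e]];
            w[e] = wn > wmax ? wmax : wn;
          }
        }
        // presynaptic role: inject current, depress via the post trace
        for (int k = out_ptr[i]; k < out_ptr[i + 1]; ++k) {
          int e = out_eid[k];
          syn[edge_post[e]] += w[e];
          if (plastic) {
            double wn = w[e] - f_minus * trace_post[edge_post[e]];
            w[e] = wn < 0.0 ? 0.0 : wn;
          }
        }
      }
      for (int i : spiking) trace_post[i] += 1.0;
    }
    for (int i = 0; i < N; ++i) {
      trace_pre[i] *= trp_decay;
      trace_post[i] *= trm_decay;
    }

    if (next_rec < n_rec && t + dt >= record_times[next_rec]) {
      for (int e = 0; e < nE; ++e) Wrec(e, next_rec) = w[e];
      ++next_rec;
    }
    if ((step + 1) % cap_check == 0) {
      double mean_rate_hz = 1000.0 * spike_count_window / ((double)N * 1000.0);
      if (mean_rate_hz > rate_cap) aborted = true;
      spike_count_window = 0;
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["spike_id"] = wrap(sp_id), _["spike_t"] = wrap(sp_t),
      _["w_final"] = wrap(w), _["w_rec"] = Wrec,
      _["record_times"] = record_times,
      _["aborted"] = aborted, _["t_end"] = aborted ? t : Ttot);
}
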