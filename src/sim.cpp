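#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// xoshiro256+ with splitmix64 seeding: fast uniform doubles in [0, 1) for
// the per-neuron spike draws; seeded explicitly so traces are a pure
// function of the dynamics seed, independent of R's global RNG kind.
namespace {
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      s[i] = x ^ (x >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline double next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return (result >> 11) * 0x1.0p-53;
  }
};
} // namespace

// Synchronous stochastic update of the full lattice.
//
// Per step, in this exact order (simultaneous-update reading: every
// right-hand side refers to the previous step's published state):
//   1. rate variable   R <- (R + I_prev) * (1 - dt/tauP) + P0 * dt/tauP
//   2. current         I <- (I + W^T S_prev) * (1 - dt/tauI)
//   3. spike draw      S ~ Bernoulli(clamp(R, 0, 1)), one uniform per
//                      neuron in fixed index order
//   4. reset           spiking neurons get R <- reset value
//
// Outgoing synapses are passed in compressed-column form of t(W)
// (column j holds the targets of presynaptic neuron j), so scattering
// input from the (typically few) spikers is O(spikes * out-degree).
//
// Spike draws come from an internal xoshiro256+ stream seeded from the
// dynamics seed, so traces are bit-reproducible and cheap to draw.
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n_neurons, int n_steps,
              IntegerVector wt_p, IntegerVector wt_i, NumericVector wt_x,
              NumericVector decay_p, NumericVector p0_term,
              NumericVector reset_val, double decay_i,
              bool keep_raster, double seed1, double seed2,
              NumericVector I0, NumericVector R0, IntegerVector S0,
              bool updated_current) {
  std::vector<double> I(n_neurons, 0.0), R(n_neurons, 0.0), acc(n_neurons, 0.0);
  std::vector<int> spikers, spikers_new;
  spikers.reserve(n_neurons);
  spikers_new.reserve(n_neurons);
  if (I0.size() == n_neurons) {
    for (int i = 0; i < n_neurons; ++i) { I[i] = I0[i]; R[i] = R0[i]; }
    for (int i = 0; i < n_neurons; ++i) if (S0[i]) spikers.push_back(i);
  }
  IntegerVector A(n_steps);
  std::vector<int> ras_t, ras_i;

  Xoshiro rng((uint64_t)seed1 * 2654435769ULL + (uint64_t)seed2);
  for (int t = 0; t < n_steps; ++t) {
    if (!updated_current) {
      // rate variable uses the previous step's published current
      for (int i = 0; i < n_neurons; ++i)
        R[i] = (R[i] + I[i]) * decay_p[i] + p0_term[i];
    }
    // synaptic input from previous-step spikes, then exponential decay
    if (!spikers.empty()) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int k = 0; k < (int)spikers.size(); ++k) {
        int j = spikers[k];
        for (int e = wt_p[j]; e < wt_p[j + 1]; ++e)
          acc[wt_i[e]] += wt_x[e];
      }
      for (int i = 0; i < n_neurons; ++i)
        I[i] = (I[i] + acc[i]) * decay_i;
    } else {
      for (int i = 0; i < n_neurons; ++i)
        I[i] *= decay_i;
    }
    if (updated_current) {
      // alternative reading: rate variable sees this step's updated current
      for (int i = 0; i < n_neurons; ++i)
        R[i] = (R[i] + I[i]) * decay_p[i] + p0_term[i];
    }
    // spike draws: exactly one uniform per neuron per step, fixed neuron
    // order, so a trace is a pure function of (topology, seed, n_steps);
    // clamp(R, 0, 1) is the probability (u ~ U(0,1) never falls below p <= 0)
    spikers_new.clear();
    for (int i = 0; i < n_neurons; ++i) {
      double p = R[i];
      if (p != p)
        stop("non-finite spiking-rate variable at step %d (parameter blow-up)", t + 1);
      double u = rng.next();
      if (p >= 1.0 || u < p) {
        spikers_new.push_back(i);
        R[i] = reset_val[i];
      }
    }
    A[t] = (int)spikers_new.size();
    if (keep_raster) {
      for (int k = 0; k < (int)spikers_new.size(); ++k) {
        ras_t.push_back(t + 1);
        ras_i.push_back(spikers_new[k] + 1);
      }
    }
    spikers.swap(spikers_new);
    if ((t & 0xFFF) == 0) {
      for (int i = 0; i < n_neurons; ++i)
        if (!std::isfinite(I[i]) || !std::isfinite(R[i]))
          stop("non-finite neuron state at step %d (parameter blow-up)", t + 1);
    }
  }

  List out = List::create(_["A"] = A);
  if (keep_raster)
    out["raster"] = DataFrame::create(_["t"] = wrap(ras_t), _["neuron"] = wrap(ras_i));
  return out;
}
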