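#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based RNG: splitmix64 finalizer chained over the key tuple.
// Every random draw in the simulator is a pure function of
// (seed, env-combination, replicate, node, step), which gives each
// (replicate, node) pair its own substream. Clamping a node therefore
// perturbs no other node's stream: components not downstream of the clamp
// follow bit-identical trajectories under the same seed.
static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t seed, uint64_t k1, uint64_t k2,
                         uint64_t k3, uint64_t k4) {
  uint64_t h = sm64(seed ^ sm64(k1 ^ sm64(k2 ^ sm64(k3 ^ sm64(k4)))));
  // 53-bit mantissa uniform on [0, 1)
  return (h >> 11) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export]]
NumericVector counter_uniform_cpp(double seed, IntegerVector k1,
                                  IntegerVector k2, IntegerVector k3,
                                  IntegerVector k4) {
  int n = k1.size();
  NumericVector out(n);
  uint64_t s = (uint64_t)(int64_t)seed;
  for (int i = 0; i < n; ++i)
    out[i] = u01(s, (uint64_t)k1[i], (uint64_t)k2[i], (uint64_t)k3[i],
                 (uint64_t)k4[i]);
  return out;
}

// Synchronous simulation of one environment combination.
//
// kind:    1 internal, 0 external (per node)
// reg_idx: per node, 1-based regulator indices (empty for externals)
// tt_out:  per node, truth-table outputs, row = regulator states read as a
//          binary number with the first-listed regulator most significant
// ext_p:   per node, Bernoulli probability in [0,100] (externals only)
// clamp:   per node, -1 free / 0 / 1, held at every step including t = 0
// Internal initial states are Bernoulli(0.5) (step key 0); external states
// are redrawn each step (step keys 0..T). AL = 100 * mean of the last
// `window` states of the T-step trajectory.
// [[Rcpp::export]]
List simulate_cpp(IntegerVector kind, List reg_idx, List tt_out,
                  NumericVector ext_p, IntegerVector clamp,
                  int steps, int window, int n_rep,
                  double seed, int env_index,
                  Nullable<IntegerVector> init = R_NilValue,
                  bool record_traj = false) {
  int n = kind.size();
  if (window > steps) stop("window must be <= steps");
  uint64_t s = (uint64_t)(int64_t)seed;
  uint64_t ek = (uint64_t)env_index;

  // pre-extract function tables
  std::vector<std::vector<int>> regs(n);
  std::vector<std::vector<int>> outs(n);
  for (int i = 0; i < n; ++i) {
    if (kind[i] == 1) {
      IntegerVector r = reg_idx[i];
      IntegerVector o = tt_out[i];
      regs[i].assign(r.begin(), r.end());
      outs[i].assign(o.begin(), o.end());
    }
  }
  bool has_init = init.isNotNull();
  IntegerVector init_v;
  if (has_init) init_v = init.get();

  NumericMatrix al(n, n_rep);
  List traj_list(record_traj ? n_rep : 0);

  std::vector<int> st(n), nx(n);
  for (int rep = 0; rep < n_rep; ++rep) {
    uint64_t rk = (uint64_t)(rep + 1);
    // t = 0
    for (int i = 0; i < n; ++i) {
      if (clamp[i] >= 0) {
        st[i] = clamp[i];
      } else if (kind[i] == 0) {
        st[i] = u01(s, ek, rk, (uint64_t)(i + 1), 0) < ext_p[i] / 100.0;
      } else if (has_init) {
        st[i] = init_v[i];
      } else {
        st[i] = u01(s, ek, rk, (uint64_t)(i + 1), 0) < 0.5;
      }
    }
    IntegerMatrix traj;
    if (record_traj) {
      traj = IntegerMatrix(n, steps + 1);
      for (int i = 0; i < n; ++i) traj(i, 0) = st[i];
    }
    std::vector<int> active(n, 0);
    for (int t = 1; t <= steps; ++t) {
      for (int i = 0; i < n; ++i) {
        if (clamp[i] >= 0) {
          nx[i] = clamp[i];
        } else if (kind[i] == 0) {
          nx[i] = u01(s, ek, rk, (uint64_t)(i + 1), (uint64_t)t) <
                  ext_p[i] / 100.0;
        } else {
          const std::vector<int> &r = regs[i];
          int idx = 0;
          for (size_t j = 0; j < r.size(); ++j)
            idx = (idx << 1) | st[r[j] - 1];
          nx[i] = outs[i][idx];
        }
      }
      st.swap(nx);
      if (record_traj)
        for (int i = 0; i < n; ++i) traj(i, t) = st[i];
      if (t > steps - window)
        for (int i = 0; i < n; ++i) active[i] += st[i];
    }
    for (int i = 0; i < n; ++i)
      al(i, rep) = 100.0 * (double)active[i] / (double)window;
    if (record_traj) traj_list[rep] = traj;
  }

  if (record_traj) return List::create(_["al"] = al, _["traj"] = traj_list);
  return List::create(_["al"] = al);
}
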