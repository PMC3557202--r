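#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Self-contained counter-based RNG (splitmix64). Each run derives its own
// stream from (master seed, run index), so ensembles are reproducible
// bit-exactly and independent of R's global RNG state.
static inline uint64_t sm64(uint64_t &s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Stream {
  uint64_t s;
  explicit Stream(uint64_t seed) : s(seed) { sm64(s); sm64(s); }
  // uniform on [0, 1)
  double unif() { return (sm64(s) >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer on {0, ..., n-1}
  int below(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

static inline uint64_t derive_seed(double master, int run) {
  uint64_t s = static_cast<uint64_t>(static_cast<int64_t>(master));
  s ^= 0xD1B54A32D192ED03ULL * static_cast<uint64_t>(run + 1);
  return s;
}

// shift-up / shift-down / decay-toward-control transition
static inline int update_state(int cur, int infl) {
  if (infl > 0) return cur < 2 ? cur + 1 : 2;
  if (infl < 0) return cur > 0 ? cur - 1 : 0;
  if (cur > 1) return cur - 1;
  if (cur < 1) return cur + 1;
  return 1;
}

struct NetArrays {
  IntegerVector src, tgt, sgn, del;
  LogicalVector clamped;
  IntegerVector clamp_level;
  IntegerVector ordinary;  // 0-based indices of non-clamped nodes
  int n_nodes;
  std::vector<std::vector<int> > inedges;  // per node: incoming edge ids

  explicit NetArrays(const List &net) {
    src = net["src"];
    tgt = net["tgt"];
    sgn = net["sgn"];
    del = net["del"];
    clamped = net["clamped"];
    clamp_level = net["clamp_level"];
    ordinary = net["ordinary"];
    n_nodes = clamped.size();
    inedges.assign(n_nodes, std::vector<int>());
    for (int e = 0; e < tgt.size(); ++e) inedges[tgt[e]].push_back(e);
  }
};

// One asynchronous run. Row 0 of `traj` is the initial state; row i the
// snapshot after full pass i. Delay-d reads while computing row i come from
// row i-1-d (baseline 1 before row 0); delay-0 reads the in-pass working
// state so updates are realized immediately.
static void one_run(const NetArrays &na, int horizon, double p, Stream &rng,
                    const int *init, const int *orders, IntegerMatrix &traj) {
  const int n = na.n_nodes;
  const int k = na.ordinary.size();
  for (int v = 0; v < n; ++v) {
    int s0;
    if (na.clamped[v]) {
      s0 = na.clamp_level[v];
    } else if (init != 0) {
      s0 = init[v];
    } else {
      double u = rng.unif();
      s0 = u < p ? 0 : (u < 2.0 * p ? 2 : 1);
    }
    traj(0, v) = s0;
  }
  std::vector<int> w(n), perm(k);
  for (int i = 1; i <= horizon; ++i) {
    for (int v = 0; v < n; ++v) w[v] = traj(i - 1, v);
    if (orders != 0) {
      for (int j = 0; j < k; ++j) perm[j] = orders[(i - 1) + (size_t)horizon * j];
    } else {
      for (int j = 0; j < k; ++j) perm[j] = na.ordinary[j];
      for (int j = k - 1; j > 0; --j) {
        int m = rng.below(j + 1);
        std::swap(perm[j], perm[m]);
      }
    }
    for (int j = 0; j < k; ++j) {
      int v = perm[j];
      int infl = 0;
      const std::vector<int> &ie = na.inedges[v];
      for (size_t q = 0; q < ie.size(); ++q) {
        int e = ie[q];
        int d = na.del[e];
        int rs;
        if (d == 0) {
          rs = w[na.src[e]];
        } else {
          int r = i - 1 - d;
          rs = r >= 0 ? traj(r, na.src[e]) : 1;
        }
        infl += na.sgn[e] * (rs - 1);
      }
      w[v] = update_state(w[v], infl);
    }
    for (int v = 0; v < n; ++v)
      traj(i, v) = na.clamped[v] ? na.clamp_level[v] : w[v];
  }
}

// [[Rcpp::export(name = ".sim_run_cpp")]]
IntegerMatrix sim_run_cpp(List net, Nullable<IntegerVector> init, int horizon,
                          double master_seed, int run_index,
                          Nullable<IntegerMatrix> orders, double p) {
  NetArrays na(net);
  Stream rng(derive_seed(master_seed, run_index));
  IntegerMatrix traj(horizon + 1, na.n_nodes);
  const int *ip = 0;
  IntegerVector iv;
  if (init.isNotNull()) {
    iv = init.get();
    ip = INTEGER(iv);
  }
  const int *op = 0;
  IntegerMatrix om;
  if (orders.isNotNull()) {
    om = orders.get();
    op = INTEGER(om);
  }
  one_run(na, horizon, p, rng, ip, op, traj);
  return traj;
}

// [[Rcpp::export(name = ".run_ensemble_cpp")]]
List run_ensemble_cpp(List net, int n_runs, int horizon, double p,
                      double master_seed, bool keep_runs) {
  NetArrays na(net);
  const int n = na.n_nodes;
  const int rows = horizon + 1;
  NumericMatrix sum(rows, n), sumsq(rows, n);
  IntegerMatrix traj(rows, n);
  IntegerVector runs;
  if (keep_runs) runs = IntegerVector(Dimension(rows, n, n_runs));
  for (int r = 0; r < n_runs; ++r) {
    Stream rng(derive_seed(master_seed, r));
    one_run(na, horizon, p, rng, 0, 0, traj);
    for (int v = 0; v < n; ++v) {
      for (int i = 0; i < rows; ++i) {
        double x = traj(i, v);
        sum(i, v) += x;
        sumsq(i, v) += x * x;
      }
    }
    if (keep_runs) {
      int *dst = INTEGER(runs) + (size_t)r * rows * n;
      for (int q = 0; q < rows * n; ++q) dst[q] = traj[q];
    }
  }
  NumericMatrix mean(rows, n), sd(rows, n);
  for (int v = 0; v < n; ++v) {
    for (int i = 0; i < rows; ++i) {
      double m = sum(i, v) / n_runs;
      mean(i, v) = m;
      double ss = n_runs > 1 ? (sumsq(i, v) - n_runs * m * m) / (n_runs - 1) : 0.0;
      sd(i, v) = ss > 0 ? std::sqrt(ss) : 0.0;
    }
  }
  List out = List::create(_["mean"] = mean, _["sd"] = sd);
  if (keep_runs) out["runs"] = runs;
  return out;
}
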