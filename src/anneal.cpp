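#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Self-contained, platform-portable PRNG: xoshiro256++ seeded by splitmix64.
// Keeps simulated-annealing trajectories bit-reproducible across platforms
// for a given 64-bit seed, independent of R's RNG state.
namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
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
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int sample(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

} // namespace

// Metropolis Monte Carlo with geometric simulated annealing over an
// interaction matrix. Single-position uniform resampling moves; returns the
// best assignment ever seen plus the per-stage best-so-far trace.
// [[Rcpp::export]]
List anneal_core(IntegerVector n_choices, List one_body,
                 IntegerVector pair_i, IntegerVector pair_j, List pair_mats,
                 double t_start, double t_end, double cooling,
                 int moves_per_stage, double seed, IntegerVector init) {
  const int np = n_choices.size();
  std::vector<NumericVector> ob(np);
  for (int p = 0; p < np; ++p) ob[p] = as<NumericVector>(one_body[p]);
  const int npair = pair_i.size();
  std::vector<NumericMatrix> tb(npair);
  std::vector<std::vector<std::pair<int, bool> > > adj(np);
  for (int e = 0; e < npair; ++e) {
    tb[e] = as<NumericMatrix>(pair_mats[e]);
    adj[pair_i[e] - 1].push_back(std::make_pair(e, true));
    adj[pair_j[e] - 1].push_back(std::make_pair(e, false));
  }
  std::vector<int> cur(np);
  for (int p = 0; p < np; ++p) cur[p] = init[p] - 1;

  auto total = [&](const std::vector<int>& a) {
    double e = 0.0;
    for (int p = 0; p < np; ++p) e += ob[p][a[p]];
    for (int k = 0; k < npair; ++k)
      e += tb[k](a[pair_i[k] - 1], a[pair_j[k] - 1]);
    return e;
  };

  double e_cur = total(cur);
  std::vector<int> best = cur;
  double e_best = e_cur;

  std::vector<int> movable;
  for (int p = 0; p < np; ++p) if (n_choices[p] > 1) movable.push_back(p);

  std::vector<double> trace;
  Xoshiro256pp rng(static_cast<uint64_t>(seed));

  if (!movable.empty()) {
    for (double t = t_start; t >= t_end; t *= cooling) {
      for (int m = 0; m < moves_per_stage; ++m) {
        const int p = movable[rng.sample((int)movable.size())];
        int c_new = rng.sample(n_choices[p] - 1);
        if (c_new >= cur[p]) ++c_new;  // uniform over the other choices
        double delta = ob[p][c_new] - ob[p][cur[p]];
        for (size_t k = 0; k < adj[p].size(); ++k) {
          const int e = adj[p][k].first;
          const NumericMatrix& M = tb[e];
          if (adj[p][k].second) {
            const int other = cur[pair_j[e] - 1];
            delta += M(c_new, other) - M(cur[p], other);
          } else {
            const int other = cur[pair_i[e] - 1];
            delta += M(other, c_new) - M(other, cur[p]);
          }
        }
        if (delta <= 0.0 || rng.unif() < std::exp(-delta / t)) {
          cur[p] = c_new;
          e_cur += delta;
          if (e_cur < e_best) {
            e_best = e_cur;
            best = cur;
          }
        }
      }
      trace.push_back(e_best);
    }
  } else {
    trace.push_back(e_best);
  }

  // guard against drift in the incrementally updated energy
  double e_exact = total(best);

  IntegerVector out(np);
  for (int p = 0; p < np; ++p) out[p] = best[p] + 1;
  return List::create(_["assignment"] = out, _["energy"] = e_exact,
                      _["trace"] = wrap(trace));
}
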