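// Collapsed Gibbs sampler for latent Dirichlet allocation with symmetric
// Dirichlet priors. Uses a self-contained xorshift128+ RNG so fits are
// bit-reproducible for a given seed across platforms, independent of R's
// RNG state.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct XorShift128 {
  uint64_t s0, s1;
  explicit XorShift128(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 2; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      z = z ^ (z >> 31);
      if (i == 0) s0 = z | 1ULL; else s1 = z | 1ULL;
    }
  }
  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

}  // namespace

// docs: list of integer vectors of 0-based vocabulary ids.
// Returns averaged (post-burn-in) topic-word matrix phi (K x V) and
// document-topic matrix theta (D x K).
// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(List docs, int V, int K, double alpha, double eta,
                   int n_iter, int burnin, double seed) {
  const int D = docs.size();
  XorShift128 rng(static_cast<uint64_t>(seed));

  std::vector<std::vector<int>> w(D);
  std::vector<std::vector<int>> z(D);
  std::vector<std::vector<int>> nw(K, std::vector<int>(V, 0));
  std::vector<std::vector<int>> nd(D, std::vector<int>(K, 0));
  std::vector<int> nwsum(K, 0);

  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    w[d].assign(doc.begin(), doc.end());
    z[d].resize(w[d].size());
    for (size_t t = 0; t < w[d].size(); ++t) {
      int k = static_cast<int>(rng.unif() * K);
      if (k >= K) k = K - 1;
      z[d][t] = k;
      ++nw[k][w[d][t]];
      ++nd[d][k];
      ++nwsum[k];
    }
  }

  NumericMatrix phi_acc(K, V);
  NumericMatrix theta_acc(D, K);
  int n_avg = 0;
  std::vector<double> p(K);

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      const size_t n = w[d].size();
      for (size_t t = 0; t < n; ++t) {
        const int word = w[d][t];
        int k = z[d][t];
        --nw[k][word]; --nd[d][k]; --nwsum[k];
        double total = 0.0;
        for (int j = 0; j < K; ++j) {
          total += (nd[d][j] + alpha) * (nw[j][word] + eta) /
                   (nwsum[j] + V * eta);
          p[j] = total;
        }
        const double u = rng.unif() * total;
        int knew = 0;
        while (knew < K - 1 && p[knew] < u) ++knew;
        z[d][t] = knew;
        ++nw[knew][word]; ++nd[d][knew]; ++nwsum[knew];
      }
    }
    if (iter >= burnin) {
      ++n_avg;
      for (int k = 0; k < K; ++k) {
        const double denom = nwsum[k] + V * eta;
        for (int v = 0; v < V; ++v) {
          phi_acc(k, v) += (nw[k][v] + eta) / denom;
        }
      }
      for (int d = 0; d < D; ++d) {
        const double denom = w[d].size() + K * alpha;
        for (int k = 0; k < K; ++k) {
          theta_acc(d, k) += (nd[d][k] + alpha) / denom;
        }
      }
    }
  }

  if (n_avg > 0) {
    for (int k = 0; k < K; ++k)
      for (int v = 0; v < V; ++v) phi_acc(k, v) /= n_avg;
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < K; ++k) theta_acc(d, k) /= n_avg;
  }
  // renormalize rows of phi exactly
  for (int k = 0; k < K; ++k) {
    double s = 0.0;
    for (int v = 0; v < V; ++v) s += phi_acc(k, v);
    if (s > 0) for (int v = 0; v < V; ++v) phi_acc(k, v) /= s;
  }
  for (int d = 0; d < D; ++d) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += theta_acc(d, k);
    if (s > 0) for (int k = 0; k < K; ++k) theta_acc(d, k) /= s;
  }
  return List::create(_["phi"] = phi_acc, _["theta"] = theta_acc);
}
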