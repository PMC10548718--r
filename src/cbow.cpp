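#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Deterministic single-threaded CBOW with negative sampling.
// Sentences are given as a flat 0-based token stream plus offsets; the
// unigram^0.75 negative-sampling distribution is passed as a CDF.

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);  // [0,1)
  }
};

inline double sigmoid_clamped(double x) {
  if (x > 6.0) return 1.0 - 1e-8;
  if (x < -6.0) return 1e-8;
  return 1.0 / (1.0 + std::exp(-x));
}

inline int sample_cdf(const NumericVector &cdf, double u) {
  int lo = 0, hi = cdf.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_cbow_train(IntegerVector tokens, IntegerVector offsets,
                             int vocab_size, int dim, int window, int epochs,
                             int negative, double alpha, double min_alpha,
                             NumericVector cdf, int seed) {
  const int n_sent = offsets.size() - 1;
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (rng.unif() - 0.5) / dim;
  }

  std::vector<double> hidden(dim), err(dim);
  const long total = static_cast<long>(epochs) * n_sent;
  long done = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s, ++done) {
      double lr = alpha - (alpha - min_alpha) *
                              (static_cast<double>(done) / total);
      if (lr < min_alpha) lr = min_alpha;
      const int beg = offsets[s], end = offsets[s + 1];
      const int len = end - beg;
      for (int pos = 0; pos < len; ++pos) {
        const int target = tokens[beg + pos];
        // mean of in-window context vectors
        int cnt = 0;
        std::fill(hidden.begin(), hidden.end(), 0.0);
        for (int j = pos - window; j <= pos + window; ++j) {
          if (j < 0 || j >= len || j == pos) continue;
          const double *v = &syn0[static_cast<size_t>(tokens[beg + j]) * dim];
          for (int d = 0; d < dim; ++d) hidden[d] += v[d];
          ++cnt;
        }
        if (cnt == 0) continue;
        for (int d = 0; d < dim; ++d) hidden[d] /= cnt;
        std::fill(err.begin(), err.end(), 0.0);
        for (int k = 0; k <= negative; ++k) {
          int w;
          double label;
          if (k == 0) {
            w = target;
            label = 1.0;
          } else {
            w = sample_cdf(cdf, rng.unif());
            if (w == target) continue;
            label = 0.0;
          }
          double *out = &syn1[static_cast<size_t>(w) * dim];
          double f = 0.0;
          for (int d = 0; d < dim; ++d) f += hidden[d] * out[d];
          const double g = (label - sigmoid_clamped(f)) * lr;
          for (int d = 0; d < dim; ++d) {
            err[d] += g * out[d];
            out[d] += g * hidden[d];
          }
        }
        for (int j = pos - window; j <= pos + window; ++j) {
          if (j < 0 || j >= len || j == pos) continue;
          double *v = &syn0[static_cast<size_t>(tokens[beg + j]) * dim];
          for (int d = 0; d < dim; ++d) v[d] += err[d];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i) {
    for (int d = 0; d < dim; ++d) {
      out(i, d) = syn0[static_cast<size_t>(i) * dim + d];
    }
  }
  return out;
}
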