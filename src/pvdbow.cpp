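#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Deterministic xorshift64* PRNG so training is bit-reproducible across
// platforms regardless of R's RNG state.
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s * UINT64_C(2685821657736338717);
}

static inline double runif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// 64-bit FNV-1a over the UTF-8 bytes of each string, rendered as 16 hex chars.
// [[Rcpp::export]]
CharacterVector fnv1a64(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  char buf[17];
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) {
      out[i] = NA_STRING;
      continue;
    }
    const char *p = CHAR(STRING_ELT(x, i));
    uint64_t h = UINT64_C(14695981039346656037);
    for (; *p; ++p) {
      h ^= (uint64_t)(unsigned char)(*p);
      h *= UINT64_C(1099511628211);
    }
    std::snprintf(buf, sizeof buf, "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}

// Distributed bag-of-words paragraph vectors (PV-DBOW) with negative
// sampling. Each document vector is trained to predict the words it
// contains against `negative` noise words drawn from the unigram^0.75
// distribution supplied as a CDF. Single-threaded by design: with a fixed
// seed the returned matrix is bit-identical across runs.
//
// docs:      list of integer vectors of 0-based word ids (may be empty)
// noise_cdf: cumulative distribution over word ids, last element == 1
// [[Rcpp::export]]
NumericMatrix pvdbow_train(List docs, int n_words, int dim, int epochs,
                           double alpha, double min_alpha, int negative,
                           NumericVector noise_cdf, int seed) {
  int n_docs = docs.size();
  uint64_t rng = (uint64_t)seed * UINT64_C(6364136223846793005) + 1442695040888963407ULL;
  // warm up the state so small seeds diverge
  for (int i = 0; i < 8; ++i) xorshift64(rng);

  std::vector<double> D((size_t)n_docs * dim);
  std::vector<double> W((size_t)n_words * dim, 0.0);
  for (size_t i = 0; i < D.size(); ++i)
    D[i] = (runif01(rng) - 0.5) / dim;

  // pre-extract documents
  std::vector<std::vector<int>> dv(n_docs);
  long long total_tokens = 0;
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector w = docs[d];
    dv[d].assign(w.begin(), w.end());
    total_tokens += w.size();
  }
  long long total_steps = (long long)epochs * total_tokens;
  if (total_steps == 0) total_steps = 1;
  long long step = 0;

  std::vector<double> grad(dim);
  const double *cdf = noise_cdf.begin();

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < n_docs; ++d) {
      double *dvec = &D[(size_t)d * dim];
      for (size_t t = 0; t < dv[d].size(); ++t) {
        double lr = alpha - (alpha - min_alpha) * ((double)step / total_steps);
        if (lr < min_alpha) lr = min_alpha;
        ++step;
        int pos = dv[d][t];
        std::fill(grad.begin(), grad.end(), 0.0);
        for (int k = 0; k <= negative; ++k) {
          int target;
          double label;
          if (k == 0) {
            target = pos;
            label = 1.0;
          } else {
            double u = runif01(rng);
            target = (int)(std::lower_bound(cdf, cdf + n_words, u) - cdf);
            if (target >= n_words) target = n_words - 1;
            if (target == pos) continue;
            label = 0.0;
          }
          double *wvec = &W[(size_t)target * dim];
          double f = 0.0;
          for (int j = 0; j < dim; ++j) f += dvec[j] * wvec[j];
          double g = (label - sigmoid(f)) * lr;
          for (int j = 0; j < dim; ++j) {
            grad[j] += g * wvec[j];
            wvec[j] += g * dvec[j];
          }
        }
        for (int j = 0; j < dim; ++j) dvec[j] += grad[j];
      }
    }
  }

  NumericMatrix out(n_docs, dim);
  for (int d = 0; d < n_docs; ++d)
    for (int j = 0; j < dim; ++j)
      out(d, j) = D[(size_t)d * dim + j];
  return out;
}
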