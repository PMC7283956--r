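#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Truncated uniform random walks over a CSR adjacency structure.
// Uses R's RNG so walks are reproducible under set.seed(); `nb` holds the
// 0-based neighbor indices, `ptr` the per-node offsets (length V+1), and
// `roots` the 0-based sequence of walk roots. Returned walks are 1-based
// vocabulary index vectors; a walk stops early at a degree-0 node.
// [[Rcpp::export]]
List cpp_generate_walks(IntegerVector nb, IntegerVector ptr,
                        IntegerVector roots, int walk_length) {
  int n_walks = roots.size();
  List out(n_walks);
  std::vector<int> buf(walk_length);
  for (int w = 0; w < n_walks; ++w) {
    int cur = roots[w];
    int len = 0;
    buf[len++] = cur + 1;
    while (len < walk_length) {
      int deg = ptr[cur + 1] - ptr[cur];
      if (deg == 0) break;
      int pick = (int)(unif_rand() * deg);
      if (pick >= deg) pick = deg - 1;  // guard against unif_rand() == 1.0
      cur = nb[ptr[cur] + pick];
      buf[len++] = cur + 1;
    }
    out[w] = IntegerVector(buf.begin(), buf.begin() + len);
  }
  return out;
}

// Deterministic 64-bit RNG (splitmix64), private to the trainer so that
// training is bit-reproducible regardless of R's RNG state.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double rng_unif(uint64_t &state) {
  return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);  // [0, 1)
}

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram SGD over a walk corpus.
//
// mode 0 = negative sampling (k noise words from unigram^(3/4), given as a
// cumulative distribution), mode 1 = hierarchical softmax (Huffman paths /
// codes flattened with per-word offsets, inner indices 0-based).
// Pairs are visited in deterministic order: epoch, walk, center position,
// context left-to-right within the clipped window. The learning rate
// decays linearly per pair from lr0 to lr_min. syn0 (input vectors) is
// initialized uniformly in [-0.5/d, 0.5/d]; syn1 starts at zero.
// [[Rcpp::export]]
List cpp_train_skipgram(List corpus, int vocab_size, int dim, int window,
                        int epochs, double lr0, double lr_min, int mode,
                        int negative, NumericVector unigram_cdf,
                        IntegerVector hs_path, IntegerVector hs_code,
                        IntegerVector hs_offsets, int seed) {
  int n_walks = corpus.size();
  std::vector<std::vector<int>> walks(n_walks);
  double total_pairs = 0.0;
  for (int w = 0; w < n_walks; ++w) {
    IntegerVector iv = corpus[w];
    walks[w].assign(iv.begin(), iv.end());
    int L = iv.size();
    for (int i = 0; i < L; ++i) {
      int lo = i - window < 0 ? 0 : i - window;
      int hi = i + window >= L ? L - 1 : i + window;
      total_pairs += hi - lo;  // window size minus the center itself
    }
  }
  total_pairs *= epochs;
  if (total_pairs <= 0) stop("corpus contains no training pairs");

  uint64_t rng = (uint64_t)(uint32_t)seed * 0x2545F4914F6CDD1DULL + 0x9E3779B9ULL;
  std::vector<double> syn0_v((size_t)vocab_size * dim);
  for (size_t i = 0; i < syn0_v.size(); ++i)
    syn0_v[i] = (rng_unif(rng) - 0.5) / dim;
  size_t syn1_rows = (mode == 0) ? (size_t)vocab_size
                                 : (size_t)(vocab_size > 1 ? vocab_size - 1 : 1);
  std::vector<double> syn1_v(syn1_rows * dim, 0.0);
  std::vector<double> neu1e_v(dim);
  double *syn0 = syn0_v.data();
  double *syn1 = syn1_v.data();
  double *neu1e = neu1e_v.data();
  const int *hpath = hs_path.begin();
  const int *hcode = hs_code.begin();
  const int *hoff = hs_offsets.begin();

  const double *cdf = unigram_cdf.begin();
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w) {
      const int *walk = walks[w].data();
      int L = (int)walks[w].size();
      for (int i = 0; i < L; ++i) {
        int center = walk[i] - 1;
        double *v = syn0 + (size_t)center * dim;
        int lo = i - window < 0 ? 0 : i - window;
        int hi = i + window >= L ? L - 1 : i + window;
        for (int k = lo; k <= hi; ++k) {
          if (k == i) continue;
          int context = walk[k] - 1;
          double lr = lr0 * (1.0 - processed / total_pairs);
          if (lr < lr_min) lr = lr_min;
          processed += 1.0;
          for (int c = 0; c < dim; ++c) neu1e[c] = 0.0;
          if (mode == 0) {
            for (int s = 0; s < negative + 1; ++s) {
              int target;
              double label;
              if (s == 0) {
                target = context;
                label = 1.0;
              } else {
                double u = rng_unif(rng);
                int lo_i = 0, hi_i = vocab_size - 1;
                while (lo_i < hi_i) {  // first index with cdf >= u
                  int mid = (lo_i + hi_i) / 2;
                  if (cdf[mid] < u) lo_i = mid + 1; else hi_i = mid;
                }
                target = lo_i;
                if (target == context) continue;
                label = 0.0;
              }
              double *u_out = syn1 + (size_t)target * dim;
              double f = 0.0;
              for (int c = 0; c < dim; ++c) f += v[c] * u_out[c];
              double g = (label - sigmoid(f)) * lr;
              for (int c = 0; c < dim; ++c) neu1e[c] += g * u_out[c];
              for (int c = 0; c < dim; ++c) u_out[c] += g * v[c];
            }
          } else {
            int from = hoff[context], to = hoff[context + 1];
            for (int j = from; j < to; ++j) {
              double *wj = syn1 + (size_t)hpath[j] * dim;
              double f = 0.0;
              for (int c = 0; c < dim; ++c) f += v[c] * wj[c];
              double g = (1.0 - hcode[j] - sigmoid(f)) * lr;
              for (int c = 0; c < dim; ++c) neu1e[c] += g * wj[c];
              for (int c = 0; c < dim; ++c) wj[c] += g * v[c];
            }
          }
          for (int c = 0; c < dim; ++c) v[c] += neu1e[c];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix input(vocab_size, dim), context_m((int)syn1_rows, dim);
  for (int r = 0; r < vocab_size; ++r)
    for (int c = 0; c < dim; ++c) input(r, c) = syn0_v[(size_t)r * dim + c];
  for (size_t r = 0; r < syn1_rows; ++r)
    for (int c = 0; c < dim; ++c)
      context_m((int)r, c) = syn1_v[r * dim + c];
  return List::create(_["input"] = input, _["context"] = context_m);
}
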