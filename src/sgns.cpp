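// Skip-gram with negative sampling over k-mer token streams.
// Single-threaded, internally seeded: bitwise-reproducible for a fixed seed.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

// xorshift64* PRNG: deterministic across platforms, independent of R's RNG.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

} // namespace

// [[Rcpp::export(name = ".sgns_train_cpp")]]
List sgns_train_cpp(List sentences, int vocab_size, int dim, int window,
                    int negative, int epochs, double lr0, double noise_exponent,
                    int seed) {
  if (vocab_size <= 0 || dim <= 0 || window <= 0 || negative < 0 || epochs <= 0)
    stop("invalid skip-gram hyperparameters");

  std::vector<std::vector<int>> corpus;
  corpus.reserve(sentences.size());
  long long total_tokens = 0;
  std::vector<double> counts(vocab_size, 0.0);
  for (R_xlen_t i = 0; i < sentences.size(); ++i) {
    IntegerVector s = sentences[i];
    std::vector<int> v(s.begin(), s.end());
    for (int t : v) {
      if (t < 0 || t >= vocab_size) stop("token id out of range");
      counts[t] += 1.0;
    }
    total_tokens += v.size();
    corpus.push_back(std::move(v));
  }
  if (total_tokens == 0) stop("empty corpus");

  // Smoothed-unigram noise table (word2vec-style alias-free table).
  const int table_size = 1 << 20;
  std::vector<int> noise_table(table_size);
  {
    double z = 0.0;
    std::vector<double> pw(vocab_size);
    for (int w = 0; w < vocab_size; ++w) {
      pw[w] = std::pow(counts[w], noise_exponent);
      z += pw[w];
    }
    if (z <= 0) stop("degenerate noise distribution");
    int w = 0;
    double cum = pw[0] / z;
    for (int i = 0; i < table_size; ++i) {
      noise_table[i] = w;
      if ((i + 1.0) / table_size > cum && w < vocab_size - 1) {
        ++w;
        cum += pw[w] / z;
      }
    }
  }

  Rng rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);

  // win: input (center) vectors, wout: output (context) vectors; row-major.
  std::vector<double> win(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> wout(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (auto &x : win) x = (rng.unif() - 0.5) / dim;

  const long long steps_total = static_cast<long long>(epochs) * total_tokens;
  long long steps_done = 0;
  std::vector<double> grad_center(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto &sent : corpus) {
      const int n = static_cast<int>(sent.size());
      for (int t = 0; t < n; ++t) {
        double lr = lr0 * (1.0 - static_cast<double>(steps_done) / steps_total);
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        ++steps_done;
        const int center = sent[t];
        double *vc = &win[static_cast<size_t>(center) * dim];
        for (int off = -window; off <= window; ++off) {
          if (off == 0) continue;
          const int pos = t + off;
          if (pos < 0 || pos >= n) continue;
          std::fill(grad_center.begin(), grad_center.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = sent[pos];
              label = 1.0;
            } else {
              target = noise_table[rng.below(table_size)];
              if (target == sent[pos]) continue;
              label = 0.0;
            }
            double *vo = &wout[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int j = 0; j < dim; ++j) dot += vc[j] * vo[j];
            const double pred = 1.0 / (1.0 + std::exp(-dot));
            const double g = lr * (label - pred);
            for (int j = 0; j < dim; ++j) {
              grad_center[j] += g * vo[j];
              vo[j] += g * vc[j];
            }
          }
          for (int j = 0; j < dim; ++j) vc[j] += grad_center[j];
        }
      }
    }
  }

  NumericMatrix in_mat(vocab_size, dim), out_mat(vocab_size, dim);
  for (int w = 0; w < vocab_size; ++w)
    for (int j = 0; j < dim; ++j) {
      in_mat(w, j) = win[static_cast<size_t>(w) * dim + j];
      out_mat(w, j) = wout[static_cast<size_t>(w) * dim + j];
    }
  return List::create(_["input"] = in_mat, _["output"] = out_mat);
}
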