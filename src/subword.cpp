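// Subword skip-gram embeddings with negative sampling.
//
// Word input vectors are composed as the average of a per-word vector and
// the hashed character n-gram vectors of the word wrapped in boundary
// markers ("<word>"). Because representations are built from character
// n-grams, out-of-vocabulary strings (including typos) still receive
// finite, spelling-informed vectors. Training is plain skip-gram with
// negative sampling over a unigram^(3/4) noise distribution, a linearly
// decaying learning rate, and a private xorshift RNG so results are fully
// reproducible from a single seed on a single worker.

#include <RcppArmadillo.h>
#include <vector>
#include <string>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline uint32_t fnv1a(const std::string& s) {
  uint32_t h = 2166136261u;
  for (unsigned char c : s) {
    h ^= c;
    h *= 16777619u;
  }
  return h;
}

static std::vector<int> word_ngram_ids(const std::string& w, int min_n,
                                       int max_n, int bucket) {
  std::string word = "<" + w + ">";
  std::vector<int> out;
  int L = (int)word.size();
  for (int n = min_n; n <= max_n; ++n) {
    for (int i = 0; i + n <= L; ++i) {
      out.push_back((int)(fnv1a(word.substr(i, n)) % (uint32_t)bucket));
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_subword_hashes(std::string word, int min_n, int max_n,
                                 int bucket) {
  std::vector<int> ids = word_ngram_ids(word, min_n, max_n, bucket);
  return wrap(ids);
}

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static inline double sigmoid1(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// sentences: list of 0-based word-id integer vectors
// [[Rcpp::export]]
List cpp_subword_train(List sentences, CharacterVector vocab,
                       NumericVector counts, int dim, int window, int epochs,
                       double lr0, int negative, int min_n, int max_n,
                       int bucket, int seed) {
  const int V = vocab.size();
  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);

  // precompute subword ids per vocab word
  std::vector<std::vector<int>> grams(V);
  for (int i = 0; i < V; ++i) {
    grams[i] = word_ngram_ids(std::string(vocab[i]), min_n, max_n, bucket);
  }

  // negative-sampling table, unigram^0.75
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    std::vector<double> p(V);
    double tot = 0.0;
    for (int i = 0; i < V; ++i) { p[i] = std::pow(counts[i], 0.75); tot += p[i]; }
    int i = 0;
    double cum = p[0] / tot;
    for (int k = 0; k < table_size; ++k) {
      table[k] = i;
      if ((double)(k + 1) / table_size > cum && i < V - 1) {
        ++i;
        cum += p[i] / tot;
      }
    }
  }

  arma::mat Vw(dim, V), B(dim, bucket), Wout(dim, V, arma::fill::zeros);
  for (auto& x : Vw) x = (rng.unif() - 0.5) / dim;
  for (auto& x : B) x = (rng.unif() - 0.5) / dim;

  // total token count for lr schedule
  double total_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    total_tokens += as<IntegerVector>(sentences[s]).size();
  }
  total_tokens *= epochs;
  double processed = 0;

  arma::vec h(dim), grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      int n = sent.size();
      for (int i = 0; i < n; ++i) {
        processed += 1.0;
        double lr = lr0 * (1.0 - processed / (total_tokens + 1.0));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        int c = sent[i];
        const std::vector<int>& gs = grams[c];
        double denom = 1.0 + gs.size();
        h = Vw.col(c);
        for (int g : gs) h += B.col(g);
        h /= denom;
        int b = 1 + rng.below(window);
        for (int j = i - b; j <= i + b; ++j) {
          if (j < 0 || j >= n || j == i) continue;
          grad.zeros();
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) { target = sent[j]; label = 1.0; }
            else {
              target = table[rng.below(table_size)];
              if (target == sent[j]) continue;
              label = 0.0;
            }
            double score = sigmoid1(arma::dot(h, Wout.col(target)));
            double g2 = (score - label) * lr;
            grad += g2 * Wout.col(target);
            Wout.col(target) -= g2 * h;
          }
          grad /= denom;
          Vw.col(c) -= grad;
          for (int g : gs) B.col(g) -= grad;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["word_vectors"] = Vw.t(), _["ngram_vectors"] = B.t(),
                      _["output_vectors"] = Wout.t());
}
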