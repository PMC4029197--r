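#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// word, doc: 0-based token streams (one entry per token occurrence).
// Randomness comes exclusively from R's RNG (unif_rand), so set.seed() on
// the R side makes runs bit-reproducible.
//
// mode_average = false: the returned assignment is the final Gibbs state
// (a posterior sample). mode_average = true: per-token topic counts are
// accumulated over post-burn-in sweeps and each token gets its argmax
// topic (ties -> smallest topic index).

// [[Rcpp::export]]
IntegerVector gibbs_lda_cpp(const IntegerVector& word,
                            const IntegerVector& doc,
                            int n_docs, int vocab, int k,
                            double alpha, double eta,
                            int iterations, int burn_in,
                            bool mode_average) {
  const int n = word.size();
  IntegerVector z(n);
  std::vector<int> cwt((size_t)k * vocab, 0);  // topic-word counts
  std::vector<int> cdt((size_t)n_docs * k, 0); // doc-topic counts
  std::vector<int> csum(k, 0);                 // tokens per topic
  std::vector<double> p(k);

  for (int i = 0; i < n; ++i) {
    int t = (int)(unif_rand() * k);
    if (t == k) t = k - 1;
    z[i] = t;
    ++cwt[(size_t)t * vocab + word[i]];
    ++cdt[(size_t)doc[i] * k + t];
    ++csum[t];
  }

  std::vector<int> acc;
  if (mode_average) acc.assign((size_t)n * k, 0);

  const double veta = vocab * eta;
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < n; ++i) {
      const int w = word[i], d = doc[i];
      int t = z[i];
      --cwt[(size_t)t * vocab + w];
      --cdt[(size_t)d * k + t];
      --csum[t];
      double tot = 0.0;
      for (int j = 0; j < k; ++j) {
        tot += (cwt[(size_t)j * vocab + w] + eta) / (csum[j] + veta) *
               (cdt[(size_t)d * k + j] + alpha);
        p[j] = tot;
      }
      const double u = unif_rand() * tot;
      t = 0;
      while (t < k - 1 && p[t] < u) ++t;
      z[i] = t;
      ++cwt[(size_t)t * vocab + w];
      ++cdt[(size_t)d * k + t];
      ++csum[t];
    }
    if (mode_average && it >= burn_in)
      for (int i = 0; i < n; ++i) ++acc[(size_t)i * k + z[i]];
  }

  if (mode_average) {
    for (int i = 0; i < n; ++i) {
      int best = 0, bestc = acc[(size_t)i * k];
      for (int j = 1; j < k; ++j) {
        const int c = acc[(size_t)i * k + j];
        if (c > bestc) { best = j; bestc = c; }
      }
      z[i] = best;
    }
  }
  return z;
}
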