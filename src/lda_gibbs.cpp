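#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA. Tokens arrive flattened: word[i] is the
// 0-based vocabulary index of token i, doc[i] its 0-based document index.
// Uses R's RNG (seeded from the R side), so runs are reproducible.
// Returns the final count matrices; the topic-word distribution is formed
// in R as (n_kw + beta) / (n_k + V * beta).
// [[Rcpp::export(name = ".gibbsLda")]]
List gibbsLda(const IntegerVector& word, const IntegerVector& doc,
              int nVocab, int nDocs, int K, double alpha, double beta,
              int nIter) {
  const int nTokens = word.size();
  IntegerMatrix nkw(K, nVocab);   // topic x word counts
  IntegerVector nk(K);            // tokens per topic
  IntegerMatrix ndk(nDocs, K);    // document x topic counts
  IntegerVector z(nTokens);       // current topic assignment

  RNGScope scope;

  for (int i = 0; i < nTokens; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    nkw(k, word[i])++;
    nk[k]++;
    ndk(doc[i], k)++;
  }

  std::vector<double> p(K);
  const double vbeta = nVocab * beta;
  for (int iter = 0; iter < nIter; ++iter) {
    for (int i = 0; i < nTokens; ++i) {
      const int w = word[i], d = doc[i];
      int k = z[i];
      nkw(k, w)--; nk[k]--; ndk(d, k)--;
      double tot = 0.0;
      for (int t = 0; t < K; ++t) {
        p[t] = (ndk(d, t) + alpha) * (nkw(t, w) + beta) / (nk[t] + vbeta);
        tot += p[t];
      }
      double u = unif_rand() * tot;
      double cum = 0.0;
      k = K - 1;
      for (int t = 0; t < K; ++t) {
        cum += p[t];
        if (u <= cum) { k = t; break; }
      }
      z[i] = k;
      nkw(k, w)++; nk[k]++; ndk(d, k)++;
    }
  }

  return List::create(_["nkw"] = nkw, _["nk"] = nk, _["ndk"] = ndk);
}
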