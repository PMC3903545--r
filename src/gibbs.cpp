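// Collapsed Gibbs sampling for LDA, plus held-out inference with fixed
// topic-word counts. A self-contained mt19937 draw keeps runs
// bit-reproducible for a given integer seed.

#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

static inline double unif01(std::mt19937 &rng) {
  // 53-bit uniform in [0, 1); avoids distribution-object portability
  const uint64_t a = rng() >> 5, b = rng() >> 6;
  return (a * 67108864.0 + b) / 9007199254740992.0;
}

// log P(w | z, T): product over topics of Dirichlet-multinomial terms
static double log_p_w_given_z(const std::vector<std::vector<int>> &nkw,
                              const std::vector<int> &nk,
                              int K, int V, double beta) {
  double ll = 0.0;
  const double lgVb = std::lgamma(V * beta);
  const double lgb = std::lgamma(beta);
  for (int k = 0; k < K; ++k) {
    ll += lgVb - V * lgb;
    for (int v = 0; v < V; ++v) ll += std::lgamma(nkw[k][v] + beta);
    ll -= std::lgamma(nk[k] + V * beta);
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_gibbs_lda(List docs, int V, int K, double alpha, double beta,
                   int burnin, int samples, int thin, int seed) {
  const int D = docs.size();
  std::vector<std::vector<int>> w(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d] = std::vector<int>(dv.begin(), dv.end());
  }

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<std::vector<int>> nkw(K, std::vector<int>(V, 0));
  std::vector<int> nk(K, 0);
  std::vector<std::vector<int>> ndk(D, std::vector<int>(K, 0));
  std::vector<std::vector<int>> z(D);

  // random initial assignments
  for (int d = 0; d < D; ++d) {
    const int n = w[d].size();
    z[d].resize(n);
    for (int i = 0; i < n; ++i) {
      int t = static_cast<int>(unif01(rng) * K);
      if (t >= K) t = K - 1;
      z[d][i] = t;
      ++nkw[t][w[d][i]];
      ++nk[t];
      ++ndk[d][t];
    }
  }

  std::vector<double> p(K);
  const int total_iter = burnin + (samples > 0 ? samples * thin : 0);
  std::vector<double> sample_ll;
  sample_ll.reserve(samples > 0 ? samples : 0);

  for (int iter = 1; iter <= total_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      const int n = w[d].size();
      for (int i = 0; i < n; ++i) {
        const int v = w[d][i];
        const int old = z[d][i];
        --nkw[old][v];
        --nk[old];
        --ndk[d][old];
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          tot += (nkw[k][v] + beta) / (nk[k] + V * beta) *
                 (ndk[d][k] + alpha);
          p[k] = tot;
        }
        const double u = unif01(rng) * tot;
        int t = 0;
        while (t < K - 1 && p[t] < u) ++t;
        z[d][i] = t;
        ++nkw[t][v];
        ++nk[t];
        ++ndk[d][t];
      }
    }
    if (samples > 0 && iter > burnin && (iter - burnin) % thin == 0) {
      sample_ll.push_back(log_p_w_given_z(nkw, nk, K, V, beta));
    }
  }

  IntegerMatrix nkw_out(K, V);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) nkw_out(k, v) = nkw[k][v];
  IntegerMatrix ndk_out(D, K);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) ndk_out(d, k) = ndk[d][k];
  List z_out(D);
  for (int d = 0; d < D; ++d) z_out[d] = IntegerVector(z[d].begin(), z[d].end());

  return List::create(
    _["topic_word"] = nkw_out,
    _["topic_totals"] = IntegerVector(nk.begin(), nk.end()),
    _["doc_topic_counts"] = ndk_out,
    _["z"] = z_out,
    _["sample_loglik"] = NumericVector(sample_ll.begin(), sample_ll.end()),
    _["loglik"] = log_p_w_given_z(nkw, nk, K, V, beta));
}

// Held-out inference: sample topic assignments for new documents while
// the training topic-word counts stay fixed.
// [[Rcpp::export]]
IntegerMatrix cpp_infer_heldout(List docs, int V, IntegerMatrix topic_word,
                                IntegerVector topic_totals, double alpha,
                                double beta, int iterations, int seed) {
  const int D = docs.size();
  const int K = topic_word.nrow();
  std::mt19937 rng(static_cast<uint32_t>(seed));

  std::vector<std::vector<int>> w(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d] = std::vector<int>(dv.begin(), dv.end());
  }

  std::vector<std::vector<int>> ndk(D, std::vector<int>(K, 0));
  std::vector<std::vector<int>> z(D);
  std::vector<double> p(K);

  for (int d = 0; d < D; ++d) {
    const int n = w[d].size();
    z[d].resize(n);
    for (int i = 0; i < n; ++i) {
      int t = static_cast<int>(unif01(rng) * K);
      if (t >= K) t = K - 1;
      z[d][i] = t;
      ++ndk[d][t];
    }
  }

  for (int iter = 0; iter < iterations; ++iter) {
    for (int d = 0; d < D; ++d) {
      const int n = w[d].size();
      for (int i = 0; i < n; ++i) {
        const int v = w[d][i];
        const int old = z[d][i];
        --ndk[d][old];
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          tot += (topic_word(k, v) + beta) / (topic_totals[k] + V * beta) *
                 (ndk[d][k] + alpha);
          p[k] = tot;
        }
        const double u = unif01(rng) * tot;
        int t = 0;
        while (t < K - 1 && p[t] < u) ++t;
        z[d][i] = t;
        ++ndk[d][t];
      }
    }
  }

  IntegerMatrix out(D, K);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) out(d, k) = ndk[d][k];
  return out;
}
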