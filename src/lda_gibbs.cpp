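#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// Tokens are passed as parallel 0-based vectors (doc, word). The per-token
// topic indicator is resampled from the collapsed conditional
//   p(z = k) propto (n_dk + alpha_k) * (n_kv + beta_v) / (n_k + sum(beta)),
// counts excluding the current token. After burn_in sweeps, the posterior
// mean estimators of theta and phi are averaged over every retained sweep.
// All randomness goes through R's RNG, so set.seed() on the R side makes
// runs bit-reproducible.

static double collapsed_log_lik(const IntegerMatrix &n_dk,
                                const IntegerMatrix &n_kv,
                                const IntegerVector &n_k,
                                const IntegerVector &n_d,
                                const NumericVector &alpha,
                                const NumericVector &beta,
                                double alpha_sum, double beta_sum,
                                double lg_alpha_sum, double lg_beta_sum,
                                double sum_lg_alpha, double sum_lg_beta) {
  const int D = n_dk.nrow(), K = n_dk.ncol(), V = n_kv.ncol();
  double ll = 0.0;
  for (int d = 0; d < D; ++d) {
    ll += lg_alpha_sum - lgamma(alpha_sum + n_d[d]) - sum_lg_alpha;
    for (int k = 0; k < K; ++k) {
      ll += lgamma(alpha[k] + n_dk(d, k));
    }
  }
  for (int k = 0; k < K; ++k) {
    ll += lg_beta_sum - lgamma(beta_sum + n_k[k]) - sum_lg_beta;
    for (int v = 0; v < V; ++v) {
      ll += lgamma(beta[v] + n_kv(k, v));
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word,
                   int D, int V, int K,
                   NumericVector alpha, NumericVector beta,
                   int n_iter, int burn_in) {
  const int N = doc.size();
  IntegerMatrix n_dk(D, K), n_kv(K, V);
  IntegerVector n_k(K), n_d(D), z(N);

  const double alpha_sum = sum(alpha);
  const double beta_sum = sum(beta);
  const double lg_alpha_sum = lgamma(alpha_sum);
  const double lg_beta_sum = lgamma(beta_sum);
  double sum_lg_alpha = 0.0, sum_lg_beta = 0.0;
  for (int k = 0; k < K; ++k) sum_lg_alpha += lgamma(alpha[k]);
  for (int v = 0; v < V; ++v) sum_lg_beta += lgamma(beta[v]);

  // random initial assignment
  for (int n = 0; n < N; ++n) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[n] = k;
    n_dk(doc[n], k) += 1;
    n_kv(k, word[n]) += 1;
    n_k[k] += 1;
    n_d[doc[n]] += 1;
  }

  NumericMatrix theta_acc(D, K), phi_acc(K, V);
  NumericVector ll_trace(n_iter);
  std::vector<double> p(K);
  int retained = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int n = 0; n < N; ++n) {
      const int d = doc[n], v = word[n], kz = z[n];
      n_dk(d, kz) -= 1;
      n_kv(kz, v) -= 1;
      n_k[kz] -= 1;
      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        total += (n_dk(d, k) + alpha[k]) * (n_kv(k, v) + beta[v]) /
                 (n_k[k] + beta_sum);
        p[k] = total;
      }
      const double u = unif_rand() * total;
      int knew = 0;
      while (knew < K - 1 && p[knew] < u) ++knew;
      z[n] = knew;
      n_dk(d, knew) += 1;
      n_kv(knew, v) += 1;
      n_k[knew] += 1;
    }
    ll_trace[it] = collapsed_log_lik(n_dk, n_kv, n_k, n_d, alpha, beta,
                                     alpha_sum, beta_sum, lg_alpha_sum,
                                     lg_beta_sum, sum_lg_alpha, sum_lg_beta);
    if (it >= burn_in) {
      ++retained;
      for (int d = 0; d < D; ++d) {
        const double denom = n_d[d] + alpha_sum;
        for (int k = 0; k < K; ++k) {
          theta_acc(d, k) += (n_dk(d, k) + alpha[k]) / denom;
        }
      }
      for (int k = 0; k < K; ++k) {
        const double denom = n_k[k] + beta_sum;
        for (int v = 0; v < V; ++v) {
          phi_acc(k, v) += (n_kv(k, v) + beta[v]) / denom;
        }
      }
    }
  }

  if (retained > 0) {
    for (R_xlen_t i = 0; i < theta_acc.size(); ++i) theta_acc[i] /= retained;
    for (R_xlen_t i = 0; i < phi_acc.size(); ++i) phi_acc[i] /= retained;
  }

  return List::create(
    _["theta"] = theta_acc,
    _["phi"] = phi_acc,
    _["z"] = z,
    _["n_dk"] = n_dk,
    _["n_kv"] = n_kv,
    _["n_k"] = n_k,
    _["n_d"] = n_d,
    _["log_lik_trace"] = ll_trace,
    _["retained"] = retained);
}
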