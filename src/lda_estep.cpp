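#include <Rcpp.h>
using namespace Rcpp;

// Batch variational E-step for LDA with point-estimate topic rows.
//
// Counts arrive in compressed-column form over cells: column d of the
// (genes x cells) sparse matrix holds cell d's nonzero gene counts.
// phi is K x V (rows sum to 1). gamma (D x K) holds the Dirichlet
// variational parameters over per-cell topic weights and is warm-started
// between outer EM iterations.
//
// Per cell, (gamma, token responsibilities) are updated by coordinate
// ascent until the mean absolute gamma change falls below
// inner_tol * (1 + total count of the cell).
//
// Returns updated gamma, topic-gene sufficient statistics (K x V) and the
// collapsed token term of the evidence lower bound,
// sum_{d,j} x_dj * log sum_k exp(Elog theta_dk) * phi_kj.
// [[Rcpp::export]]
List lda_estep_cpp(IntegerVector p, IntegerVector idx, NumericVector x,
                   NumericMatrix phi, NumericMatrix gamma,
                   NumericVector alpha, int inner_max, double inner_tol) {
  const int K = phi.nrow();
  const int V = phi.ncol();
  const int D = gamma.nrow();
  NumericMatrix gamma_out(clone(gamma));
  NumericMatrix sstats(K, V);
  double token_ll = 0.0;

  std::vector<double> expE(K), gnew(K), phinorm;
  for (int d = 0; d < D; ++d) {
    const int start = p[d], end = p[d + 1];
    const int nt = end - start;
    if (nt == 0) {
      for (int k = 0; k < K; ++k) gamma_out(d, k) = alpha[k];
      continue;
    }
    phinorm.assign(nt, 0.0);
    double doc_total = 0.0;
    for (int t = 0; t < nt; ++t) doc_total += x[start + t];
    const double thresh = inner_tol * (1.0 + doc_total);

    for (int it = 0; it < inner_max; ++it) {
      double gsum = 0.0;
      for (int k = 0; k < K; ++k) gsum += gamma_out(d, k);
      const double dgsum = R::digamma(gsum);
      for (int k = 0; k < K; ++k)
        expE[k] = std::exp(R::digamma(gamma_out(d, k)) - dgsum);
      // one fused pass over the cell's tokens
      std::fill(gnew.begin(), gnew.end(), 0.0);
      for (int t = 0; t < nt; ++t) {
        const double* pc = &phi(0, idx[start + t]);
        double s = 1e-100;
        for (int k = 0; k < K; ++k) s += expE[k] * pc[k];
        const double w = x[start + t] / s;
        for (int k = 0; k < K; ++k) gnew[k] += w * pc[k];
      }
      double change = 0.0;
      for (int k = 0; k < K; ++k) {
        const double g = alpha[k] + expE[k] * gnew[k];
        change += std::fabs(g - gamma_out(d, k));
        gamma_out(d, k) = g;
      }
      if (change / K < thresh) break;
    }

    // final responsibilities at the converged gamma
    double gsum = 0.0;
    for (int k = 0; k < K; ++k) gsum += gamma_out(d, k);
    const double dgsum = R::digamma(gsum);
    for (int k = 0; k < K; ++k)
      expE[k] = std::exp(R::digamma(gamma_out(d, k)) - dgsum);
    for (int t = 0; t < nt; ++t) {
      const int j = idx[start + t];
      const double* pc = &phi(0, j);
      double* sc = &sstats(0, j);
      double s = 1e-100;
      for (int k = 0; k < K; ++k) s += expE[k] * pc[k];
      token_ll += x[start + t] * std::log(s);
      const double w = x[start + t] / s;
      for (int k = 0; k < K; ++k) sc[k] += expE[k] * pc[k] * w;
    }
  }
  return List::create(_["gamma"] = gamma_out, _["sstats"] = sstats,
                      _["token_ll"] = token_ll);
}
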