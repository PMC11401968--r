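// Bayesian correlation model: z-scored variables, multivariate normal with
// zero means, unit scales, and a free correlation matrix under an LKJ(1)
// prior. Parameters are the unconstrained correlation-Cholesky vector.
// [[Rcpp::depends(RcppArmadillo)]]
#include "dyadhg.h"

class CorrModel : public Model {
 public:
  int K, n, p;
  arma::mat S;  // X'X over complete rows

  CorrModel(const arma::mat& X) : K(X.n_cols), n(X.n_rows), p(K * (K - 1) / 2) {
    S = X.t() * X;
  }

  int dim() const override { return p; }

  double logp_grad(const arma::vec& q, arma::vec& grad) const override {
    grad.zeros(p);
    double lp = 0.0;
    arma::mat L(K, K), Lbar(K, K, arma::fill::zeros);
    std::vector<double> zc(p), wc(p);
    lp += lkj_forward(q.memptr(), K, L, zc.data(), wc.data());
    lp += lkj_lpdf_eta1(K, L, Lbar);
    arma::mat R = L * L.t();
    arma::mat Rinv;
    if (!arma::inv_sympd(Rinv, R)) return -arma::datum::inf;
    double logdet = 2.0 * arma::sum(arma::log(L.diag()));
    lp += -0.5 * n * logdet - 0.5 * arma::trace(Rinv * S) -
          0.5 * n * K * std::log(2.0 * M_PI);
    arma::mat Gbar = -0.5 * n * Rinv + 0.5 * Rinv * S * Rinv;
    arma::mat LbarLik = 2.0 * Gbar * L;
    for (int a = 0; a < K; ++a)
      for (int b = 0; b <= a; ++b) Lbar(a, b) += LbarLik(a, b);
    lkj_reverse(K, L, zc.data(), wc.data(), Lbar, grad.memptr());
    return lp;
  }
};

// [[Rcpp::export(rng = false)]]
Rcpp::List nuts_corr_cpp(const arma::mat& X, const arma::vec& init, int iter,
                         int warmup, int thin, int max_treedepth,
                         double adapt_delta, double seed) {
  CorrModel m(X);
  NutsControl ctrl{iter, warmup, thin, max_treedepth, adapt_delta};
  NutsResult r = run_nuts(m, init, ctrl, (std::uint64_t)seed);
  return Rcpp::List::create(
      Rcpp::Named("draws") = r.draws, Rcpp::Named("divergent") = r.divergent,
      Rcpp::Named("treedepth") = r.treedepth,
      Rcpp::Named("stepsize") = r.stepsize);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List corr_logp_grad_cpp(const arma::vec& q, const arma::mat& X) {
  CorrModel m(X);
  arma::vec g(m.dim());
  double lp = m.logp_grad(q, g);
  return Rcpp::List::create(Rcpp::Named("logp") = lp, Rcpp::Named("grad") = g);
}
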