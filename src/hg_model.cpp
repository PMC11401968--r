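// Dyadic hurdle-gamma path model: two members (parent, youth), each with a
// mediator submodel (lack of coping self-efficacy on the standardized
// exogenous variable) and an outcome submodel (topology outcome on the
// standardized exogenous variable and standardized mediator). Outcomes follow
// a hurdle-gamma law: point mass hu at zero, gamma(shape alpha, mean
// exp(eta)) on positives. Dyad-level random intercepts and slopes for all
// four submodels form one jointly correlated 10-vector (non-centered, LKJ(1)
// correlation prior).
//
// Unconstrained parameter layout (K = 10 random effects):
//   [0..9]    fixed effects: p_med(b0,a), p_out(b0,c,b), y_med(b0,a),
//             y_out(b0,c,b)
//   [10..13]  log shape per submodel (p_med, p_out, y_med, y_out)
//   [14..17]  logit hurdle probability per submodel
//   [18..27]  log random-effect SDs (med_int, med_slope, out_int, out_xslope,
//             out_mslope; parent then youth)
//   [28..72]  correlation-Cholesky unconstrained vector (45)
//   [73..]    innovations z, dyad-major (10 per dyad)
// [[Rcpp::depends(RcppArmadillo)]]
#include "dyadhg.h"

static const int KRE = 10;
static const int NGLOBAL = 73;
static const int NLKJ = 45;

class HGModel : public Model {
 public:
  int n;
  arma::mat Y;      // n x 4 outcomes (p_med, p_out, y_med, y_out)
  arma::mat logY;   // cached log of positive outcomes
  arma::mat ZX;     // n x 2 standardized exogenous (parent, youth)
  arma::mat ZM;     // n x 2 standardized mediator (parent, youth)
  arma::mat P; // 4 x 28, one column per parameter: 10 beta, 4 shape, 4 hu,
               // 10 sd; rows (type, a, b, c)

  HGModel(const arma::mat& Y_, const arma::mat& ZX_, const arma::mat& ZM_,
          const arma::mat& priors_)
      : n(Y_.n_rows), Y(Y_), ZX(ZX_), ZM(ZM_), P(priors_.t()) {
    logY = Y;
    for (arma::uword i = 0; i < Y.n_elem; ++i)
      logY[i] = (Y[i] > 0) ? std::log(Y[i]) : 0.0;
  }

  int dim() const override { return NGLOBAL + KRE * n; }

  double logp_grad(const arma::vec& q, arma::vec& grad) const override {
    grad.zeros(dim());
    double lp = 0.0;
    const double* beta = q.memptr();
    double alpha[4], hu[4], logalpha[4], dgam[4], lgam[4], sd[KRE];
    for (int s = 0; s < 4; ++s) {
      logalpha[s] = q[10 + s];
      alpha[s] = std::exp(logalpha[s]);
      hu[s] = 1.0 / (1.0 + std::exp(-q[14 + s]));
      dgam[s] = R::digamma(alpha[s]);
      lgam[s] = std::lgamma(alpha[s]);
    }
    for (int k = 0; k < KRE; ++k) sd[k] = std::exp(q[18 + k]);

    // correlation Cholesky
    arma::mat L(KRE, KRE), Lbar(KRE, KRE, arma::fill::zeros);
    double zc[NLKJ], wc[NLKJ];
    lp += lkj_forward(q.memptr() + 28, KRE, L, zc, wc);
    lp += lkj_lpdf_eta1(KRE, L, Lbar);

    // priors
    for (int j = 0; j < 10; ++j)
      grad[j] += prior_loc(P.colptr(j), beta[j], lp);
    for (int s = 0; s < 4; ++s)
      grad[10 + s] += prior_pos(P.colptr(10 + s), q[10 + s], lp);
    for (int s = 0; s < 4; ++s)
      grad[14 + s] += prior_loc(P.colptr(14 + s), q[14 + s], lp);
    for (int k = 0; k < KRE; ++k)
      grad[18 + k] += prior_pos(P.colptr(18 + k), q[18 + k], lp);

    const double LOG2PI = std::log(2.0 * M_PI);
    double v[KRE], u[KRE], ubar[KRE];
    for (int d = 0; d < n; ++d) {
      const double* z = q.memptr() + NGLOBAL + d * KRE;
      double* zg = grad.memptr() + NGLOBAL + d * KRE;
      for (int k = 0; k < KRE; ++k) {
        double acc = 0.0;
        for (int j = 0; j <= k; ++j) acc += L(k, j) * z[j];
        v[k] = acc;
        u[k] = sd[k] * acc;
        ubar[k] = 0.0;
        lp += -0.5 * z[k] * z[k] - 0.5 * LOG2PI;
        zg[k] += -z[k];
      }
      for (int m = 0; m < 2; ++m) {
        int bo = m * 5;      // fixed-effect offset
        int ro = m * 5;      // random-effect offset
        int sm = 2 * m;      // mediator submodel index
        int so = 2 * m + 1;  // outcome submodel index
        double zx = ZX(d, m), zm = ZM(d, m);
        // mediator submodel
        {
          double eta = beta[bo] + (beta[bo + 1] + u[ro + 1]) * zx + u[ro];
          double y = Y(d, sm);
          double ge = 0.0;
          if (y <= 0.0) {
            lp += std::log(hu[sm]);
            grad[14 + sm] += 1.0 - hu[sm];
          } else {
            double r = y * std::exp(-eta);
            double ly = logY(d, sm);
            lp += std::log1p(-hu[sm]) + alpha[sm] * (logalpha[sm] - eta) -
                  lgam[sm] + (alpha[sm] - 1.0) * ly - alpha[sm] * r;
            grad[14 + sm] += -hu[sm];
            ge = alpha[sm] * (r - 1.0);
            grad[10 + sm] += alpha[sm] * (logalpha[sm] + 1.0 - eta - dgam[sm] +
                                          ly - r);
          }
          grad[bo] += ge;
          grad[bo + 1] += ge * zx;
          ubar[ro] += ge;
          ubar[ro + 1] += ge * zx;
        }
        // outcome submodel
        {
          double eta = beta[bo + 2] + (beta[bo + 3] + u[ro + 3]) * zx +
                       (beta[bo + 4] + u[ro + 4]) * zm + u[ro + 2];
          double y = Y(d, so);
          double ge = 0.0;
          if (y <= 0.0) {
            lp += std::log(hu[so]);
            grad[14 + so] += 1.0 - hu[so];
          } else {
            double r = y * std::exp(-eta);
            double ly = logY(d, so);
            lp += std::log1p(-hu[so]) + alpha[so] * (logalpha[so] - eta) -
                  lgam[so] + (alpha[so] - 1.0) * ly - alpha[so] * r;
            grad[14 + so] += -hu[so];
            ge = alpha[so] * (r - 1.0);
            grad[10 + so] += alpha[so] * (logalpha[so] + 1.0 - eta - dgam[so] +
                                          ly - r);
          }
          grad[bo + 2] += ge;
          grad[bo + 3] += ge * zx;
          grad[bo + 4] += ge * zm;
          ubar[ro + 2] += ge;
          ubar[ro + 3] += ge * zx;
          ubar[ro + 4] += ge * zm;
        }
      }
      // backprop u = sd .* (L z)
      for (int k = 0; k < KRE; ++k) {
        double vb = sd[k] * ubar[k];
        grad[18 + k] += ubar[k] * u[k];
        for (int j = 0; j <= k; ++j) {
          zg[j] += L(k, j) * vb;
          Lbar(k, j) += vb * z[j];
        }
      }
    }
    lkj_reverse(KRE, L, zc, wc, Lbar, grad.memptr() + 28);
    return lp;
  }
};

static HGModel make_hg(const Rcpp::List& dat, const arma::mat& priors) {
  arma::mat Y = dat["Y"], ZX = dat["ZX"], ZM = dat["ZM"];
  return HGModel(Y, ZX, ZM, priors);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List hg_logp_grad_cpp(const arma::vec& q, const Rcpp::List& dat,
                            const arma::mat& priors) {
  HGModel m = make_hg(dat, priors);
  arma::vec g(m.dim());
  double lp = m.logp_grad(q, g);
  return Rcpp::List::create(Rcpp::Named("logp") = lp, Rcpp::Named("grad") = g);
}

// [[Rcpp::export(rng = false)]]
arma::vec hg_logp_mat_cpp(const arma::mat& Q, const Rcpp::List& dat,
                          const arma::mat& priors) {
  HGModel m = make_hg(dat, priors);
  arma::vec out(Q.n_rows);
  arma::vec g(m.dim());
  for (arma::uword i = 0; i < Q.n_rows; ++i)
    out[i] = m.logp_grad(Q.row(i).t(), g);
  return out;
}

// [[Rcpp::export(rng = false)]]
Rcpp::List nuts_hg_cpp(const Rcpp::List& dat, const arma::mat& priors,
                       const arma::vec& init, int iter, int warmup, int thin,
                       int max_treedepth, double adapt_delta, double seed) {
  HGModel m = make_hg(dat, priors);
  NutsControl ctrl{iter, warmup, thin, max_treedepth, adapt_delta};
  NutsResult r = run_nuts(m, init, ctrl, (std::uint64_t)seed);
  return Rcpp::List::create(
      Rcpp::Named("draws") = r.draws, Rcpp::Named("divergent") = r.divergent,
      Rcpp::Named("treedepth") = r.treedepth,
      Rcpp::Named("stepsize") = r.stepsize,
      Rcpp::Named("inv_metric") = r.inv_metric);
}

// Reconstruct correlation-matrix entries from unconstrained LKJ draws.
// Returns draws x (K*(K-1)/2) matrix of lower-triangle correlations,
// row-wise (2,1), (3,1), (3,2), ...
// [[Rcpp::export(rng = false)]]
arma::mat lkj_corrs_cpp(const arma::mat& Ylkj, int K) {
  int p = K * (K - 1) / 2;
  arma::mat out(Ylkj.n_rows, p);
  arma::mat L(K, K);
  std::vector<double> zc(p), wc(p);
  for (arma::uword i = 0; i < Ylkj.n_rows; ++i) {
    arma::vec y = Ylkj.row(i).t();
    lkj_forward(y.memptr(), K, L, zc.data(), wc.data());
    arma::mat R = L * L.t();
    int idx = 0;
    for (int a = 1; a < K; ++a)
      for (int b = 0; b < a; ++b, ++idx) out(i, idx) = R(a, b);
  }
  return out;
}
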