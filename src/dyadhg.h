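#ifndef DYADHG_H
#define DYADHG_H

#include <RcppArmadillo.h>
#include <random>

// Abstract target density: log posterior kernel and its gradient on the
// unconstrained scale. Implementations must be thread-safe const.
struct Model {
  virtual int dim() const = 0;
  virtual double logp_grad(const arma::vec& q, arma::vec& grad) const = 0;
  virtual ~Model() = default;
};

struct NutsControl {
  int iter;           // total iterations per chain (incl. warmup)
  int warmup;         // warmup iterations
  int thin;           // keep every thin-th post-warmup draw
  int max_treedepth;  // cap on doubling depth
  double adapt_delta; // dual-averaging target acceptance
};

struct NutsResult {
  arma::mat draws;        // kept x dim, unconstrained
  arma::ivec divergent;   // per post-warmup iteration (before thinning)
  arma::ivec treedepth;   // per post-warmup iteration
  double stepsize;        // final adapted step size
  arma::vec inv_metric;   // final diagonal inverse metric
};

NutsResult run_nuts(const Model& m, const arma::vec& init,
                    const NutsControl& ctrl, std::uint64_t seed);

// ---- correlation-Cholesky transform (unconstrained y -> lower L) ----
// y has length K*(K-1)/2 ordered row-wise (i = 1..K-1, j = 0..i-1).
// Returns log|Jacobian| of the map; caches tanh values and row scales.
inline double lkj_forward(const double* y, int K, arma::mat& L,
                          double* zc, double* wc) {
  L.zeros();
  L(0, 0) = 1.0;
  double logj = 0.0;
  int idx = 0;
  for (int i = 1; i < K; ++i) {
    double s = 0.0;
    for (int j = 0; j < i; ++j, ++idx) {
      double z = std::tanh(y[idx]);
      if (z > 1.0 - 1e-12) z = 1.0 - 1e-12;
      if (z < -1.0 + 1e-12) z = -1.0 + 1e-12;
      double w = std::sqrt(std::max(1.0 - s, 1e-16));
      L(i, j) = z * w;
      s += L(i, j) * L(i, j);
      zc[idx] = z;
      wc[idx] = w;
      logj += std::log1p(-z * z) + std::log(w);
    }
    L(i, i) = std::sqrt(std::max(1.0 - s, 1e-16));
  }
  return logj;
}

// Reverse pass: Lbar holds adjoints of L from the likelihood and the LKJ
// prior (the Jacobian term's own adjoints are added here); accumulates into
// ybar (length K*(K-1)/2).
inline void lkj_reverse(int K, const arma::mat& L, const double* zc,
                        const double* wc, const arma::mat& Lbar, double* ybar) {
  for (int i = K - 1; i >= 1; --i) {
    int rowstart = i * (i - 1) / 2;
    double as = Lbar(i, i) * (-0.5 / L(i, i));
    for (int j = i - 1; j >= 0; --j) {
      int idx = rowstart + j;
      double z = zc[idx], w = wc[idx];
      double g = Lbar(i, j) + as * 2.0 * L(i, j);
      double zbar = g * w - 2.0 * z / (1.0 - z * z);
      double wbar = g * z + 1.0 / w;
      as += wbar * (-0.5 / w);
      ybar[idx] += zbar * (1.0 - z * z);
    }
  }
}

// LKJ(eta = 1) log density on the Cholesky factor, up to the normalizing
// constant (constant is shared by models with equal K, so Bayes factors are
// unaffected); adds diagonal adjoints.
inline double lkj_lpdf_eta1(int K, const arma::mat& L, arma::mat& Lbar) {
  double lp = 0.0;
  for (int i = 1; i < K; ++i) {
    lp += (K - 1 - i) * std::log(L(i, i));
    Lbar(i, i) += (K - 1 - i) / L(i, i);
  }
  return lp;
}

// ---- prior helpers ----
// Location prior on an unbounded parameter.
// row = (type, a, b, c): type 0 normal(mu=a, sd=b); type 1 student_t(nu=a,
// mu=b, sigma=c). Adds the full log density to lp, returns d lp / d x.
inline double prior_loc(const double* pr, double x, double& lp) {
  if (pr[0] == 0.0) {
    double mu = pr[1], s = pr[2];
    double zv = (x - mu) / s;
    lp += -0.5 * zv * zv - std::log(s) - 0.5 * std::log(2.0 * M_PI);
    return -zv / s;
  }
  double nu = pr[1], mu = pr[2], s = pr[3];
  double t = (x - mu) / s;
  lp += std::lgamma(0.5 * (nu + 1.0)) - std::lgamma(0.5 * nu) -
        0.5 * std::log(nu * M_PI) - std::log(s) -
        0.5 * (nu + 1.0) * std::log1p(t * t / nu);
  return -(nu + 1.0) * t / (s * (nu + t * t));
}

// Prior on a positive parameter v sampled as u = log v. type 2 is
// gamma(shape=a, rate=b); types 0/1 are half-normal / half-student-t.
// Adds log density + log Jacobian; returns d lp / d u.
inline double prior_pos(const double* pr, double u, double& lp) {
  double v = std::exp(u);
  if (pr[0] == 2.0) {
    double a = pr[1], b = pr[2];
    lp += a * std::log(b) - std::lgamma(a) + (a - 1.0) * u - b * v + u;
    return a - b * v;
  }
  double g = prior_loc(pr, v, lp);
  lp += M_LN2 + u;  // half-distribution doubling + Jacobian
  return g * v + 1.0;
}

#endif
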