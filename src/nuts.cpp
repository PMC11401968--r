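// Multinomial No-U-Turn sampler with dual-averaging step-size adaptation and
// windowed diagonal metric estimation (Stan-style warmup schedule).
#include "dyadhg.h"

namespace {

struct Phase {
  arma::vec q, p, g;
  double logp;
};

struct Sampler {
  const Model& m;
  std::mt19937_64 rng;
  std::normal_distribution<double> ndist;
  std::uniform_real_distribution<double> udist;
  arma::vec inv_metric;
  double eps;
  int max_depth;
  // per-iteration tallies
  double sum_acc;
  int n_leapfrog;
  bool divergent;

  Sampler(const Model& mod, std::uint64_t seed)
      : m(mod), rng(seed), ndist(0.0, 1.0), udist(0.0, 1.0),
        inv_metric(mod.dim(), arma::fill::ones), eps(0.1), max_depth(10),
        sum_acc(0), n_leapfrog(0), divergent(false) {}

  double runif() { return udist(rng); }
  double rnorm() { return ndist(rng); }

  double hamiltonian(const Phase& z) const {
    double kin = 0.5 * arma::dot(arma::square(z.p), inv_metric);
    double h = -z.logp + kin;
    return std::isfinite(h) ? h : 1e100;
  }

  void leapfrog(Phase& z, double e) {
    z.p += 0.5 * e * z.g;
    z.q += e * (inv_metric % z.p);
    z.logp = m.logp_grad(z.q, z.g);
    if (!z.g.is_finite()) z.g.zeros();
    z.p += 0.5 * e * z.g;
  }

  void sample_momentum(Phase& z) {
    for (arma::uword k = 0; k < z.p.n_elem; ++k)
      z.p[k] = rnorm() / std::sqrt(inv_metric[k]);
  }

  bool uturn(const Phase& zl, const Phase& zr) const {
    arma::vec dq = zr.q - zl.q;
    return arma::dot(dq, inv_metric % zl.p) < 0 ||
           arma::dot(dq, inv_metric % zr.p) < 0;
  }

  struct Tree {
    Phase zleft, zright;  // endpoints in trajectory time
    arma::vec q_prop;
    double log_w;
    bool bad;  // divergent or internal u-turn
  };

  // Builds a subtree of 2^depth leapfrog steps starting from z in direction
  // dir; z is advanced to the far end on return.
  void build_tree(int depth, int dir, double H0, Phase& z, Tree& t) {
    if (depth == 0) {
      leapfrog(z, dir * eps);
      double H = hamiltonian(z);
      ++n_leapfrog;
      double lw = H0 - H;
      sum_acc += std::min(1.0, std::exp(lw));
      t.log_w = lw;
      t.bad = (H - H0) > 1000.0;
      if (t.bad) divergent = true;
      t.zleft = z;
      t.zright = z;
      t.q_prop = z.q;
      return;
    }
    Tree t1, t2;
    build_tree(depth - 1, dir, H0, z, t1);
    if (t1.bad) {
      t = std::move(t1);
      return;
    }
    build_tree(depth - 1, dir, H0, z, t2);
    t.bad = t2.bad;
    if (dir == 1) {
      t.zleft = t1.zleft;
      t.zright = t2.zright;
    } else {
      t.zleft = t2.zleft;
      t.zright = t1.zright;
    }
    if (!t.bad && uturn(t.zleft, t.zright)) t.bad = true;
    double lw = std::max(t1.log_w, t2.log_w) +
                std::log(std::exp(t1.log_w - std::max(t1.log_w, t2.log_w)) +
                         std::exp(t2.log_w - std::max(t1.log_w, t2.log_w)));
    t.log_w = lw;
    // multinomial within-subtree sampling
    if (std::log(runif()) < t2.log_w - lw)
      t.q_prop = std::move(t2.q_prop);
    else
      t.q_prop = std::move(t1.q_prop);
  }

  // One NUTS transition from q (logp/grad supplied); returns treedepth used.
  int transition(arma::vec& q, double& logp, arma::vec& grad) {
    Phase z;
    z.q = q;
    z.g = grad;
    z.logp = logp;
    z.p.set_size(q.n_elem);
    sample_momentum(z);
    double H0 = hamiltonian(z);
    Phase zleft = z, zright = z;
    arma::vec q_sample = q;
    double log_w = 0.0;
    sum_acc = 0.0;
    n_leapfrog = 0;
    divergent = false;
    int depth = 0;
    for (; depth < max_depth; ++depth) {
      int dir = (runif() < 0.5) ? -1 : 1;
      Phase zstart = (dir == 1) ? zright : zleft;
      Tree sub;
      build_tree(depth, dir, H0, zstart, sub);
      if (sub.bad) break;
      // biased progressive sampling toward the new subtree
      if (std::log(runif()) < sub.log_w - log_w) q_sample = sub.q_prop;
      double mx = std::max(log_w, sub.log_w);
      log_w = mx + std::log(std::exp(log_w - mx) + std::exp(sub.log_w - mx));
      if (dir == 1)
        zright = sub.zright;
      else
        zleft = sub.zleft;
      if (uturn(zleft, zright)) {
        ++depth;
        break;
      }
    }
    q = q_sample;
    logp = m.logp_grad(q, grad);
    return depth;
  }

  double init_stepsize(const arma::vec& q0) {
    Phase z;
    z.q = q0;
    z.g.set_size(q0.n_elem);
    z.p.set_size(q0.n_elem);
    z.logp = m.logp_grad(z.q, z.g);
    sample_momentum(z);
    double H0 = hamiltonian(z);
    double e = 1.0;
    Phase zt = z;
    leapfrog(zt, e);
    double dH = H0 - hamiltonian(zt);
    int dir = (dH > std::log(0.8)) ? 1 : -1;
    for (int it = 0; it < 100; ++it) {
      zt = z;
      leapfrog(zt, e);
      dH = H0 - hamiltonian(zt);
      if (dir == 1 && !(dH > std::log(0.8))) break;
      if (dir == -1 && !(dH < std::log(0.8))) break;
      e = (dir == 1) ? 2.0 * e : 0.5 * e;
      if (e > 1e7 || e < 1e-10) break;
    }
    return e;
  }
};

struct Welford {
  arma::vec mean, m2;
  double n = 0;
  void reset(int d) {
    mean.zeros(d);
    m2.zeros(d);
    n = 0;
  }
  void add(const arma::vec& x) {
    n += 1;
    arma::vec d = x - mean;
    mean += d / n;
    m2 += d % (x - mean);
  }
  arma::vec var() const { return m2 / std::max(n - 1.0, 1.0); }
};

}  // namespace

NutsResult run_nuts(const Model& m, const arma::vec& init,
                    const NutsControl& ctrl, std::uint64_t seed) {
  Sampler s(m, seed);
  s.max_depth = ctrl.max_treedepth;
  const int dim = m.dim();
  arma::vec q = init, grad(dim);
  double logp = m.logp_grad(q, grad);
  if (!std::isfinite(logp))
    Rcpp::stop("log density is not finite at the initial values");

  // warmup windows for metric estimation
  int wu = ctrl.warmup;
  int init_buf = 75, term_buf = 50, base_win = 25;
  bool adapt_metric = wu >= 40;
  if (wu < 150 && adapt_metric) {
    init_buf = std::max(1, (int)std::round(0.15 * wu));
    term_buf = std::max(1, (int)std::round(0.10 * wu));
    base_win = wu - init_buf - term_buf;
  }
  int win_start = init_buf, win_size = base_win;
  int win_end = adapt_metric ? std::min(win_start + win_size, wu - term_buf)
                             : wu + 1;

  // dual averaging
  s.eps = s.init_stepsize(q);
  double mu = std::log(10.0 * s.eps), log_eps_bar = 0.0, h_bar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;
  Welford wf;
  wf.reset(dim);

  int n_post = ctrl.iter - ctrl.warmup;
  int n_keep = n_post / ctrl.thin;
  NutsResult res;
  res.draws.set_size(n_keep, dim);
  res.divergent.zeros(n_post);
  res.treedepth.zeros(n_post);

  int kept = 0;
  for (int it = 0; it < ctrl.iter; ++it) {
    if (it % 100 == 0) Rcpp::checkUserInterrupt();
    int depth = s.transition(q, logp, grad);
    bool warm = it < wu;
    if (warm) {
      // dual averaging step
      double astat =
          (s.n_leapfrog > 0) ? s.sum_acc / s.n_leapfrog : 0.0;
      da_count += 1;
      double frac = 1.0 / (da_count + t0);
      h_bar = (1.0 - frac) * h_bar + frac * (ctrl.adapt_delta - astat);
      double log_eps = mu - std::sqrt((double)da_count) / gamma * h_bar;
      double eta = std::pow((double)da_count, -kappa);
      log_eps_bar = eta * log_eps + (1.0 - eta) * log_eps_bar;
      s.eps = std::exp(log_eps);
      if (adapt_metric && it >= win_start && it < win_end) wf.add(q);
      if (adapt_metric && it == win_end - 1 && win_end <= wu - term_buf) {
        arma::vec v = wf.var();
        double nn = wf.n;
        s.inv_metric = v * (nn / (nn + 5.0)) + 1e-3 * (5.0 / (nn + 5.0));
        wf.reset(dim);
        win_start = win_end;
        win_size *= 2;
        win_end = win_start + win_size;
        if (win_end + 2 * win_size > wu - term_buf) win_end = wu - term_buf;
        win_end = std::min(win_end, wu - term_buf);
        // restart step-size adaptation around a fresh estimate
        s.eps = s.init_stepsize(q);
        mu = std::log(10.0 * s.eps);
        log_eps_bar = 0.0;
        h_bar = 0.0;
        da_count = 0;
        logp = m.logp_grad(q, grad);
      }
      if (it == wu - 1) s.eps = std::exp(log_eps_bar);
    } else {
      int pit = it - wu;
      res.divergent[pit] = s.divergent ? 1 : 0;
      res.treedepth[pit] = depth;
      if ((pit + 1) % ctrl.thin == 0 && kept < n_keep) {
        res.draws.row(kept) = q.t();
        ++kept;
      }
    }
  }
  res.stepsize = s.eps;
  res.inv_metric = s.inv_metric;
  return res;
}
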