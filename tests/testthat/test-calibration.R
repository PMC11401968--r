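# Simulation-based calibration smoke test: draw the full parameter vector
# from a concentrated prior (sampled with a long prior-only chain, so the
# LKJ-distributed correlation matrix is drawn from the model's own prior),
# generate a dataset from it, refit with the same priors, and record the rank
# of the true mediator-path coefficient among the posterior draws. Under a
# correct sampler the ranks are uniform; the smoke gate only rejects gross
# miscalibration (any quartile bin holding more than half the cycles).

sbc_priors <- function(spec) {
  ps <- build_prior_set(spec, "weak")
  for (nm in grep("^b_", names(ps), value = TRUE))
    ps <- set_prior(ps, nm, prior_normal(0.2, 0.15))
  for (nm in grep("^shape_", names(ps), value = TRUE))
    ps <- set_prior(ps, nm, prior_gamma(40, 20))    # shapes near 2
  for (nm in grep("^hu_", names(ps), value = TRUE))
    ps <- set_prior(ps, nm, prior_normal(-2.2, 0.3))  # hurdle near 0.1
  for (nm in grep("^sd_", names(ps), value = TRUE))
    ps <- set_prior(ps, nm, prior_gamma(16, 80))    # SDs near 0.2
  ps
}

sbc_generate <- function(g, n, zx_p, zx_y, seed) {
  set.seed(seed)
  L <- dyadhg:::.lkj_chol(g$y_lkj)
  z <- matrix(rnorm(n * 10), n, 10)
  u <- (z %*% t(L)) %*% diag(g$re_sd)
  b <- g$beta
  mk <- function(m, zx) {
    o <- (m - 1) * 5
    med <- rhgamma(n, exp(b[o + 1] + (b[o + 2] + u[, o + 2]) * zx +
                            u[, o + 1]), g$shape[2 * m - 1], g$hu[2 * m - 1])
    zm <- as.numeric(scale(med))
    out <- rhgamma(n, exp(b[o + 3] + (b[o + 4] + u[, o + 4]) * zx +
                            (b[o + 5] + u[, o + 5]) * zm + u[, o + 3]),
                   g$shape[2 * m], g$hu[2 * m])
    list(med = med, out = out)
  }
  p <- mk(1, zx_p); y <- mk(2, zx_y)
  data.frame(dyad_id = seq_len(n),
             p_ptss = zx_p, p_lack_cse = p$med, p_ccope_rev = p$out,
             y_ptss = zx_y, y_lack_cse = y$med, y_ccope_rev = y$out)
}

test_that("posterior ranks show no gross miscalibration over prior draws", {
  spec <- dyad_model_spec("distress")
  ps <- sbc_priors(spec)
  empty <- generate_dyads(dyad_config(n_dyads = 0))
  prior_fit <- fit_dyad_model(empty, "distress", priors = ps,
                              mcmc = mcmc_config(chains = 2, iter = 1600,
                                                 warmup = 300, seed = 41))
  prior_q <- do.call(rbind, prior_fit$draws)
  n_cycles <- 20
  idx <- round(seq(50, nrow(prior_q) - 10, length.out = n_cycles))
  n <- 30
  set.seed(42)
  zx_p <- as.numeric(scale(rnorm(n))); zx_y <- as.numeric(scale(rnorm(n)))
  ranks <- integer(n_cycles)
  for (i in seq_len(n_cycles)) {
    g <- dyadhg:::.unpack_global(prior_q[idx[i], ], spec)
    d <- sbc_generate(g, n, zx_p, zx_y, seed = 1000 + i)
    f <- fit_dyad_model(d, "distress", priors = ps,
                        mcmc = mcmc_config(chains = 2, iter = 500,
                                           warmup = 250, seed = 50 + i))
    post <- posterior_draws(f, pars = "b_p_lack_cse_ptss")[, 1]
    # thin to ~independent draws before ranking
    post <- post[seq(1, length(post), by = 5)]
    ranks[i] <- sum(post < g$beta[2])
  }
  bins <- cut(ranks / (length(post) + 1), breaks = seq(0, 1, 0.25),
              include.lowest = TRUE)
  expect_lte(max(table(bins)), n_cycles / 2)
  # ranks span the range rather than piling at the ends
  expect_gt(length(unique(bins)), 1)
})
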