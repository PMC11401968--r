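test_that("mediation products multiply the path draws elementwise", {
  f <- quick_fit(tiny_dyads(30, seed = 3), seed = 7)
  mp <- mediation_product(f, "parent")
  # independent reconstruction straight from the raw unconstrained draws:
  # beta columns 2 (mediator path in) and 5 (mediator path out)
  raw <- do.call(rbind, f$draws)
  expect_equal(mp$product_draws, raw[, 2] * raw[, 5])
  my <- mediation_product(f, "youth")
  expect_equal(my$product_draws, raw[, 7] * raw[, 10])
})

test_that("constant and annihilating draws give degenerate products", {
  q <- rep(0, 73)
  q[2] <- 0.25; q[5] <- 0.12
  f <- fake_fit(q)
  expect_true(all(mediation_product(f, "parent")$product_draws == 0.03))
  q[2] <- 0
  expect_true(all(mediation_product(fake_fit(q), "parent")$product_draws
                  == 0))
})

test_that("exceedance curves count strict exceedances and are monotone", {
  ms <- structure(list(product_draws = c(0.01, 0.02, 0.03, 0.04),
                       member = "parent"), class = "mediation_summary")
  expect_equal(exceedance_curve(ms, 0.025)$probability, 0.5)
  expect_equal(exceedance_curve(ms, 0.0)$probability, 1)
  expect_equal(exceedance_curve(ms, 1)$probability, 0)
  expect_equal(exceedance_curve(ms, c(-Inf, Inf))$probability, c(1, 0))
  expect_error(exceedance_curve(ms, c(0.02, 0.01)), "sorted")
  # monotone nonincreasing on real draws
  f <- quick_fit(tiny_dyads(30, seed = 3), seed = 7)
  curve <- exceedance_curve(mediation_product(f, "youth"),
                            seq(-0.2, 0.2, by = 0.01))
  expect_true(all(diff(curve$probability) <= 0))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
})

test_that("member differences report probability and evidence ratio", {
  # symmetric members: identical draws -> p = 0.5, evidence ratio 1
  q <- rep(0, 73)
  q[c(2, 5)] <- c(0.3, 0.2)
  q[c(7, 10)] <- c(0.3, 0.2)
  md <- member_difference(fake_fit(q))
  expect_equal(md$prob_positive, 0.5)
  expect_equal(md$evidence_ratio, 1)
  # p = .96 implies an evidence ratio of 24 (the published 25.03 pattern
  # arises from rounding p)
  p <- 0.96
  expect_equal(p / (1 - p), 24, tolerance = 1e-12)
  # monotone in p
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(ps / (1 - ps)) > 0))
  # directional case from a real fit
  f <- quick_fit(tiny_dyads(30, seed = 3), seed = 7)
  md2 <- member_difference(f)
  expect_equal(md2$evidence_ratio,
               md2$prob_positive / (1 - md2$prob_positive))
  expect_equal(mean(md2$draws > 0), md2$prob_positive)
})

test_that("bayes factors follow the threshold-3 decision rule exactly", {
  b1 <- bayes_factor(-10, -10)
  expect_equal(b1$bf, 1)
  expect_equal(b1$decision, "inconclusive")
  b2 <- bayes_factor(-5, -5 - log(20))
  expect_equal(b2$bf, 20)
  expect_match(b2$decision, "favors model A")
  b3 <- bayes_factor(-5 - log(20), -5)
  expect_match(b3$decision, "favors model B")
  # reciprocity: BF(A,B) * BF(B,A) = 1
  expect_equal(b2$bf * b3$bf, 1)
  # the decision boundary sits at 3
  expect_match(bayes_factor(log(3.01), 0)$decision, "favors")
  expect_equal(bayes_factor(log(2.99), 0)$decision, "inconclusive")
})

test_that("bridge sampling reproduces the conjugate normal evidence", {
  toy <- conjugate_toy(seed = 11)
  set.seed(21)
  est <- log_marginal_likelihood(toy$draws, toy$log_density)
  expect_lt(abs(est$lml - toy$lml), 3 * max(est$mc_error, 1e-4))
  # self-consistency across proposal seeds
  set.seed(99)
  est2 <- log_marginal_likelihood(toy$draws, toy$log_density)
  expect_lt(abs(est$lml - est2$lml),
            4 * max(est$mc_error + est2$mc_error, 1e-4))
})

test_that("a point-mass parameter reduces the evidence to the likelihood", {
  ll <- -12.34
  est <- log_marginal_likelihood(matrix(numeric(0), 10, 0),
                                 function(x) rep(ll, nrow(x)))
  expect_equal(est$lml, ll)
  expect_equal(est$mc_error, 0)
})

test_that("bridge equals importance sampling under a (near) perfect proposal", {
  toy <- conjugate_toy(seed = 13, n_draws = 8000)
  set.seed(3)
  est <- log_marginal_likelihood(toy$draws, toy$log_density)
  # simple importance sampling with the same moment-matched normal proposal
  qf <- toy$draws[seq(1, nrow(toy$draws), 2), , drop = FALSE]
  mu <- mean(qf); s <- sd(qf)
  th <- matrix(rnorm(4000, mu, s), ncol = 1)
  w <- toy$log_density(th) - dnorm(th[, 1], mu, s, log = TRUE)
  is_est <- log(mean(exp(w - max(w)))) + max(w)
  expect_lt(abs(est$lml - is_est), 0.01)
})

test_that("random-effect correlations are reconstructed from the Cholesky", {
  spec <- dyad_model_spec("distress")
  # identity Cholesky: all off-diagonal entries 0, none flagged
  rc0 <- random_effect_correlations(fake_fit(rep(0, 73)))
  expect_true(all(rc0$estimate == 0))
  expect_false(any(rc0$excludes_zero))
  # a fixed known correlation matrix round-trips through the transform
  R0 <- diag(10)
  R0[1, 2] <- R0[2, 1] <- -0.89
  R0[3, 8] <- R0[8, 3] <- 0.48
  y0 <- dyadhg:::.lkj_unconstrain(t(chol(R0)))$y
  q <- rep(0, 73); q[29:73] <- y0
  rc <- random_effect_correlations(fake_fit(q))
  i12 <- which(rc$parameter_1 == "Parent Lack of CSE Intercept" &
                 rc$parameter_2 == "Parent Lack of CSE-Parent PTSS")
  expect_equal(rc$estimate[i12], -0.89, tolerance = 1e-6)
  # rows follow the published labeling, e.g. the parent/youth communal
  # coping intercept pair
  expect_true(any(rc$parameter_1 == "Parent CCOPE Intercept" &
                    rc$parameter_2 == "Youth CCOPE Intercept"))
})

test_that("bayesian correlations track the sample Pearson correlation", {
  set.seed(44)
  n <- 500
  x <- rnorm(n)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  d <- data.frame(p_ptss = x, y_ptss = y)
  bc <- bayesian_correlations(d, vars = c("p_ptss", "y_ptss"),
                              mcmc = mcmc_config(chains = 2, iter = 1000,
                                                 warmup = 500, seed = 3),
                              flip = character())
  r_pearson <- cor(x, y)
  expect_lt(abs(bc$table$estimate[1] - r_pearson), 0.08)
  expect_true(bc$table$excludes_zero[1])
  # sign restoration for reverse-coded variables
  d2 <- data.frame(p_ptss = x, p_lack_cse = y)
  bc2 <- bayesian_correlations(d2, vars = c("p_ptss", "p_lack_cse"),
                               mcmc = mcmc_config(chains = 2, iter = 1000,
                                                  warmup = 500, seed = 3))
  expect_equal(bc2$table$estimate[1], -bc$table$estimate[1], tolerance = 1e-9)
  expect_equal(sort(c(bc2$table$var_1[1], bc2$table$var_2[1])),
               c("p_cse", "p_ptss"))
  # near-duplicate variables correlate at ~1; constants are rejected
  d3 <- data.frame(a = x, b = x + rnorm(n, 0, 0.01))
  bc3 <- bayesian_correlations(d3, vars = c("a", "b"),
                               mcmc = mcmc_config(chains = 2, iter = 600,
                                                  warmup = 300, seed = 4),
                               flip = character())
  expect_gt(bc3$table$estimate[1], 0.99)
  expect_error(bayesian_correlations(data.frame(a = x, b = 1),
                                     vars = c("a", "b"), flip = character()),
               "constant")
})
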