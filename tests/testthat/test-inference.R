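test_that("MCMC configuration profiles match their definitions", {
  desk <- mcmc_config("desk")
  expect_equal(desk[c("chains", "iter", "warmup", "thin")],
               list(chains = 4L, iter = 1500L, warmup = 500L, thin = 1L))
  paper <- mcmc_config("paper")
  expect_equal(paper[c("chains", "iter", "warmup", "thin")],
               list(chains = 32L, iter = 7500L, warmup = 3750L, thin = 4L))
  # 30,000 post-warmup draws retained
  expect_equal(paper$chains * (paper$iter - paper$warmup) / paper$thin, 30000)
  expect_error(mcmc_config(iter = 100, warmup = 200), "warmup")
  expect_error(mcmc_config(chains = 1), "chains")
})

test_that("fits are reproducible under a fixed seed", {
  d <- tiny_dyads(25, seed = 11)
  f1 <- quick_fit(d, seed = 3, iter = 300, warmup = 150)
  f2 <- quick_fit(d, seed = 3, iter = 300, warmup = 150)
  expect_identical(f1$draws, f2$draws)
  f3 <- quick_fit(d, seed = 4, iter = 300, warmup = 150)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("prior-only fits return the informative prior means", {
  empty <- generate_dyads(dyad_config(n_dyads = 0))
  f <- fit_dyad_model(empty, "distress", priors = "informative",
                      mcmc = mcmc_config(seed = 2, iter = 4000,
                                         warmup = 1000))
  arr <- posterior_draws(f, merge_chains = FALSE)
  targets <- c(b_p_ccope_rev_lack_cse = 0.21, b_p_lack_cse_ptss = 0.36,
               b_y_ccope_rev_lack_cse = 0.21, b_y_lack_cse_ptss = 0.36)
  for (nm in names(targets)) {
    v <- as.numeric(arr[, , nm])
    mcse <- sd(v) / sqrt(ess_bulk(arr[, , nm]))
    expect_lt(abs(mean(v) - targets[[nm]]), 3 * mcse)
  }
})

test_that("with no data, posterior moments match the priors (prior recovery)", {
  empty <- generate_dyads(dyad_config(n_dyads = 0))
  f <- fit_dyad_model(empty, "distress", priors = "informative",
                      mcmc = mcmc_config(seed = 5, iter = 4000,
                                         warmup = 1000))
  arr <- posterior_draws(f, merge_chains = FALSE)
  # the two normal-prior coefficients: mean and SD match the prior
  for (nm in c("b_p_ccope_rev_lack_cse", "b_p_lack_cse_ptss")) {
    v <- as.numeric(arr[, , nm])
    truth <- if (nm == "b_p_lack_cse_ptss") c(0.36, 0.06) else c(0.21, 0.10)
    ess <- ess_bulk(arr[, , nm])
    expect_lt(abs(mean(v) - truth[1]), 3 * truth[2] / sqrt(ess))
    expect_lt(abs(sd(v) - truth[2]), 3 * truth[2] / sqrt(ess))
  }
  # heavy-tailed student-t coefficients: symmetric around 0
  for (nm in c("b_p_ccope_rev_ptss", "b_y_lack_cse_Intercept")) {
    v <- as.numeric(arr[, , nm])
    expect_lt(abs(median(v)), 0.15)
    expect_lt(abs(mean(v <= 0) - 0.5), 0.05)
  }
})

test_that("coefficients are recovered from generated data (short check)", {
  d <- generate_dyads(dyad_config(n_dyads = 150, seed = 17))
  f <- quick_fit(d, seed = 6, chains = 2, iter = 600, warmup = 300)
  truth <- attr(d, "config")$fixed_effects
  est <- coef(f)
  expect_lt(abs(est[["b_p_lack_cse_ptss"]] -
                  truth[["b_p_lack_cse_ptss"]]), 0.2)
  expect_lt(abs(est[["b_y_ccope_rev_lack_cse"]] -
                  truth[["b_y_ccope_rev_lack_cse"]]), 0.2)
})

test_that("missing data are rejected with a pointer to imputation", {
  d <- inject_missingness(tiny_dyads(30), 0.1, seed = 1)
  expect_error(fit_dyad_model(d, "distress", priors = "weak"),
               "impute_missing")
})

test_that("posterior predictive replicates obey the hurdle-gamma identities", {
  d <- tiny_dyads(40, seed = 9)
  n <- 40
  spec <- dyad_model_spec("distress")
  q <- c(seq(-0.1, 0.3, length.out = 10),  # betas
         log(c(2, 2, 2, 2)), qlogis(rep(0.2, 4)), log(rep(0.2, 10)),
         rep(0, 45), rep(0, 10 * n))       # identity corr, zero innovations
  f <- fake_fit_with_data(q, d, n_keep = 600, chains = 2)
  set.seed(31)
  reps <- posterior_predictive_draws(f, n_rep = 1000)
  # replicate mean ~ (1 - hu) * mean(exp(eta)); with z = 0 the etas are the
  # fixed-effect predictors
  b <- q[1:10]
  zx <- f$dat$ZX[, 1]; zm <- f$dat$ZM[, 1]
  eta_med <- b[1] + b[2] * zx
  eta_out <- b[3] + b[4] * zx + b[5] * zm
  for (s in 1:2) {
    eta <- if (s == 1) eta_med else eta_out
    target <- 0.8 * mean(exp(eta))
    got <- mean(reps[[s]])
    mc_se <- sd(as.numeric(reps[[s]])) / sqrt(length(reps[[s]]))
    expect_lt(abs(got - target), 4 * mc_se)
    # zero fraction matches the hurdle probability
    expect_lt(abs(mean(reps[[s]] == 0) - 0.2), 0.02)
  }
  expect_error(posterior_predictive_draws(f, n_rep = 1300), "exceeds")
  # simulate() is the S3 alias
  s <- simulate(f, nsim = 5, seed = 1)
  expect_length(s, 4)
  expect_equal(dim(s[[1]]), c(5, 40))
})

test_that("summary tables carry estimates, intervals and diagnostics", {
  f <- quick_fit(tiny_dyads(30, seed = 5), seed = 2)
  s <- summary(f)
  expect_s3_class(s, "summary.dyadfit")
  expect_true(all(c("estimate", "lower", "upper", "rhat", "bulk_ess",
                    "tail_ess") %in% names(s$table)))
  expect_equal(nrow(s$table), 28)  # 10 betas + 4 shapes + 4 hu + 10 sds
  expect_true(all(s$table$lower <= s$table$estimate + 1e-9))
  expect_output(print(f), "distress topology")
})
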