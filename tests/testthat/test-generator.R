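test_that("zero dyads give an empty dataset with the full schema", {
  d <- generate_dyads(dyad_config(n_dyads = 0))
  expect_equal(nrow(d), 0)
  expect_named(d, c("dyad_id", "p_ptss", "p_lack_cse", "p_ccope_rev",
                    "y_ptss", "y_lack_cse", "y_ccope_rev",
                    "days_since_event"))
})

test_that("the default configuration yields the study sample size", {
  d <- generate_dyads(dyad_config(seed = 3))
  expect_equal(nrow(d), 452)
  expect_true(all(as.matrix(d[, 2:7]) >= 0))
  expect_equal(anyDuplicated(d$dyad_id), 0)
})

test_that("gamma mean identity: sample mean of a no-noise outcome is exp(eta)", {
  # all random-effect SDs 0, no hurdle: E[y] = exp(intercept) for the
  # exogenous marginal; verified against direct simulation at 50,000 dyads
  eta <- 0.43
  defaults <- dyad_config()
  cfg <- dyad_config(
    n_dyads = 50000, seed = 99,
    re_sd = setNames(rep(0, 10), names(defaults$re_sd)),
    hurdle_prob = setNames(rep(0, 6), names(defaults$hurdle_prob)),
    intercepts = c(x_p_ptss = eta))
  d <- generate_dyads(cfg)
  shape <- cfg$shape[["x_p_ptss"]]
  mc_se <- exp(eta) / sqrt(shape) / sqrt(50000)
  expect_lt(abs(mean(d$p_ptss) - exp(eta)), 3 * mc_se)
})

test_that("realized dyad random effects converge to the configured correlation", {
  Rc <- diag(10)
  Rc[1, 2] <- Rc[2, 1] <- -0.6
  Rc[3, 8] <- Rc[8, 3] <- 0.5
  d <- generate_dyads(dyad_config(n_dyads = 20000, re_corr = Rc, seed = 5))
  u <- attr(d, "random_effects")
  emp <- cor(u)
  expect_lt(max(abs(emp - Rc)), 0.05)
})

test_that("generation is byte-identical under the same seed", {
  d1 <- generate_dyads(dyad_config(n_dyads = 100, seed = 21))
  d2 <- generate_dyads(dyad_config(n_dyads = 100, seed = 21))
  expect_identical(d1, d2)
  d3 <- generate_dyads(dyad_config(n_dyads = 100, seed = 22))
  expect_false(identical(d1$p_ptss, d3$p_ptss))
})

test_that("configuration invariants are enforced", {
  bad <- diag(10); bad[1, 2] <- bad[2, 1] <- 1.2  # not PSD
  expect_error(dyad_config(re_corr = bad), "positive semi-definite")
  ns <- names(dyad_config()$shape)
  expect_error(dyad_config(shape = setNames(rep(-1, 6), ns)), "positive")
  expect_error(dyad_config(missing_rate = 1.5), "missing_rate")
  expect_error(dyad_config(fixed_effects = c(nonsense = 1)), "unknown names")
})

test_that("missingness injection is MCAR at the nominal rate", {
  d <- generate_dyads(dyad_config(n_dyads = 400, seed = 2))
  expect_identical(inject_missingness(d, 0), d)

  big <- generate_dyads(dyad_config(n_dyads = 20000, seed = 8))
  m <- inject_missingness(big, 0.023, seed = 4)
  cells <- 6 * nrow(big)  # > 100,000 analysis cells
  frac <- sum(is.na(m[, 2:7])) / cells
  se <- sqrt(0.023 * 0.977 / cells)
  expect_lt(abs(frac - 0.023), 3 * se)

  all_gone <- inject_missingness(d, 1, seed = 1)
  expect_true(all(is.na(all_gone[, 2:7])))
  expect_identical(all_gone$dyad_id, d$dyad_id)
  expect_error(inject_missingness(d, -0.1), "rate")
})

test_that("datasets and configs round-trip through CSV/YAML", {
  d <- inject_missingness(generate_dyads(dyad_config(n_dyads = 30, seed = 1)),
                          0.1, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_dyads(d, f)
  d2 <- read_dyads(f)
  expect_equal(as.data.frame(d), d2, tolerance = 1e-12, ignore_attr = TRUE)

  cfg <- dyad_config(n_dyads = 17, topology = "communal", seed = 9)
  fy <- tempfile(fileext = ".yaml")
  write_dyad_config(cfg, fy)
  cfg2 <- read_dyad_config(fy)
  expect_equal(cfg$fixed_effects, cfg2$fixed_effects)
  expect_equal(cfg$re_corr, cfg2$re_corr)
  # YAML stores numbers at 15 significant digits
  expect_equal(generate_dyads(cfg), generate_dyads(cfg2),
               tolerance = 1e-7, ignore_attr = TRUE)
})
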