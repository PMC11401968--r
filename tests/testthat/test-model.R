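spec_d <- dyad_model_spec("distress")
spec_c <- dyad_model_spec("communal")

test_that("prior sets follow the published ledger", {
  ps <- build_prior_set(spec_d, "informative")
  # lack-of-CSE coefficient in the communal-coping submodel
  expect_equal(ps[["b_p_ccope_rev_lack_cse"]],
               prior_normal(0.21, 0.1))
  # PTSS coefficient in the lack-of-CSE submodel
  expect_equal(ps[["b_y_lack_cse_ptss"]], prior_normal(0.36, 0.06))
  # the same two informative priors sit on the mirrored paths in the
  # communal topology
  pc <- build_prior_set(spec_c, "informative")
  expect_equal(pc[["b_p_lack_cse_ccope_rev"]], prior_normal(0.21, 0.1))
  expect_equal(pc[["b_y_ptss_lack_cse"]], prior_normal(0.36, 0.06))
  # direct path and all intercepts/SDs are weakly informative
  expect_equal(ps[["b_p_ccope_rev_ptss"]], prior_student_t(3, 0, 1))
  expect_equal(ps[["b_p_lack_cse_Intercept"]], prior_student_t(3, 0, 1))
  expect_equal(ps[["sd_y_ccope_rev_ptss"]], prior_student_t(3, 0, 1))
  # shapes are gamma(1, 1) in both profiles
  expect_equal(ps[["shape_p_lack_cse"]], prior_gamma(1, 1))
  # weak profile: student_t(3, 0, 1) on every location/scale parameter
  pw <- build_prior_set(spec_d, "weak")
  locs <- grep("^(b_|hu_|sd_)", names(pw), value = TRUE)
  for (nm in locs) expect_equal(pw[[nm]], prior_student_t(3, 0, 1))
  # parent and youth carry identical priors
  expect_equal(ps[["b_p_lack_cse_ptss"]], ps[["b_y_lack_cse_ptss"]])
})

test_that("model specifications and priors serialize to YAML", {
  f <- tempfile(fileext = ".yaml")
  write_model_yaml(spec_d, build_prior_set(spec_d, "informative"), f)
  y <- yaml::read_yaml(f)
  expect_equal(y$topology, "distress")
  expect_equal(y$prior_profile, "informative")
  expect_equal(y$priors$b_p_lack_cse_ptss, "normal(0.36, 0.06)")
  expect_equal(y$re_correlation_prior, "lkj(1)")
  expect_output(print(spec_d), "hurdle gamma, log link")
})

test_that("unknown parameter names are rejected", {
  ps <- build_prior_set(spec_d, "weak")
  expect_error(set_prior(ps, "b_p_nonexistent", prior_normal(0, 1)),
               "unknown parameter")
  ps2 <- set_prior(ps, "b_p_lack_cse_ptss", prior_normal(0.3, 0.2))
  expect_equal(ps2[["b_p_lack_cse_ptss"]], prior_normal(0.3, 0.2))
})

# independent R-side oracle for the joint density at a parameter point with
# diagonal Cholesky (so the LKJ kernel and Jacobian vanish at jacobian=FALSE)
oracle_density <- function(theta, data, spec, priors) {
  n <- nrow(data)
  lp <- 0
  if (n > 0) {
    zx <- as.numeric(scale(data[[paste0("p_", spec$x)]]))
    zxy <- as.numeric(scale(data[[paste0("y_", spec$x)]]))
    zmp <- as.numeric(scale(data[[paste0("p_", spec$mediator)]]))
    zmy <- as.numeric(scale(data[[paste0("y_", spec$mediator)]]))
    b <- theta$beta
    u <- theta$re_z %*% t(theta$re_chol) %*% diag(theta$re_sd)
    etas <- list(
      cbind(b[1] + (b[2] + u[, 2]) * zx + u[, 1],
            b[3] + (b[4] + u[, 4]) * zx + (b[5] + u[, 5]) * zmp + u[, 3]),
      cbind(b[6] + (b[7] + u[, 7]) * zxy + u[, 6],
            b[8] + (b[9] + u[, 9]) * zxy + (b[10] + u[, 10]) * zmy + u[, 8]))
    ys <- list(cbind(data[[paste0("p_", spec$mediator)]],
                     data[[paste0("p_", spec$outcome)]]),
               cbind(data[[paste0("y_", spec$mediator)]],
                     data[[paste0("y_", spec$outcome)]]))
    for (m in 1:2) for (s in 1:2) {
      k <- 2 * (m - 1) + s
      lp <- lp + sum(hurdle_gamma_logpdf(ys[[m]][, s], exp(etas[[m]][, s]),
                                         theta$shape[k], theta$hu[k]))
    }
    lp <- lp + sum(dnorm(theta$re_z, log = TRUE))
  }
  tpdf <- function(x, nu, mu, sg) dt((x - mu) / sg, nu, log = TRUE) - log(sg)
  for (i in seq_along(spec$beta_names)) {
    p <- priors[[spec$beta_names[i]]]
    lp <- lp + if (p$dist == "normal") dnorm(theta$beta[i], p$mu, p$sd, TRUE)
    else tpdf(theta$beta[i], p$nu, p$mu, p$sigma)
  }
  for (i in 1:4) {
    lp <- lp + dgamma(theta$shape[i], 1, 1, log = TRUE)    # gamma(1,1) shape
    lp <- lp + tpdf(qlogis(theta$hu[i]), 3, 0, 1)          # logit-scale prior
  }
  for (i in 1:10) lp <- lp + tpdf(theta$re_sd[i], 3, 0, 1) + log(2)
  unname(lp)
}

test_that("joint log density matches a term-by-term oracle on two dyads", {
  set.seed(10)
  data <- data.frame(
    dyad_id = 1:2,
    p_ptss = c(1.2, 0), p_lack_cse = c(0.5, 2.1), p_ccope_rev = c(0, 1.4),
    y_ptss = c(2.2, 0.4), y_lack_cse = c(1.1, 0.2), y_ccope_rev = c(0.8, 3))
  ps <- build_prior_set(spec_d, "weak")
  theta <- parameter_point(
    spec_d,
    beta = setNames(seq(-0.2, 0.25, length.out = 10), spec_d$beta_names),
    shape = setNames(c(2, 1.5, 2.5, 1.2), spec_d$shape_names),
    hu = setNames(c(0.1, 0.2, 0.15, 0.05), spec_d$hu_names),
    re_sd = setNames(seq(0.1, 0.55, length.out = 10), spec_d$sd_names),
    re_z = matrix(rnorm(20), 2, 10))
  expect_equal(joint_log_density(theta, data, spec_d, ps),
               oracle_density(theta, data, spec_d, ps), tolerance = 1e-10)
})

test_that("with zero dyads the joint density is the log prior alone", {
  empty <- generate_dyads(dyad_config(n_dyads = 0))
  ps <- build_prior_set(spec_d, "weak")
  theta <- parameter_point(spec_d, re_z = matrix(0, 0, 10))
  expect_equal(joint_log_density(theta, empty, spec_d, ps),
               oracle_density(theta, empty, spec_d, ps), tolerance = 1e-10)
})

test_that("with no data the informative prior peaks at its published mean", {
  empty <- generate_dyads(dyad_config(n_dyads = 0))
  ps <- build_prior_set(spec_d, "informative")
  at <- function(b) {
    th <- parameter_point(spec_d, beta = c(b_p_ccope_rev_lack_cse = b),
                          re_z = matrix(0, 0, 10))
    joint_log_density(th, empty, spec_d, ps)
  }
  expect_gt(at(0.21), at(0.16))
  expect_gt(at(0.21), at(0.26))
})

test_that("the joint density is invariant to dyad ordering", {
  set.seed(2)
  data <- tiny_dyads(n = 15, seed = 4)
  ps <- build_prior_set(spec_d, "weak")
  z <- matrix(rnorm(150), 15, 10)
  th <- function(zm) parameter_point(
    spec_d, beta = setNames(rep(0.1, 10), spec_d$beta_names),
    re_sd = setNames(rep(0.3, 10), spec_d$sd_names), re_z = zm)
  perm <- sample(15)
  expect_equal(
    joint_log_density(th(z), data, spec_d, ps),
    joint_log_density(th(z[perm, ]), data[perm, ], spec_d, ps),
    tolerance = 1e-10)
})

test_that("the two topologies are mirror images under variable swap", {
  data <- tiny_dyads(n = 12, seed = 6)
  swapped <- data
  swapped[c("p_ptss", "p_ccope_rev")] <- data[c("p_ccope_rev", "p_ptss")]
  swapped[c("y_ptss", "y_ccope_rev")] <- data[c("y_ccope_rev", "y_ptss")]
  set.seed(8)
  z <- matrix(rnorm(120), 12, 10)
  mk <- function(spec) parameter_point(
    spec, beta = setNames(seq(-0.1, 0.3, length.out = 10), spec$beta_names),
    shape = setNames(c(2, 1.4, 2.2, 1.8), spec$shape_names),
    hu = setNames(rep(0.12, 4), spec$hu_names),
    re_sd = setNames(rep(0.25, 10), spec$sd_names), re_z = z)
  expect_equal(
    joint_log_density(mk(spec_d), data, spec_d,
                      build_prior_set(spec_d, "weak")),
    joint_log_density(mk(spec_c), swapped, spec_c,
                      build_prior_set(spec_c, "weak")),
    tolerance = 1e-10)
})

test_that("incomplete data are rejected with a pointer to imputation", {
  d <- inject_missingness(tiny_dyads(20), 0.1, seed = 2)
  th <- parameter_point(spec_d, re_z = matrix(0, nrow(d), 10))
  expect_error(
    joint_log_density(th, d, spec_d, build_prior_set(spec_d, "weak")),
    "impute_missing")
})
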