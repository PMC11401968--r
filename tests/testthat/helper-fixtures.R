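# Shared fixtures: tiny analysis-ready datasets and short fits.

tiny_dyads <- function(n = 40, seed = 7, topology = "distress") {
  generate_dyads(dyad_config(n_dyads = n, topology = topology, seed = seed))
}

quick_mcmc <- function(seed = 1, chains = 2, iter = 400, warmup = 200) {
  mcmc_config(chains = chains, iter = iter, warmup = warmup, seed = seed)
}

quick_fit <- function(data = tiny_dyads(), topology = "distress",
                      priors = "weak", seed = 1, ...) {
  fit_dyad_model(data, topology, priors = priors,
                 mcmc = quick_mcmc(seed = seed, ...))
}

# a minimal dyadfit-shaped object whose global draws are fully controlled;
# n_keep rows, all equal to the supplied 73-vector of unconstrained values
fake_fit <- function(q_global, spec = dyad_model_spec("distress"),
                     n_keep = 50, chains = 2) {
  stopifnot(length(q_global) == 73)
  m <- matrix(rep(q_global, each = n_keep), n_keep, 73)
  structure(list(draws = replicate(chains, m, simplify = FALSE),
                 spec = spec, n_dyads = 0L),
            class = "dyadfit")
}

# a controlled fit over real data: every draw equals the supplied full
# unconstrained vector (globals + innovations), so posterior-predictive
# identities can be checked exactly
fake_fit_with_data <- function(q_full, data,
                               spec = dyad_model_spec("distress"),
                               n_keep = 50, chains = 2) {
  data <- standardize_predictors(data)
  dat <- dyadhg:::.hg_data(data, spec)
  stopifnot(length(q_full) == 73 + 10 * dat$n)
  m <- matrix(rep(q_full, each = n_keep), n_keep, length(q_full))
  structure(list(draws = replicate(chains, m, simplify = FALSE),
                 spec = spec, n_dyads = dat$n, dat = dat, data = data),
            class = "dyadfit")
}

# conjugate normal-normal toy: data, closed-form evidence, exact posterior
conjugate_toy <- function(n = 50, sigma = 1.3, mu0 = 0.5, tau0 = 2,
                          seed = 11, n_draws = 4000) {
  set.seed(seed)
  y <- rnorm(n, 1.2, sigma)
  ybar <- mean(y)
  lml <- -n / 2 * log(2 * pi * sigma^2) - sum((y - ybar)^2) / (2 * sigma^2) +
    0.5 * log(sigma^2 / (n * tau0^2 + sigma^2)) -
    n * (ybar - mu0)^2 / (2 * (n * tau0^2 + sigma^2))
  taun2 <- 1 / (1 / tau0^2 + n / sigma^2)
  mun <- taun2 * (mu0 / tau0^2 + sum(y) / sigma^2)
  draws <- matrix(rnorm(n_draws, mun, sqrt(taun2)), ncol = 1)
  log_density <- function(x) apply(x, 1, function(t)
    sum(dnorm(y, t, sigma, log = TRUE)) + dnorm(t, mu0, tau0, log = TRUE))
  list(lml = lml, draws = draws, log_density = log_density)
}
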