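#' MCMC configuration
#'
#' The `desk` profile (4 chains x 1,500 iterations, 500 warmup, no thinning,
#' 4,000 post-warmup draws) is the default working configuration. The
#' `paper` profile reproduces the published run: 32 chains x 7,500
#' iterations, 3,750 warmup, thinning 4 (30,000 post-warmup draws kept).
#' Explicit arguments override the profile.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param chains,iter,warmup,thin overrides.
#' @param seed integer seed driving all chains.
#' @param init `"zero"` (all unconstrained parameters start at 0, so shapes
#'   and SDs start at 1 and hurdle probabilities at 0.5) or `"random"`
#'   (uniform(-2, 2) on the unconstrained scale).
#' @param adapt_delta dual-averaging target acceptance.
#' @param max_treedepth NUTS doubling cap.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(profile = c("desk", "paper"), chains = NULL,
                        iter = NULL, warmup = NULL, thin = NULL, seed = 1L,
                        init = c("zero", "random"), adapt_delta = 0.9,
                        max_treedepth = 10L) {
  profile <- match.arg(profile)
  init <- match.arg(init)
  def <- if (profile == "paper") list(chains = 32L, iter = 7500L,
                                      warmup = 3750L, thin = 4L)
         else list(chains = 4L, iter = 1500L, warmup = 500L, thin = 1L)
  cfg <- list(profile = profile,
              chains = as.integer(chains %||% def$chains),
              iter = as.integer(iter %||% def$iter),
              warmup = as.integer(warmup %||% def$warmup),
              thin = as.integer(thin %||% def$thin),
              seed = as.integer(seed), init = init,
              adapt_delta = adapt_delta,
              max_treedepth = as.integer(max_treedepth))
  stopifnot(cfg$warmup < cfg$iter, cfg$thin >= 1, cfg$chains >= 2)
  structure(cfg, class = "mcmc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a dyadic hurdle-gamma path model
#'
#' Samples the joint posterior with the package's No-U-Turn sampler
#' (multinomial NUTS with dual-averaging step-size adaptation and a windowed
#' diagonal metric). Covariates are z-scored internally, so coefficients are
#' on the standardized log-link scale. A zero-row dataset yields a
#' prior-only fit.
#'
#' @param data complete dyad data frame (see [impute_missing()]).
#' @param topology `"distress"` or `"communal"`.
#' @param priors `"informative"`, `"weak"`, or a [build_prior_set()] object.
#' @param mcmc an [mcmc_config()].
#' @param verbose print per-chain progress.
#' @return A `dyadfit` object with methods `print`, `summary`, `coef`,
#'   `simulate`, and `plot`.
#' @examples
#' \donttest{
#' d <- generate_dyads(dyad_config(n_dyads = 60, seed = 1))
#' f <- fit_dyad_model(d, "distress", priors = "weak",
#'                     mcmc = mcmc_config(chains = 2, iter = 400,
#'                                        warmup = 200))
#' coef(f)
#' }
#' @export
fit_dyad_model <- function(data, topology = c("distress", "communal"),
                           priors = c("informative", "weak"),
                           mcmc = mcmc_config(), verbose = FALSE) {
  topology <- match.arg(topology)
  spec <- dyad_model_spec(topology)
  if (is.character(priors))
    priors <- build_prior_set(spec, match.arg(priors))
  stopifnot(inherits(priors, "prior_set"), inherits(mcmc, "mcmc_config"))
  if (nrow(data) > 0) data <- standardize_predictors(data)
  dat <- .hg_data(data, spec)
  pm <- .prior_matrix(priors, spec)
  D <- spec$n_global + 10L * dat$n

  draws <- vector("list", mcmc$chains)
  divergent <- 0L
  treedepth <- numeric(0)
  t0 <- proc.time()[3]
  for (ch in seq_len(mcmc$chains)) {
    init <- if (mcmc$init == "zero") {
      rep(0, D)
    } else {
      set.seed(mcmc$seed * 1000L + ch)
      stats::runif(D, -2, 2)
    }
    r <- nuts_hg_cpp(dat, pm, init, mcmc$iter, mcmc$warmup, mcmc$thin,
                     mcmc$max_treedepth, mcmc$adapt_delta,
                     mcmc$seed * 10000 + ch)
    draws[[ch]] <- r$draws
    divergent <- divergent + sum(r$divergent)
    treedepth <- c(treedepth, mean(r$treedepth))
    if (verbose)
      message(sprintf("chain %d: stepsize %.3g, %d divergences", ch,
                      r$stepsize, sum(r$divergent)))
  }
  elapsed <- proc.time()[3] - t0
  n_total <- mcmc$chains * (mcmc$iter - mcmc$warmup)
  if (divergent > 0.01 * n_total)
    warning(sprintf("%d of %d post-warmup transitions were divergent (>1%%)",
                    divergent, n_total))

  fit <- structure(list(
    draws = draws, spec = spec, priors = priors, mcmc = mcmc,
    data = data, n_dyads = dat$n, dat = dat, prior_matrix = pm,
    divergent = divergent, mean_treedepth = mean(treedepth),
    elapsed = elapsed), class = "dyadfit")
  fit
}

# merged constrained draws for the global parameters (+ correlations)
#' Extract posterior draws
#'
#' Returns a matrix of posterior draws on natural scales: fixed effects,
#' gamma shapes, hurdle probabilities, random-effect SDs, and the 45
#' random-effect correlations reconstructed from the Cholesky draws.
#'
#' @param fit a `dyadfit`.
#' @param pars optional character vector of parameter names to keep.
#' @param merge_chains if `FALSE`, return a 3-d array (draw, chain, par).
#' @export
posterior_draws <- function(fit, pars = NULL, merge_chains = TRUE) {
  spec <- fit$spec
  per_chain <- lapply(fit$draws, function(d) {
    g <- d[, 1:73, drop = FALSE]
    out <- cbind(g[, 1:10, drop = FALSE], exp(g[, 11:14, drop = FALSE]),
                 stats::plogis(g[, 15:18, drop = FALSE]),
                 exp(g[, 19:28, drop = FALSE]),
                 lkj_corrs_cpp(g[, 29:73, drop = FALSE], 10L))
    colnames(out) <- c(spec$beta_names, spec$shape_names, spec$hu_names,
                       spec$sd_names, spec$cor_names)
    out
  })
  if (!is.null(pars)) {
    miss <- setdiff(pars, colnames(per_chain[[1]]))
    if (length(miss)) stop("unknown parameter(s): ",
                           paste(miss, collapse = ", "))
    per_chain <- lapply(per_chain, function(m) m[, pars, drop = FALSE])
  }
  if (merge_chains) return(do.call(rbind, per_chain))
  arr <- array(unlist(per_chain),
               dim = c(nrow(per_chain[[1]]), ncol(per_chain[[1]]),
                       length(per_chain)),
               dimnames = list(NULL, colnames(per_chain[[1]]), NULL))
  aperm(arr, c(1, 3, 2))
}

#' @export
print.dyadfit <- function(x, ...) {
  cat("Bayesian dyadic hurdle-gamma path model (", x$spec$topology,
      " topology)\n", sep = "")
  cat(sprintf("  dyads: %d   priors: %s\n", x$n_dyads,
              attr(x$priors, "profile")))
  kept <- nrow(x$draws[[1]])
  cat(sprintf(
    "  chains: %d   post-warmup draws: %d (%d kept/chain)   divergences: %d\n",
    length(x$draws), length(x$draws) * kept, kept, x$divergent))
  cat("Use summary() for coefficient tables.\n")
  invisible(x)
}

#' @export
coef.dyadfit <- function(object, ...) {
  colMeans(posterior_draws(object, pars = object$spec$beta_names))
}

#' Summarize a dyadic path model fit
#'
#' One row per fixed effect, gamma shape, hurdle probability and
#' random-effect SD: posterior mean, 95% credible interval, rank-normalized
#' split R-hat, and bulk/tail effective sample sizes.
#'
#' @param object a `dyadfit`.
#' @param prob credible-interval mass.
#' @param ... unused.
#' @export
summary.dyadfit <- function(object, prob = 0.95, ...) {
  arr <- posterior_draws(object, merge_chains = FALSE)
  pars <- c(object$spec$beta_names, object$spec$shape_names,
            object$spec$hu_names, object$spec$sd_names)
  a2 <- (1 - prob) / 2
  rows <- lapply(pars, function(p) {
    m <- arr[, , p]
    v <- as.numeric(m)
    data.frame(parameter = p, estimate = mean(v),
               lower = stats::quantile(v, a2),
               upper = stats::quantile(v, 1 - a2),
               rhat = rhat(m), bulk_ess = ess_bulk(m),
               tail_ess = ess_tail(m), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  structure(list(table = out, topology = object$spec$topology,
                 n_dyads = object$n_dyads, divergent = object$divergent,
                 chains = length(object$draws), prob = prob),
            class = "summary.dyadfit")
}

#' @export
print.summary.dyadfit <- function(x, digits = 2, ...) {
  cat("Dyadic hurdle-gamma path model (", x$topology, "), ",
      x$n_dyads, " dyads, ", x$chains, " chains\n\n", sep = "")
  tab <- x$table
  num <- c("estimate", "lower", "upper")
  tab[num] <- lapply(tab[num], round, digits)
  tab$rhat <- round(tab$rhat, 3)
  tab$bulk_ess <- round(tab$bulk_ess)
  tab$tail_ess <- round(tab$tail_ess)
  print(tab, row.names = FALSE)
  if (x$divergent > 0)
    cat("\n", x$divergent, "divergent transitions; interpret with care.\n")
  invisible(x)
}

#' Posterior predictive replicates
#'
#' Draws `n_rep` replicated outcome vectors for each of the four submodels
#' from the fitted hurdle-gamma law, conditional on the posterior draws of
#' all parameters including each dyad's own random effects.
#'
#' @param fit a `dyadfit` with data.
#' @param n_rep number of replicate datasets (at most the number of kept
#'   draws).
#' @return A named list of four `n_rep x n_dyads` matrices.
#' @export
posterior_predictive_draws <- function(fit, n_rep = 100L) {
  if (fit$n_dyads == 0) stop("no data to replicate")
  all_draws <- do.call(rbind, fit$draws)
  if (n_rep > nrow(all_draws))
    stop("n_rep exceeds the number of available posterior draws")
  idx <- round(seq(1, nrow(all_draws), length.out = n_rep))
  spec <- fit$spec
  n <- fit$n_dyads
  out <- stats::setNames(
    replicate(4, matrix(0, n_rep, n), simplify = FALSE), spec$submodels)
  ZX <- fit$dat$ZX; ZM <- fit$dat$ZM
  for (r in seq_len(n_rep)) {
    q <- all_draws[idx[r], ]
    g <- .unpack_global(q, spec)
    L <- .lkj_chol(q[29:73])
    z <- matrix(q[-(1:73)], nrow = n, byrow = TRUE)
    u <- (z %*% t(L)) %*% diag(g$re_sd)
    for (m in 1:2) {
      bo <- (m - 1) * 5
      eta_med <- g$beta[bo + 1] + (g$beta[bo + 2] + u[, bo + 2]) * ZX[, m] +
        u[, bo + 1]
      eta_out <- g$beta[bo + 3] + (g$beta[bo + 4] + u[, bo + 4]) * ZX[, m] +
        (g$beta[bo + 5] + u[, bo + 5]) * ZM[, m] + u[, bo + 3]
      sm <- 2 * m - 1; so <- 2 * m
      out[[sm]][r, ] <- rhgamma(n, exp(eta_med), g$shape[sm], g$hu[sm])
      out[[so]][r, ] <- rhgamma(n, exp(eta_out), g$shape[so], g$hu[so])
    }
  }
  out
}

# R-side forward transform (Cholesky only), mirrors the sampler
.lkj_chol <- function(y, K = 10) {
  L <- diag(K)
  idx <- 1L
  for (i in 2:K) {
    s <- 0
    for (j in 1:(i - 1)) {
      L[i, j] <- tanh(y[idx]) * sqrt(max(1 - s, 0))
      s <- s + L[i, j]^2
      idx <- idx + 1L
    }
    L[i, i] <- sqrt(max(1 - s, 0))
  }
  L
}

#' @export
simulate.dyadfit <- function(object, nsim = 100, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  posterior_predictive_draws(object, n_rep = nsim)
}

#' Posterior predictive density overlay
#'
#' Plots, per submodel, the observed outcome density (positives) with
#' replicate densities underneath, plus the observed vs replicated zero
#' fractions in the panel label.
#'
#' @param x a `dyadfit`.
#' @param n_rep replicates to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dyadfit <- function(x, n_rep = 50, ...) {
  reps <- posterior_predictive_draws(x, n_rep = n_rep)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in seq_along(reps)) {
    obs <- x$dat$Y[, s]
    dens <- stats::density(obs[obs > 0], from = 0)
    ymax <- max(dens$y)
    zr <- mean(reps[[s]] == 0)
    graphics::plot(dens, main = sprintf("%s (zeros: obs %.2f, rep %.2f)",
                                        x$spec$submodels[s],
                                        mean(obs == 0), zr),
                   xlab = "outcome", lwd = 2, ylim = c(0, 1.3 * ymax), ...)
    for (r in seq_len(min(n_rep, 20))) {
      rep_r <- reps[[s]][r, ]
      if (sum(rep_r > 0) > 2)
        graphics::lines(stats::density(rep_r[rep_r > 0], from = 0),
                        col = grDevices::adjustcolor("steelblue", 0.3))
    }
    graphics::lines(dens, lwd = 2)
  }
  invisible(x)
}
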