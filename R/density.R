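# Parameter containers, transforms between natural and unconstrained scales,
# and the joint log density used by the sampler and the bridge estimator.

# build the data block the sampler consumes: raw outcomes + z-scored
# covariates, ordered (p_mediator, p_outcome, y_mediator, y_outcome)
.hg_data <- function(data, spec) {
  n <- nrow(data)
  cols <- c(paste0("p_", spec$mediator), paste0("p_", spec$outcome),
            paste0("y_", spec$mediator), paste0("y_", spec$outcome))
  if (n == 0) {
    return(list(Y = matrix(0, 0, 4), ZX = matrix(0, 0, 2),
                ZM = matrix(0, 0, 2), n = 0L))
  }
  need <- c(cols, paste0(c("p_", "y_"), spec$x))
  if (anyNA(data[need]))
    stop("data contain missing values; run impute_missing() first")
  if (!all(paste0("z_", need) %in% names(data)))
    data <- standardize_predictors(data)
  list(Y = as.matrix(data[cols]),
       ZX = as.matrix(data[paste0("z_", c("p_", "y_"), spec$x)]),
       ZM = as.matrix(data[paste0("z_", c("p_", "y_"), spec$mediator)]),
       n = n)
}

#' Bundle a full set of model parameters
#'
#' A parameter point holds every free quantity of a dyadic hurdle-gamma path
#' model on its natural scale: fixed effects, gamma shapes, hurdle
#' probabilities, random-effect SDs, the random-effect correlation Cholesky
#' factor, and the per-dyad non-centered innovations `re_z` (the dyad's
#' random-effect vector is `diag(re_sd) %*% L %*% z`).
#'
#' @param spec a [dyad_model_spec()].
#' @param beta named fixed-effect vector (10).
#' @param shape named gamma shapes (4), positive.
#' @param hu named hurdle probabilities (4) in `[0, 1)`.
#' @param re_sd named random-effect SDs (10), positive.
#' @param re_chol 10 x 10 lower-triangular correlation Cholesky factor.
#' @param re_z n x 10 innovation matrix (one row per dyad).
#' @return A `parameter_point` list.
#' @export
parameter_point <- function(spec, beta = NULL, shape = NULL, hu = NULL,
                            re_sd = NULL, re_chol = NULL, re_z = NULL) {
  z10 <- stats::setNames(rep(0, 10), spec$beta_names)
  beta <- .fill_named(beta, z10)
  shape <- .fill_named(shape, stats::setNames(rep(1, 4), spec$shape_names))
  hu <- .fill_named(hu, stats::setNames(rep(0.5, 4), spec$hu_names))
  re_sd <- .fill_named(re_sd, stats::setNames(rep(1, 10), spec$sd_names))
  if (is.null(re_chol)) re_chol <- diag(10)
  if (is.null(re_z)) re_z <- matrix(0, 0, 10)
  stopifnot(all(shape > 0), all(hu > 0 & hu < 1), all(re_sd > 0),
            nrow(re_chol) == 10, all(diag(re_chol) > 0),
            ncol(re_z) == 10)
  structure(list(beta = beta, shape = shape, hu = hu, re_sd = re_sd,
                 re_chol = re_chol, re_z = re_z),
            class = "parameter_point")
}

# inverse of the correlation-Cholesky transform; returns the unconstrained
# vector and the log Jacobian of the forward map at that point
.lkj_unconstrain <- function(L) {
  K <- nrow(L)
  y <- numeric(K * (K - 1) / 2)
  logjac <- 0
  idx <- 1L
  for (i in 2:K) {
    s <- 0
    for (j in 1:(i - 1)) {
      w <- sqrt(max(1 - s, 1e-16))
      z <- L[i, j] / w
      z <- min(max(z, -1 + 1e-12), 1 - 1e-12)
      y[idx] <- atanh(z)
      logjac <- logjac + log1p(-z^2) + log(w)
      s <- s + L[i, j]^2
      idx <- idx + 1L
    }
  }
  list(y = y, logjac = logjac)
}

# natural-scale parameter point -> unconstrained sampler vector
.pack_point <- function(theta, n) {
  lk <- .lkj_unconstrain(theta$re_chol)
  if (nrow(theta$re_z) != n)
    stop("re_z must have one row per dyad")
  c(unname(theta$beta), log(unname(theta$shape)),
    stats::qlogis(unname(theta$hu)), log(unname(theta$re_sd)),
    lk$y, as.numeric(t(theta$re_z)))
}

# unconstrained vector -> natural-scale list (global parameters only)
.unpack_global <- function(q, spec) {
  list(beta = stats::setNames(q[1:10], spec$beta_names),
       shape = stats::setNames(exp(q[11:14]), spec$shape_names),
       hu = stats::setNames(stats::plogis(q[15:18]), spec$hu_names),
       re_sd = stats::setNames(exp(q[19:28]), spec$sd_names),
       y_lkj = q[29:73])
}

#' Joint log density of a dyadic hurdle-gamma path model
#'
#' Sums, over dyads and submodels, the hurdle-gamma log likelihoods at linear
#' predictors `eta = intercept + sum(beta * x) + dyad random effects`, the
#' log priors of every free parameter (half-distributions on SDs and shapes
#' unless the shape prior is gamma; priors on hurdle logits; LKJ(1) kernel on
#' the correlation, up to its normalizing constant), and the standard-normal
#' log density of the non-centered innovations. With `jacobian = TRUE` the
#' log Jacobians of the unconstraining transforms (log shapes, log SDs,
#' correlation Cholesky) are added; this is the density the sampler and the
#' bridge estimator target.
#'
#' @param theta a [parameter_point()].
#' @param data complete dyad data frame (zero rows allowed: the result is
#'   then the log prior alone).
#' @param spec a [dyad_model_spec()].
#' @param priors a [build_prior_set()] result.
#' @param jacobian add unconstraining-transform Jacobians?
#' @return A single numeric value.
#' @export
joint_log_density <- function(theta, data, spec, priors, jacobian = FALSE) {
  stopifnot(inherits(theta, "parameter_point"))
  dat <- .hg_data(data, spec)
  q <- .pack_point(theta, dat$n)
  lp <- hg_logp_grad_cpp(q, dat, .prior_matrix(priors, spec))$logp
  if (!jacobian) {
    lk <- .lkj_unconstrain(theta$re_chol)
    lp <- lp - sum(log(theta$shape)) - sum(log(theta$re_sd)) - lk$logjac
  }
  lp
}
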