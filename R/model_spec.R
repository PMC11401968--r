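#' Specify a dyadic hurdle-gamma path model
#'
#' Both competing topologies share one structure per member (parent, youth):
#' a mediator regression of lack of coping self-efficacy on the standardized
#' exogenous variable, and an outcome regression on the standardized exogenous
#' variable (direct path) and the standardized mediator (mediator path). The
#' `distress` topology runs PTSS -> lack of CSE -> reverse-coded communal
#' coping; the `communal` topology runs reverse-coded communal coping -> lack
#' of CSE -> PTSS. Outcomes follow hurdle-gamma laws with a log link on the
#' gamma mean and an intercept-only hurdle. Dyad-level random intercepts and
#' slopes of all four submodels (10 effects) are jointly correlated with an
#' LKJ(1) prior on the correlation matrix, in a non-centered
#' parameterization.
#'
#' @param topology `"distress"` or `"communal"`.
#' @return An object of class `dyad_model_spec`.
#' @examples
#' dyad_model_spec("distress")
#' @export
dyad_model_spec <- function(topology = c("distress", "communal")) {
  topology <- match.arg(topology)
  x <- if (topology == "distress") "ptss" else "ccope_rev"
  outcome <- if (topology == "distress") "ccope_rev" else "ptss"
  mediator <- "lack_cse"
  members <- c(parent = "p", youth = "y")
  sub <- function(pfx) {
    c(paste0(pfx, "_", mediator), paste0(pfx, "_", outcome))
  }
  submodels <- c(sub("p"), sub("y"))[c(1, 2, 3, 4)]
  # order matches the sampler layout: p_med, p_out, y_med, y_out
  beta_names <- unlist(lapply(c("p", "y"), function(m) c(
    paste0("b_", m, "_", mediator, "_Intercept"),
    paste0("b_", m, "_", mediator, "_", x),
    paste0("b_", m, "_", outcome, "_Intercept"),
    paste0("b_", m, "_", outcome, "_", x),
    paste0("b_", m, "_", outcome, "_", mediator))))
  re_names <- unlist(lapply(c("p", "y"), function(m) c(
    paste0(m, "_", mediator, "_Intercept"),
    paste0(m, "_", mediator, "_", x),
    paste0(m, "_", outcome, "_Intercept"),
    paste0(m, "_", outcome, "_", x),
    paste0(m, "_", outcome, "_", mediator))))
  sub_names <- unlist(lapply(c("p", "y"), function(m)
    c(paste0(m, "_", mediator), paste0(m, "_", outcome))))
  cor_names <- character(45)
  k <- 1L
  for (i in 2:10) for (j in 1:(i - 1)) {
    cor_names[k] <- paste0("cor_", re_names[i], "__", re_names[j])
    k <- k + 1L
  }
  structure(list(
    topology = topology, x = x, mediator = mediator, outcome = outcome,
    members = members, submodels = sub_names,
    beta_names = beta_names,
    shape_names = paste0("shape_", sub_names),
    hu_names = paste0("hu_", sub_names),
    sd_names = paste0("sd_", re_names),
    re_names = re_names, cor_names = cor_names,
    n_re = 10L, n_global = 73L
  ), class = "dyad_model_spec")
}

#' @export
print.dyad_model_spec <- function(x, ...) {
  cat("Dyadic hurdle-gamma path model (", x$topology, " topology)\n", sep = "")
  cat("  exogenous: ", x$x, "  mediator: ", x$mediator,
      "  outcome: ", x$outcome, "\n", sep = "")
  for (m in c("p", "y")) {
    who <- if (m == "p") "parent" else "youth"
    cat(sprintf("  %s: %s ~ %s | %s ~ %s + %s  (hurdle gamma, log link)\n",
                who, x$mediator, x$x, x$outcome, x$x, x$mediator))
  }
  cat("  dyad random effects: 10 correlated intercepts/slopes, LKJ(1)\n")
  invisible(x)
}

#' Prior distribution tags
#'
#' Constructors for the three prior families used by the models. Scale
#' parameters (`prior_student_t` on an SD, `prior_normal` on an SD) are
#' interpreted as half-distributions; `prior_gamma` applies on the natural
#' positive scale.
#'
#' @param mu,sd,nu,sigma,shape,rate distribution parameters.
#' @return A `dyad_prior` object.
#' @export
prior_normal <- function(mu, sd) {
  stopifnot(sd > 0)
  structure(list(dist = "normal", mu = mu, sd = sd), class = "dyad_prior")
}

#' @rdname prior_normal
#' @export
prior_student_t <- function(nu, mu, sigma) {
  stopifnot(nu > 0, sigma > 0)
  structure(list(dist = "student_t", nu = nu, mu = mu, sigma = sigma),
            class = "dyad_prior")
}

#' @rdname prior_normal
#' @export
prior_gamma <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  structure(list(dist = "gamma", shape = shape, rate = rate),
            class = "dyad_prior")
}

#' @export
format.dyad_prior <- function(x, ...) {
  switch(x$dist,
         normal = sprintf("normal(%g, %g)", x$mu, x$sd),
         student_t = sprintf("student_t(%g, %g, %g)", x$nu, x$mu, x$sigma),
         gamma = sprintf("gamma(%g, %g)", x$shape, x$rate))
}

#' @export
print.dyad_prior <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Build the prior set for a dyadic path model
#'
#' The informative profile places `normal(0.36, 0.06)` on the coefficient
#' linking PTSS and lack of CSE (a published meta-analytic weighted
#' correlation between self-efficacy and symptom severity) and
#' `normal(0.21, 0.1)` on the coefficient linking lack of CSE and
#' reverse-coded communal coping (mean correlation across prior studies); all
#' remaining coefficients, intercepts and random-effect SDs get the weakly
#' informative `student_t(3, 0, 1)` and gamma shapes get `gamma(1, 1)`. The
#' weak profile uses `student_t(3, 0, 1)` everywhere except the `gamma(1, 1)`
#' shapes. Hurdle probabilities get `student_t(3, 0, 1)` on the logit scale.
#' Identical priors apply to parent and youth. The random-effect correlation
#' matrix always carries an LKJ(1) prior.
#'
#' @param spec a [dyad_model_spec()].
#' @param profile `"informative"` or `"weak"`.
#' @return A named list of `dyad_prior` objects (class `prior_set`) with one
#'   entry per fixed effect, shape, hurdle probability and random-effect SD.
#' @examples
#' ps <- build_prior_set(dyad_model_spec("distress"), "informative")
#' ps[["b_p_lack_cse_ptss"]]
#' @export
build_prior_set <- function(spec, profile = c("informative", "weak")) {
  profile <- match.arg(profile)
  stopifnot(inherits(spec, "dyad_model_spec"))
  weak <- prior_student_t(3, 0, 1)
  nm <- c(spec$beta_names, spec$shape_names, spec$hu_names, spec$sd_names)
  ps <- stats::setNames(rep(list(weak), length(nm)), nm)
  for (s in spec$shape_names) ps[[s]] <- prior_gamma(1, 1)
  if (profile == "informative") {
    for (m in c("p", "y")) {
      # path between PTSS and lack of CSE
      nm1 <- if (spec$topology == "distress")
        paste0("b_", m, "_lack_cse_ptss")
      else paste0("b_", m, "_ptss_lack_cse")
      # path between lack of CSE and reverse-coded communal coping
      nm2 <- if (spec$topology == "distress")
        paste0("b_", m, "_ccope_rev_lack_cse")
      else paste0("b_", m, "_lack_cse_ccope_rev")
      ps[[nm1]] <- prior_normal(0.36, 0.06)
      ps[[nm2]] <- prior_normal(0.21, 0.1)
    }
  }
  structure(ps, class = c("prior_set", "list"), profile = profile,
            topology = spec$topology)
}

#' Replace one prior in a prior set
#'
#' @param priors a `prior_set`.
#' @param name parameter name (must exist in the set).
#' @param prior a `dyad_prior`.
#' @export
set_prior <- function(priors, name, prior) {
  stopifnot(inherits(priors, "prior_set"), inherits(prior, "dyad_prior"))
  if (!name %in% names(priors))
    stop("unknown parameter name: ", name)
  priors[[name]] <- prior
  priors
}

#' @export
print.prior_set <- function(x, ...) {
  cat("Prior set (profile: ", attr(x, "profile"), ")\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  cat("  random-effect correlation     lkj(1)\n")
  invisible(x)
}

#' Serialize a model specification and prior set to YAML
#'
#' @param spec a [dyad_model_spec()].
#' @param priors a [build_prior_set()] result (optional).
#' @param path file path.
#' @export
write_model_yaml <- function(spec, priors = NULL, path) {
  x <- list(topology = spec$topology, exogenous = spec$x,
            mediator = spec$mediator, outcome = spec$outcome,
            submodels = spec$submodels, random_effects = spec$re_names,
            re_correlation_prior = "lkj(1)")
  if (!is.null(priors)) {
    x$prior_profile <- attr(priors, "profile")
    x$priors <- lapply(priors, format)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

# prior set -> 28 x 4 numeric matrix in sampler order (type, a, b, c)
.prior_matrix <- function(priors, spec) {
  nm <- c(spec$beta_names, spec$shape_names, spec$hu_names, spec$sd_names)
  miss <- setdiff(nm, names(priors))
  if (length(miss)) stop("prior set is missing: ", paste(miss, collapse = ", "))
  out <- matrix(0, length(nm), 4)
  for (i in seq_along(nm)) {
    p <- priors[[nm[i]]]
    out[i, ] <- switch(p$dist,
                       normal = c(0, p$mu, p$sd, 0),
                       student_t = c(1, p$nu, p$mu, p$sigma),
                       gamma = c(2, p$shape, p$rate, 0))
  }
  out
}

# log density of a prior at x (location use) -- mirrors the sampler
.prior_lpdf <- function(p, x) {
  switch(p$dist,
         normal = stats::dnorm(x, p$mu, p$sd, log = TRUE),
         student_t = stats::dt((x - p$mu) / p$sigma, p$nu, log = TRUE) -
           log(p$sigma),
         gamma = stats::dgamma(x, shape = p$shape, rate = p$rate, log = TRUE))
}

# half-distribution log density on a positive scale parameter
.prior_lpdf_pos <- function(p, x) {
  if (p$dist == "gamma") .prior_lpdf(p, x) else .prior_lpdf(p, x) + log(2)
}
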