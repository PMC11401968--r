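#' Configure the synthetic dyad generator
#'
#' The generator draws parent-youth dyads from the generative form the path
#' models assume: every analysis variable is hurdle-gamma distributed (point
#' mass `hurdle_prob` at zero, gamma with shape `shape` and mean
#' `exp(linear predictor)` otherwise) and each dyad carries a 10-vector of
#' correlated random intercepts and slopes spanning both members' mediator
#' and outcome submodels. Generation follows the topology: the exogenous
#' variable is drawn from its marginal hurdle-gamma law, standardized within
#' the sample, and fed to the mediator submodel; the mediator is then
#' standardized and fed, together with the exogenous variable, to the outcome
#' submodel. This matches the convention that covariates enter the fitted
#' linear predictors z-scored, so the configured coefficients are the ones
#' the models estimate.
#'
#' Defaults reproduce the conditions of a published study of 452 post-flood
#' parent-youth dyads: fixed effects and intercepts at that study's posterior
#' point estimates (distress topology: PTSS -> lack of CSE -> reverse-coded
#' communal coping), exogenous marginals matched to its descriptive means,
#' gamma shapes 2, hurdle probabilities 0.1, random-effect SDs 0.2 with an
#' identity correlation matrix, and a 2.3% missing-cell rate.
#'
#' @param n_dyads number of pairs.
#' @param topology `"distress"` or `"communal"`.
#' @param fixed_effects named vector of slope coefficients on the log-link
#'   scale; names follow [dyad_model_spec()] `beta_names` (slopes only).
#' @param intercepts named vector of intercepts for the four submodels plus
#'   the two exogenous marginals (`x_p_<var>`, `x_y_<var>`).
#' @param shape named vector of gamma shapes for the same six laws.
#' @param hurdle_prob named vector of zero-probabilities for the same six
#'   laws, each in `[0, 1)`.
#' @param re_sd named vector of 10 random-effect SDs (>= 0), names =
#'   `dyad_model_spec()$re_names`.
#' @param re_corr 10 x 10 random-effect correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite).
#' @param missing_rate fraction of analysis cells set missing by
#'   [inject_missingness()] when the pipeline asks for it.
#' @param seed integer seed; the same seed gives byte-identical data.
#' @return A `dyad_generator_config` list.
#' @seealso [generate_dyads()], [inject_missingness()]
#' @export
dyad_config <- function(n_dyads = 452L,
                        topology = c("distress", "communal"),
                        fixed_effects = NULL,
                        intercepts = NULL,
                        shape = NULL,
                        hurdle_prob = NULL,
                        re_sd = NULL,
                        re_corr = NULL,
                        missing_rate = 0.023,
                        seed = 1L) {
  topology <- match.arg(topology)
  spec <- dyad_model_spec(topology)
  def <- .default_truth(spec)
  fixed_effects <- .fill_named(fixed_effects, def$fixed_effects)
  intercepts <- .fill_named(intercepts, def$intercepts)
  shape <- .fill_named(shape, def$shape)
  hurdle_prob <- .fill_named(hurdle_prob, def$hurdle_prob)
  re_sd <- .fill_named(re_sd, def$re_sd)
  if (is.null(re_corr)) re_corr <- diag(10)

  if (n_dyads < 0 || n_dyads != round(n_dyads))
    stop("'n_dyads' must be a nonnegative integer")
  if (any(shape <= 0)) stop("gamma shapes must be positive")
  if (any(hurdle_prob < 0 | hurdle_prob >= 1))
    stop("hurdle probabilities must lie in [0, 1)")
  if (any(re_sd < 0)) stop("random-effect SDs must be nonnegative")
  if (missing_rate < 0 || missing_rate > 1)
    stop("'missing_rate' must lie in [0, 1]")
  if (!isTRUE(all.equal(re_corr, t(re_corr))) ||
      !isTRUE(all.equal(unname(diag(re_corr)), rep(1, 10))))
    stop("'re_corr' must be symmetric with unit diagonal")
  ev <- eigen(re_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("'re_corr' must be positive semi-definite")

  structure(list(
    n_dyads = as.integer(n_dyads), topology = topology, spec = spec,
    fixed_effects = fixed_effects, intercepts = intercepts, shape = shape,
    hurdle_prob = hurdle_prob, re_sd = re_sd, re_corr = re_corr,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "dyad_generator_config")
}

# default truth: published point estimates for the fitted submodels, plus
# exogenous marginals matched to the study's descriptive means under
# hurdle 0.1 (E[y] = (1 - hu) exp(eta))
.default_truth <- function(spec) {
  x <- spec$x; med <- spec$mediator; out <- spec$outcome
  slopes <- spec$beta_names[!grepl("_Intercept$", spec$beta_names)]
  if (spec$topology == "distress") {
    fe <- c(0.25, 0.04, 0.12, 0.27, -0.03, 0.18)
    ic <- c(-0.06, 0.13, -0.02, 0.14)
    x_icpt <- log(1.38 / 0.9)     # PTSS marginal, item-mean metric
  } else {
    fe <- c(0.18, 0.03, 0.24, 0.22, 0.03, 0.26)
    ic <- c(0.12, -0.10, 0.06, -0.33)
    x_icpt <- log((7 - 5.58) / 0.9)  # reverse-coded communal coping marginal
  }
  names(fe) <- slopes
  icpt_names <- spec$beta_names[grepl("_Intercept$", spec$beta_names)]
  names(ic) <- icpt_names
  six <- c(spec$submodels, paste0("x_", c("p", "y"), "_", x))
  list(
    fixed_effects = fe,
    intercepts = c(ic, stats::setNames(rep(x_icpt, 2), six[5:6])),
    shape = stats::setNames(rep(2, 6), six),
    hurdle_prob = stats::setNames(rep(0.1, 6), six),
    re_sd = stats::setNames(rep(0.2, 10), spec$re_names)
  )
}

.fill_named <- function(user, def) {
  if (is.null(user)) return(def)
  bad <- setdiff(names(user), names(def))
  if (length(bad)) stop("unknown names: ", paste(bad, collapse = ", "))
  def[names(user)] <- user
  def
}

#' Generate synthetic parent-youth dyads
#'
#' Draws `config$n_dyads` complete dyads from the hurdle-gamma path process
#' described in [dyad_config()]. `days_since_event` is independent noise
#' (gamma, mean 416.75, SD 160.78) and never enters the models.
#'
#' @param config a [dyad_config()].
#' @return A data frame with columns `dyad_id`, `p_ptss`, `p_lack_cse`,
#'   `p_ccope_rev`, `y_ptss`, `y_lack_cse`, `y_ccope_rev`,
#'   `days_since_event`, with the generating configuration attached as
#'   attribute `"config"`.
#' @examples
#' d <- generate_dyads(dyad_config(n_dyads = 20, seed = 7))
#' nrow(d)
#' @export
generate_dyads <- function(config) {
  stopifnot(inherits(config, "dyad_generator_config"))
  spec <- config$spec
  n <- config$n_dyads
  cols <- c("dyad_id", "p_ptss", "p_lack_cse", "p_ccope_rev",
            "y_ptss", "y_lack_cse", "y_ccope_rev", "days_since_event")
  if (n == 0) {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), numeric(0), simplify = FALSE), cols))
    attr(out, "config") <- config
    return(out)
  }
  set.seed(config$seed)
  # dyad random effects: u = diag(sd) L z
  L <- t(chol(config$re_corr + diag(1e-10, 10)))
  z <- matrix(stats::rnorm(n * 10), n, 10)
  u <- (z %*% t(L)) %*% diag(config$re_sd)
  colnames(u) <- spec$re_names

  fe <- config$fixed_effects; ic <- config$intercepts
  sh <- config$shape; hu <- config$hurdle_prob
  x <- spec$x; med <- spec$mediator; outv <- spec$outcome

  vals <- list()
  zsc <- function(v) as.numeric(scale(v))
  for (m in c("p", "y")) {
    xm <- rhgamma(n, mu = exp(ic[[paste0("x_", m, "_", x)]]),
                  shape = sh[[paste0("x_", m, "_", x)]],
                  hu = hu[[paste0("x_", m, "_", x)]])
    zx <- zsc(xm)
    smed <- paste0(m, "_", med)
    eta_med <- ic[[paste0("b_", smed, "_Intercept")]] +
      (fe[[paste0("b_", smed, "_", x)]] + u[, paste0(m, "_", med, "_", x)]) * zx +
      u[, paste0(m, "_", med, "_Intercept")]
    medv <- rhgamma(n, mu = exp(eta_med), shape = sh[[smed]], hu = hu[[smed]])
    zm <- zsc(medv)
    sout <- paste0(m, "_", outv)
    eta_out <- ic[[paste0("b_", sout, "_Intercept")]] +
      (fe[[paste0("b_", sout, "_", x)]] +
         u[, paste0(m, "_", outv, "_", x)]) * zx +
      (fe[[paste0("b_", sout, "_", med)]] +
         u[, paste0(m, "_", outv, "_", med)]) * zm +
      u[, paste0(m, "_", outv, "_Intercept")]
    outy <- rhgamma(n, mu = exp(eta_out), shape = sh[[sout]], hu = hu[[sout]])
    vals[[paste0(m, "_", x)]] <- xm
    vals[[paste0(m, "_", med)]] <- medv
    vals[[paste0(m, "_", outv)]] <- outy
  }
  days <- stats::rgamma(n, shape = (416.75 / 160.78)^2,
                        rate = (416.75 / 160.78)^2 / 416.75)
  out <- data.frame(
    dyad_id = seq_len(n),
    p_ptss = vals$p_ptss, p_lack_cse = vals$p_lack_cse,
    p_ccope_rev = vals$p_ccope_rev,
    y_ptss = vals$y_ptss, y_lack_cse = vals$y_lack_cse,
    y_ccope_rev = vals$y_ccope_rev,
    days_since_event = days)
  attr(out, "config") <- config
  attr(out, "random_effects") <- u
  out
}

#' Mask analysis cells completely at random
#'
#' Each analysis-variable cell (the six PTSS / lack-CSE / communal-coping
#' columns) is independently set missing with probability `rate` (MCAR);
#' `dyad_id` and `days_since_event` are never masked.
#'
#' @param data a dyad data frame.
#' @param rate missingness probability in `[0, 1]`.
#' @param seed integer seed; deterministic under a fixed seed.
#' @return The data with `NA`s injected.
#' @export
inject_missingness <- function(data, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("'rate' must lie in [0, 1]")
  if (rate == 0) return(data)
  vars <- .analysis_vars()
  set.seed(seed)
  for (v in vars) {
    mask <- stats::runif(nrow(data)) < rate
    data[[v]][mask] <- NA_real_
  }
  data
}

.analysis_vars <- function() {
  c("p_ptss", "p_lack_cse", "p_ccope_rev",
    "y_ptss", "y_lack_cse", "y_ccope_rev")
}

#' Read and write dyad datasets
#'
#' CSV round-trip with empty cells for missing values.
#'
#' @param data a dyad data frame.
#' @param path file path.
#' @export
write_dyads <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dyads
#' @export
read_dyads <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA"))
}

#' Serialize a generator configuration to YAML
#'
#' @param config a [dyad_config()].
#' @param path file path.
#' @export
write_dyad_config <- function(config, path) {
  x <- config
  x$spec <- NULL
  x$re_corr <- apply(x$re_corr, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(lapply(x, function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v), path,
    precision = 15L)
  invisible(path)
}

#' @rdname write_dyad_config
#' @export
read_dyad_config <- function(path) {
  y <- yaml::read_yaml(path)
  dyad_config(
    n_dyads = y$n_dyads, topology = y$topology,
    fixed_effects = unlist(y$fixed_effects),
    intercepts = unlist(y$intercepts),
    shape = unlist(y$shape), hurdle_prob = unlist(y$hurdle_prob),
    re_sd = unlist(y$re_sd),
    re_corr = do.call(rbind, y$re_corr),
    missing_rate = y$missing_rate, seed = y$seed)
}
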