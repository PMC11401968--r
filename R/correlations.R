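#' Posterior random-effect correlations
#'
#' Reconstructs the 10 x 10 dyad-level random-effect correlation matrix from
#' each posterior draw of its Cholesky factor and summarizes every pairwise
#' entry: posterior mean, 95% credible interval, and a flag for intervals
#' excluding 0 (the "meaningful" correlations).
#'
#' @param fit a `dyadfit`.
#' @return A data frame (class `correlation_table`) with one row per
#'   random-effect pair.
#' @export
random_effect_correlations <- function(fit) {
  spec <- fit$spec
  d <- posterior_draws(fit, pars = spec$cor_names)
  labels <- do.call(rbind, strsplit(sub("^cor_", "", spec$cor_names), "__"))
  out <- data.frame(
    parameter_1 = .re_label(labels[, 2], spec),
    parameter_2 = .re_label(labels[, 1], spec),
    estimate = colMeans(d),
    lower = apply(d, 2, stats::quantile, 0.025),
    upper = apply(d, 2, stats::quantile, 0.975), row.names = NULL)
  out$excludes_zero <- out$lower > 0 | out$upper < 0
  class(out) <- c("correlation_table", "data.frame")
  out
}

# "p_ccope_rev_Intercept" -> "Parent CCOPE Intercept";
# "p_ccope_rev_ptss" -> "Parent CCOPE-Parent PTSS"
.re_label <- function(x, spec) {
  pretty_var <- c(ptss = "PTSS", lack_cse = "Lack of CSE",
                  ccope_rev = "CCOPE")
  vapply(x, function(s) {
    member <- if (startsWith(s, "p_")) "Parent" else "Youth"
    rest <- sub("^[py]_", "", s)
    for (v in names(pretty_var)) {
      if (startsWith(rest, v)) {
        dv <- pretty_var[[v]]
        tail <- sub(paste0("^", v, "_?"), "", rest)
        if (tail == "Intercept" || tail == "")
          return(paste(member, dv,
                       if (tail == "Intercept") "Intercept" else ""))
        return(paste0(member, " ", dv, "-", member, " ",
                      pretty_var[[tail]]))
      }
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.correlation_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- c("estimate", "lower", "upper")
  df[num] <- lapply(df[num], round, digits)
  df$` ` <- ifelse(df$excludes_zero, "*", "")
  df$excludes_zero <- NULL
  print(df, row.names = FALSE)
  cat("* 95% credible interval excludes 0\n")
  invisible(x)
}

#' Bayesian correlations among study variables
#'
#' Fits a multivariate-normal model to z-scored variables with intercepts
#' fixed at 0, residual scales fixed at 1, and a free correlation matrix
#' under an LKJ(1) prior, sampled with the package's NUTS. Variables listed
#' in `flip` have their reported correlations sign-flipped (and their labels
#' cleaned of the `lack_`/`_rev` markers) so tables can be read on the
#' original instrument coding.
#'
#' @param data dyad data frame (complete cases are used; at least 3
#'   required).
#' @param vars variables to correlate.
#' @param mcmc an [mcmc_config()]; default 4 chains x 2,000 iterations with
#'   1,000 warmup.
#' @param flip columns whose sign is restored to the original coding.
#' @return A list (class `bayesian_correlations`) with `table` (pairwise
#'   rows: estimate, 95% CI, exclusion flag) and `descriptives` (mean, SD on
#'   the analyzed coding).
#' @export
bayesian_correlations <- function(data,
                                  vars = c(.analysis_vars(),
                                           "days_since_event"),
                                  mcmc = mcmc_config(chains = 4, iter = 2000,
                                                     warmup = 1000),
                                  flip = c("p_lack_cse", "y_lack_cse",
                                           "p_ccope_rev", "y_ccope_rev")) {
  vars <- intersect(vars, names(data))
  X <- data[vars]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 complete dyads")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) stop("constant variable(s): ",
                          paste(vars[sds == 0], collapse = ", "))
  desc <- data.frame(variable = vars, mean = colMeans(X), sd = sds,
                     row.names = NULL)
  Z <- scale(as.matrix(X))
  K <- ncol(Z)
  p <- K * (K - 1) / 2
  draws <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    r <- nuts_corr_cpp(Z, rep(0, p), mcmc$iter, mcmc$warmup, mcmc$thin,
                       mcmc$max_treedepth, mcmc$adapt_delta,
                       mcmc$seed * 10000 + ch)
    draws[[ch]] <- r$draws
  }
  cor_draws <- lkj_corrs_cpp(do.call(rbind, draws), K)
  # sign restoration for reverse-coded variables
  sgn <- ifelse(vars %in% flip, -1, 1)
  labels <- sub("lack_cse", "cse", sub("_rev$", "", vars))
  labels <- sub("_lack_", "_", labels)
  idx <- 1L
  rows <- list()
  for (i in 2:K) for (j in 1:(i - 1)) {
    d <- cor_draws[, idx] * sgn[i] * sgn[j]
    rows[[idx]] <- data.frame(
      var_1 = labels[i], var_2 = labels[j], estimate = mean(d),
      lower = stats::quantile(d, 0.025), upper = stats::quantile(d, 0.975),
      row.names = NULL)
    idx <- idx + 1L
  }
  tab <- do.call(rbind, rows)
  tab$excludes_zero <- tab$lower > 0 | tab$upper < 0
  class(tab) <- c("correlation_table", "data.frame")
  structure(list(table = tab, descriptives = desc, n = nrow(X)),
            class = "bayesian_correlations")
}

#' @export
print.bayesian_correlations <- function(x, ...) {
  cat("Bayesian correlations (", x$n, " complete dyads)\n", sep = "")
  print(x$table)
  cat("\nDescriptives (analyzed coding):\n")
  d <- x$descriptives
  d$mean <- round(d$mean, 2); d$sd <- round(d$sd, 2)
  print(d, row.names = FALSE)
  invisible(x)
}
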