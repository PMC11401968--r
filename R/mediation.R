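#' Mediation-product posterior
#'
#' The indirect effect of the exogenous variable through lack of CSE is the
#' per-draw product `a * b` of the path into the mediator (exogenous ->
#' lack of CSE) and the path out of it (lack of CSE -> outcome), preserving
#' the posterior dependence between the two coefficients.
#'
#' @param fit a `dyadfit`.
#' @param member `"parent"` or `"youth"`.
#' @return A `mediation_summary` with the product draws, point summaries,
#'   and an `exceedance(c)` helper.
#' @export
mediation_product <- function(fit, member = c("parent", "youth")) {
  member <- match.arg(member)
  m <- if (member == "parent") "p" else "y"
  spec <- fit$spec
  a_name <- paste0("b_", m, "_", spec$mediator, "_", spec$x)
  b_name <- paste0("b_", m, "_", spec$outcome, "_", spec$mediator)
  d <- posterior_draws(fit, pars = c(a_name, b_name))
  prod <- d[, 1] * d[, 2]
  structure(list(
    member = member, a = a_name, b = b_name, product_draws = prod,
    mean = mean(prod), median = stats::median(prod),
    ci = stats::quantile(prod, c(0.025, 0.975))),
    class = "mediation_summary")
}

#' @export
print.mediation_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Mediation product for %s (%s x %s)\n", x$member, x$a, x$b))
  cat(sprintf("  mean %.3f, median %.3f, 95%% CI [%.3f, %.3f]\n",
              x$mean, x$median, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Exceedance probabilities of the mediation effect
#'
#' For each threshold `c`, the fraction of mediation-product draws strictly
#' greater than `c` (ties have probability zero under continuous draws).
#'
#' @param summary a [mediation_product()] result.
#' @param thresholds increasing numeric vector.
#' @return A data frame `(threshold, probability)`; monotone nonincreasing.
#' @export
exceedance_curve <- function(summary, thresholds = seq(0, 0.1, by = 0.005)) {
  stopifnot(inherits(summary, "mediation_summary"))
  if (!length(summary$product_draws)) stop("no product draws")
  if (is.unsorted(thresholds, strictly = FALSE))
    stop("'thresholds' must be sorted ascending")
  prob <- vapply(thresholds,
                 function(c) mean(summary$product_draws > c), numeric(1))
  data.frame(threshold = thresholds, probability = prob)
}

#' Parent-youth difference in the mediation effect
#'
#' Per-draw youth product minus parent product, with the posterior
#' probability `p` of a positive difference and the one-sided evidence ratio
#' `p / (1 - p)`.
#'
#' @param fit a `dyadfit`.
#' @return A `member_difference` list.
#' @export
member_difference <- function(fit) {
  py <- mediation_product(fit, "youth")$product_draws
  pp <- mediation_product(fit, "parent")$product_draws
  d <- py - pp
  # midpoint convention for ties, so identical members give p = 0.5
  p <- mean(d > 0) + 0.5 * mean(d == 0)
  structure(list(
    mean = mean(d), ci = stats::quantile(d, c(0.025, 0.975)),
    prob_positive = p,
    evidence_ratio = if (p == 1) Inf else p / (1 - p),
    draws = d), class = "member_difference")
}

#' @export
print.member_difference <- function(x, ...) {
  cat("Youth - parent mediation-effect difference\n")
  cat(sprintf(
    "  mean %.3f, 95%% CI [%.3f, %.3f], P(>0) = %.3f, evidence ratio %.2f\n",
    x$mean, x$ci[1], x$ci[2], x$prob_positive, x$evidence_ratio))
  invisible(x)
}

#' Plot exceedance curves
#'
#' @param fit a `dyadfit`.
#' @param thresholds threshold grid.
#' @export
plot_exceedance <- function(fit, thresholds = seq(0, 0.1, by = 0.002)) {
  cp <- exceedance_curve(mediation_product(fit, "parent"), thresholds)
  cy <- exceedance_curve(mediation_product(fit, "youth"), thresholds)
  graphics::plot(cp$threshold, cp$probability, type = "l", lwd = 2,
                 xlab = "mediation coefficient", ylab = "P(product > c)",
                 ylim = c(0, 1), col = "firebrick")
  graphics::lines(cy$threshold, cy$probability, lwd = 2, col = "steelblue")
  graphics::legend("topright", c("parent", "youth"), lwd = 2,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(list(parent = cp, youth = cy))
}
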