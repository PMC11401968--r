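#' The hurdle-gamma distribution
#'
#' Two-part law for nonnegative, positively skewed scores with a point mass at
#' zero: with probability `hu` the value is exactly 0, otherwise it follows a
#' gamma distribution with shape `shape` and mean `mu` (so rate =
#' `shape / mu`). This is the outcome family used throughout the dyadic path
#' models, where `mu = exp(eta)` under the log link.
#'
#' @param x,y vector of quantiles (nonnegative).
#' @param mu positive mean of the gamma component.
#' @param shape positive gamma shape.
#' @param hu zero point-mass probability in `[0, 1)`.
#' @param log logical; return log density?
#' @param n number of draws.
#' @return `dhgamma` the (log) density, `phgamma` the CDF, `rhgamma` draws,
#'   `hurdle_gamma_logpdf` the log density (always on the log scale).
#' @examples
#' hurdle_gamma_logpdf(0, mu = 1, shape = 2, hu = 0.2) # log(0.2)
#' integrate(function(y) dhgamma(y, 1.5, 2, 0.1), 0, Inf)$value + 0.1
#' @name hurdle_gamma
NULL

.check_hg_pars <- function(mu, shape, hu) {
  if (any(mu <= 0)) stop("'mu' must be positive")
  if (any(shape <= 0)) stop("'shape' must be positive")
  if (any(hu < 0 | hu >= 1)) stop("'hu' must lie in [0, 1)")
}

#' @rdname hurdle_gamma
#' @export
dhgamma <- function(x, mu, shape, hu, log = FALSE) {
  .check_hg_pars(mu, shape, hu)
  if (any(x < 0)) stop("hurdle-gamma support is [0, Inf)")
  n <- max(length(x), length(mu), length(shape), length(hu))
  x <- rep_len(x, n); mu <- rep_len(mu, n)
  shape <- rep_len(shape, n); hu <- rep_len(hu, n)
  out <- ifelse(x == 0, log(hu),
                log1p(-hu) + stats::dgamma(x, shape = shape,
                                           rate = shape / mu, log = TRUE))
  if (log) out else exp(out)
}

#' @rdname hurdle_gamma
#' @export
phgamma <- function(x, mu, shape, hu) {
  .check_hg_pars(mu, shape, hu)
  ifelse(x < 0, 0,
         hu + (1 - hu) * stats::pgamma(x, shape = shape, rate = shape / mu))
}

#' @rdname hurdle_gamma
#' @export
rhgamma <- function(n, mu, shape, hu) {
  .check_hg_pars(mu, shape, hu)
  y <- stats::rgamma(n, shape = shape, rate = shape / mu)
  y[stats::runif(n) < hu] <- 0
  y
}

#' @rdname hurdle_gamma
#' @export
hurdle_gamma_logpdf <- function(y, mu, shape, hu) {
  dhgamma(y, mu, shape, hu, log = TRUE)
}
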