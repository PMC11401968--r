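# Rank-normalized split R-hat and bulk/tail effective sample sizes,
# following the rank-normalization recommendations for MCMC diagnostics.

.split_chains <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  cbind(x[seq_len(half), , drop = FALSE],
        x[seq.int(n - half + 1, n), , drop = FALSE])
}

.rank_normalize <- function(x) {
  r <- rank(as.numeric(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

# basic split-free R-hat on an iterations x chains matrix
.rhat_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  cm <- colMeans(x)
  w <- mean(apply(x, 2, stats::var))
  b <- n * stats::var(cm)
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# Geyer initial-monotone-sequence ESS on an iterations x chains matrix
.ess_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  chain_var <- apply(x, 2, stats::var)
  if (all(!is.finite(chain_var)) || all(chain_var == 0)) return(NA_real_)
  acov <- sapply(seq_len(m), function(k) {
    if (!is.finite(chain_var[k]) || chain_var[k] == 0) return(rep(0, n))
    v <- x[, k] - mean(x[, k])
    na <- stats::nextn(2 * n)
    f <- stats::fft(c(v, rep(0, na - n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:n] / na
    ac / ac[1] * chain_var[k] * (n - 1) / n
  })
  mean_var <- mean(chain_var) * (n - 1) / n
  var_plus <- mean_var
  if (m > 1) var_plus <- var_plus + stats::var(colMeans(x))
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # paired sums, initial positive + monotone
  maxpair <- floor(n / 2) - 1
  p <- numeric(0)
  for (t in 0:maxpair) {
    pt <- rho[2 * t + 1] + if (2 * t + 2 <= n) rho[2 * t + 2] else 0
    if (!is.finite(pt)) break
    if (t > 0 && pt <= 0) break
    p <- c(p, pt)
  }
  if (length(p) > 1) p <- cummin(p)
  tau <- -1 + 2 * sum(p)
  # antithetic chains can drive tau below 1; regularize as is standard
  tau <- max(tau, 1 / log10(m * n))
  m * n / tau
}

#' MCMC convergence measures
#'
#' `rhat()` is the rank-normalized split R-hat (the maximum of the bulk and
#' the folded, median-absolute-deviation version). `ess_bulk()` is the
#' effective sample size of the rank-normalized split chains; `ess_tail()`
#' the minimum ESS of the 5% and 95% quantile indicators.
#'
#' @param x an iterations x chains numeric matrix.
#' @return A scalar; `NA` for zero-variance chains.
#' @export
rhat <- function(x) {
  x <- .split_chains(x)
  if (stats::sd(as.numeric(x)) == 0) return(NA_real_)
  z <- .rank_normalize(x)
  folded <- .rank_normalize(matrix(abs(as.numeric(x) -
                                         stats::median(x)), nrow(x), ncol(x)))
  max(.rhat_basic(z), .rhat_basic(folded))
}

#' @rdname rhat
#' @export
ess_bulk <- function(x) {
  x <- .split_chains(x)
  if (stats::sd(as.numeric(x)) == 0) return(NA_real_)
  .ess_basic(.rank_normalize(x))
}

#' @rdname rhat
#' @export
ess_tail <- function(x) {
  x <- .split_chains(x)
  if (stats::sd(as.numeric(x)) == 0) return(NA_real_)
  ess_q <- sapply(c(0.05, 0.95), function(p) {
    ind <- (x <= stats::quantile(as.numeric(x), p)) * 1
    if (stats::sd(as.numeric(ind)) == 0) return(NA_real_)
    .ess_basic(ind)
  })
  min(ess_q, na.rm = TRUE)
}

#' Convergence report for a fitted model
#'
#' Per-parameter rank-normalized split R-hat, bulk ESS, and tail ESS with
#' pass flags: R-hat <= 1.01, bulk ESS > 100 x chains, and tail ESS > 10% of
#' the total post-warmup draws. Zero-variance parameters are flagged, not
#' fatal.
#'
#' @param fit a `dyadfit`, or a 3-d array (draw, chain, parameter).
#' @param params optional parameter subset.
#' @return A data frame (class `diagnostics_report`) with attributes
#'   `thresholds` and `all_pass`.
#' @export
convergence_report <- function(fit, params = NULL) {
  if (inherits(fit, "dyadfit")) {
    chains <- length(fit$draws)
    total <- chains * nrow(fit$draws[[1]])
    arr <- posterior_draws(fit, merge_chains = FALSE)
  } else {
    arr <- fit
    chains <- dim(arr)[2]
    total <- dim(arr)[1] * chains
  }
  if (chains < 2) stop("need at least 2 chains")
  pars <- params %||% dimnames(arr)[[3]]
  rows <- lapply(pars, function(p) {
    m <- arr[, , p]
    data.frame(parameter = p, rhat = rhat(m), bulk_ess = ess_bulk(m),
               tail_ess = ess_tail(m))
  })
  out <- do.call(rbind, rows)
  out$rhat_ok <- !is.na(out$rhat) & out$rhat <= 1.01
  out$bulk_ok <- !is.na(out$bulk_ess) & out$bulk_ess > 100 * chains
  out$tail_ok <- !is.na(out$tail_ess) & out$tail_ess > 0.10 * total
  out$degenerate <- is.na(out$rhat)
  attr(out, "thresholds") <- c(rhat = 1.01, bulk_ess = 100 * chains,
                               tail_ess = 0.10 * total)
  attr(out, "all_pass") <- all(out$rhat_ok & out$bulk_ok & out$tail_ok |
                                 out$degenerate)
  class(out) <- c("diagnostics_report", "data.frame")
  out
}

#' @export
print.diagnostics_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "Convergence gates: R-hat <= %.2f, bulk ESS > %g, tail ESS > %g\n",
    th["rhat"], th["bulk_ess"], th["tail_ess"]))
  df <- as.data.frame(x)
  df$rhat <- round(df$rhat, 3)
  df$bulk_ess <- round(df$bulk_ess)
  df$tail_ess <- round(df$tail_ess)
  print(df, row.names = FALSE)
  cat(if (attr(x, "all_pass")) "All parameters pass.\n"
      else "Some parameters FAIL the gates.\n")
  invisible(x)
}
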