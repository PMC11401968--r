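#' Drop dyads with no usable responses
#'
#' Removes dyads in which either member is missing all three analysis
#' measures (PTSS, lack of CSE, communal coping); dyads with any observed
#' analysis value for both members are kept.
#'
#' @param data a dyad data frame.
#' @return A list with `data` (retained rows) and `excluded` (count
#'   dropped).
#' @export
exclude_incomplete <- function(data) {
  p_all_na <- rowSums(!is.na(data[c("p_ptss", "p_lack_cse", "p_ccope_rev")])) == 0
  y_all_na <- rowSums(!is.na(data[c("y_ptss", "y_lack_cse", "y_ccope_rev")])) == 0
  drop <- p_all_na | y_all_na
  kept <- data[!drop, , drop = FALSE]
  if (nrow(kept) == 0) warning("all dyads excluded")
  list(data = kept, excluded = sum(drop))
}

#' Random-forest imputation of missing analysis values
#'
#' Chained per-variable imputation with regression forests (via
#' \pkg{ranger}), run jointly over the dyad-wide variable block so each
#' member's values inform the other's. Missing cells are initialized at
#' column means; variables are revisited in order of increasing missingness
#' until the relative change in imputed values falls below `tol` or
#' `max_iter` sweeps. Deterministic under a fixed seed.
#'
#' @param data a dyad data frame (post-exclusion).
#' @param seed integer seed.
#' @param num_trees trees per forest.
#' @param tol relative-change stopping tolerance.
#' @param max_iter maximum sweeps.
#' @return The data with all analysis cells filled.
#' @export
impute_missing <- function(data, seed = 1L, num_trees = 100L,
                           tol = 1e-4, max_iter = 10L) {
  vars <- intersect(.analysis_vars(), names(data))
  block <- data[vars]
  n_na <- vapply(block, function(v) sum(is.na(v)), integer(1))
  fully <- names(n_na)[n_na == nrow(data)]
  if (length(fully))
    stop("variable(s) fully missing, cannot impute: ",
         paste(fully, collapse = ", "))
  if (sum(n_na) == 0) return(data)
  na_idx <- lapply(block, function(v) which(is.na(v)))
  for (v in vars) {
    block[[v]][na_idx[[v]]] <- mean(block[[v]], na.rm = TRUE)
  }
  order_vars <- names(sort(n_na))
  order_vars <- order_vars[n_na[order_vars] > 0]
  prev <- unlist(lapply(vars, function(v) block[[v]][na_idx[[v]]]))
  for (it in seq_len(max_iter)) {
    for (v in order_vars) {
      obs <- setdiff(seq_len(nrow(block)), na_idx[[v]])
      fit <- ranger::ranger(
        x = block[obs, setdiff(vars, v), drop = FALSE],
        y = block[[v]][obs],
        num.trees = num_trees, seed = seed + it, num.threads = 1)
      pred <- stats::predict(
        fit, data = block[na_idx[[v]], setdiff(vars, v), drop = FALSE],
        num.threads = 1)$predictions
      block[[v]][na_idx[[v]]] <- pred
    }
    cur <- unlist(lapply(vars, function(v) block[[v]][na_idx[[v]]]))
    delta <- sum((cur - prev)^2) / max(sum(cur^2), .Machine$double.eps)
    prev <- cur
    if (delta < tol) break
  }
  data[vars] <- block
  data
}

#' Z-score the covariate versions of the analysis variables
#'
#' Adds `z_`-prefixed columns holding each analysis variable standardized to
#' sample mean 0 and SD 1; the original (hurdle-gamma scale) outcome columns
#' are untouched. The centers and scales are attached as attributes.
#'
#' @param data a complete dyad data frame.
#' @return The data with added `z_*` columns.
#' @export
standardize_predictors <- function(data) {
  vars <- intersect(.analysis_vars(), names(data))
  centers <- scales <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    if (anyNA(data[[v]]))
      stop("missing values in ", v, "; run impute_missing() first")
    s <- stats::sd(data[[v]])
    if (!is.finite(s) || s == 0) stop("zero-variance column: ", v)
    centers[v] <- mean(data[[v]]); scales[v] <- s
    data[[paste0("z_", v)]] <- (data[[v]] - centers[v]) / s
  }
  attr(data, "centers") <- centers
  attr(data, "scales") <- scales
  data
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: (score if item-level) -> exclude all-missing dyads -> impute
#' -> (reverse-code if original coding) -> standardize predictors. Synthetic
#' data from [generate_dyads()] is already on the reversed coding, so
#' `reverse_vars` defaults to none.
#'
#' @param data dyad data frame on the analysis schema.
#' @param seed seed passed to [impute_missing()].
#' @param reverse_vars named numeric vector mapping column names to their
#'   scale maxima for reverse coding (e.g. `c(p_cse = 7)`), applied after
#'   imputation.
#' @return A list with `data` (analysis-ready), `excluded`, and `log` (the
#'   ordered step record).
#' @export
preprocess_dyads <- function(data, seed = 1L, reverse_vars = NULL) {
  log <- character()
  ex <- exclude_incomplete(data)
  log <- c(log, sprintf("exclude: dropped %d all-missing dyads, kept %d",
                        ex$excluded, nrow(ex$data)))
  dat <- ex$data
  n_missing <- sum(is.na(dat[intersect(.analysis_vars(), names(dat))]))
  dat <- impute_missing(dat, seed = seed)
  log <- c(log, sprintf("impute: random-forest imputation of %d cells",
                        n_missing))
  if (!is.null(reverse_vars)) {
    for (v in names(reverse_vars)) {
      dat[[v]] <- reverse_code(dat[[v]], reverse_vars[[v]])
    }
    log <- c(log, paste("reverse-code:", paste(names(reverse_vars),
                                               collapse = ", ")))
  }
  dat <- standardize_predictors(dat)
  log <- c(log, "standardize: z-scored covariate columns added")
  list(data = dat, excluded = ex$excluded, log = log)
}
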