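#' Questionnaire scale definitions
#'
#' Built-in registry covering the four instruments: the 4-item Communal
#' Coping Scale and the 12-item trauma coping self-efficacy scale (1-7,
#' averaged), and the 6-item parent / 8-item youth posttraumatic stress
#' scales (0-4, summed).
#'
#' @param name scale identifier.
#' @param n_items number of items (>= 2).
#' @param item_range length-2 numeric `(min, max)` of the response scale.
#' @param aggregation `"mean"` or `"sum"`.
#' @return A `scale_definition` object.
#' @export
scale_def <- function(name, n_items, item_range, aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  stopifnot(n_items >= 2, length(item_range) == 2,
            item_range[1] < item_range[2])
  structure(list(name = name, n_items = as.integer(n_items),
                 item_range = as.numeric(item_range),
                 aggregation = aggregation),
            class = "scale_definition")
}

#' @rdname scale_def
#' @export
scale_registry <- function() {
  list(
    ccs = scale_def("ccs", 4, c(1, 7), "mean"),
    cse_t = scale_def("cse_t", 12, c(1, 7), "mean"),
    ies6 = scale_def("ies6", 6, c(0, 4), "sum"),
    cries8 = scale_def("cries8", 8, c(0, 4), "sum")
  )
}

#' Read and write a scale-definition registry as YAML
#'
#' @param registry named list of [scale_def()] objects.
#' @param path file path.
#' @export
write_scale_registry <- function(registry, path) {
  yaml::write_yaml(lapply(registry, function(d)
    list(name = d$name, n_items = d$n_items,
         item_range = as.list(d$item_range), aggregation = d$aggregation)),
    path)
  invisible(path)
}

#' @rdname write_scale_registry
#' @export
read_scale_registry <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(d)
    scale_def(d$name, d$n_items, unlist(d$item_range), d$aggregation))
}

#' Score a questionnaire scale
#'
#' Mean scales average the available items; sum scales return the prorated
#' sum `sum(available) * n_items / n_available`. Respondents with all items
#' missing get `NA`.
#'
#' @param items numeric matrix or data frame, one row per respondent, one
#'   column per item; values within the scale's response range or `NA`.
#' @param definition a [scale_def()].
#' @return Numeric score vector, one per respondent.
#' @examples
#' score_scale(matrix(7, 3, 4), scale_def("ccs", 4, c(1, 7), "mean"))
#' @export
score_scale <- function(items, definition) {
  stopifnot(inherits(definition, "scale_definition"))
  items <- as.matrix(items)
  if (ncol(items) != definition$n_items)
    stop("expected ", definition$n_items, " items, got ", ncol(items))
  rng <- definition$item_range
  bad <- which(!is.na(items) & (items < rng[1] | items > rng[2]),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("item value out of range [%g, %g] at row %d, item %d",
                 rng[1], rng[2], bad[1, 1], bad[1, 2]))
  k <- rowSums(!is.na(items))
  m <- rowMeans(items, na.rm = TRUE)
  out <- if (definition$aggregation == "mean") m else m * definition$n_items
  out[k == 0] <- NA_real_
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability from the classical variance
#' decomposition: `alpha = k/(k-1) * (1 - sum(item variances) / var(total))`,
#' computed on complete cases.
#'
#' @param items numeric matrix/data frame of item responses.
#' @return A list (class `reliability_report`) with `alpha`,
#'   `n_respondents`, and `n_items`.
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' cronbach_alpha(x + rnorm(100))$alpha  # shared variance raises alpha
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2) stop("need at least 2 items")
  cc <- stats::complete.cases(items)
  if (sum(cc) < 3) stop("need at least 3 complete respondents")
  x <- items[cc, , drop = FALSE]
  tot <- rowSums(x)
  vt <- stats::var(tot)
  if (vt == 0) stop("total-score variance is zero; alpha undefined")
  alpha <- k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / vt)
  structure(list(alpha = alpha, n_respondents = sum(cc), n_items = k),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d items, %d complete respondents)\n",
              x$alpha, x$n_items, x$n_respondents))
  invisible(x)
}

#' Reverse-code a scale score
#'
#' Returns `scale_max - score`, so a ceiling response maps to exactly 0 --
#' the zero point mass the hurdle-gamma outcome family models. Used to turn
#' the negatively skewed CSE and communal-coping scores into positively
#' skewed "lack of CSE" and reverse-coded communal-coping variables.
#'
#' @param score numeric score(s), each `<= scale_max`.
#' @param scale_max scale ceiling.
#' @export
reverse_code <- function(score, scale_max) {
  if (any(score > scale_max, na.rm = TRUE))
    stop("score exceeds 'scale_max'")
  scale_max - score
}

#' Simulate equal-loading item responses
#'
#' A deliberately simple one-factor item simulator for reliability tests:
#' each item is `sqrt(rho) * common + sqrt(1 - rho) * unique` on a latent
#' normal scale, shifted to the middle of the response range and truncated
#' to it. It does not attempt realistic inter-item structure.
#'
#' @param n respondents.
#' @param definition a [scale_def()].
#' @param rho common-factor loading squared (0 = independent items,
#'   1 = identical items up to truncation).
#' @param seed integer seed.
#' @export
simulate_scale_items <- function(n, definition, rho = 0.6, seed = 1L) {
  stopifnot(rho >= 0, rho <= 1)
  set.seed(seed)
  common <- stats::rnorm(n)
  rng <- definition$item_range
  mid <- mean(rng); spread <- diff(rng) / 6
  items <- sapply(seq_len(definition$n_items), function(j)
    sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(n))
  items <- mid + spread * items
  items[items < rng[1]] <- rng[1]
  items[items > rng[2]] <- rng[2]
  colnames(items) <- paste0(definition$name, "_", seq_len(definition$n_items))
  items
}
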