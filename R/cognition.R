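#' Mean-impute missing cognition scores
#'
#' Each missing cell is replaced by the arithmetic mean of the observed
#' values of its dimension, computed over `fit_rows` (default: all rows).
#' Restricting `fit_rows` to a training split keeps fold evaluation
#' leakage-free; passing all rows reproduces whole-cohort imputation.
#' Observed cells are never touched, so the per-dimension observed mean is
#' preserved exactly.
#'
#' @param scores subjects x 6 numeric matrix (`NA` = missing), as returned
#'   by [score_table()].
#' @param fit_rows indices (or logical mask) of the rows whose observed
#'   values define the imputation means; default all rows.
#' @return the matrix with no `NA` cells.
#' @export
impute_missing <- function(scores, fit_rows = NULL) {
  fit_rows <- fit_rows %||% seq_len(nrow(scores))
  out <- scores
  for (j in seq_len(ncol(scores))) {
    obs <- scores[fit_rows, j]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0) {
      abort(sprintf("dimension '%s' has no observed value in the fit set",
                    colnames(scores)[j]),
            class = "epcog_imputation_error")
    }
    miss <- is.na(out[, j])
    out[miss, j] <- mean(obs)
  }
  out
}

#' Fit an equal-width binning scheme for cognitive-level classes
#'
#' Each dimension's observed range \[min, max\] is divided into `n` equal
#' parts; because ranges differ between dimensions, so do the interval
#' widths. The scheme is fitted on (imputed) scores from a chosen subject
#' set and then applied to any score via [apply_binning()].
#'
#' @param scores imputed subjects x dimensions matrix (no `NA`).
#' @param n number of categories (>= 2).
#' @return a `binning_scheme`: tibble with `dimension`, `min`, `max`, `n`
#'   and an `edges` list-column of the n+1 ascending bin edges.
#' @export
fit_binning <- function(scores, n) {
  n <- as.integer(n)
  if (n < 2L) abort("`n` must be at least 2", class = "epcog_argument_error")
  if (anyNA(scores)) {
    abort("scores must be imputed before binning", class = "epcog_argument_error")
  }
  dims <- colnames(scores) %||% paste0("dim", seq_len(ncol(scores)))
  lo <- apply(scores, 2, min)
  hi <- apply(scores, 2, max)
  if (any(hi <= lo)) {
    abort(sprintf("degenerate range (max = min) in dimension(s): %s",
                  paste(dims[hi <= lo], collapse = ", ")),
          class = "epcog_degenerate_error")
  }
  edges <- purrr::map2(unname(lo), unname(hi),
                       function(a, b) seq(a, b, length.out = n + 1L))
  scheme <- tibble(
    dimension = dims, min = unname(lo), max = unname(hi), n = n,
    edges = edges
  )
  structure(scheme, class = c("binning_scheme", class(tibble())))
}

#' Map scores to cognitive-level categories
#'
#' Category `k` (1-based) covers `edges[k] <= score < edges[k+1]`; a score
#' exactly on an interior edge goes to the upper bin, the maximum falls in
#' the top bin, and out-of-range scores (possible at inference time) clamp
#' to the end bins.
#'
#' @param scheme a [fit_binning()] scheme.
#' @param score numeric vector of scores.
#' @param dimension dimension name (must exist in the scheme).
#' @return integer categories in `1..n`.
#' @export
apply_binning <- function(scheme, score, dimension) {
  i <- match(dimension, scheme$dimension)
  if (is.na(i)) {
    abort(sprintf("unknown dimension '%s'", dimension), class = "epcog_key_error")
  }
  if (any(!is.finite(score))) {
    abort("scores must be finite", class = "epcog_argument_error")
  }
  edges <- scheme$edges[[i]]
  pmin(pmax(findInterval(score, edges), 1L), scheme$n[i])
}

#' Bin a whole score matrix
#'
#' @inheritParams apply_binning
#' @param scores imputed subjects x dimensions matrix with column names
#'   matching the scheme.
#' @return integer matrix of categories, same shape as `scores`.
#' @export
bin_scores <- function(scheme, scores) {
  out <- matrix(NA_integer_, nrow(scores), ncol(scores),
                dimnames = dimnames(scores))
  for (d in colnames(scores)) {
    out[, d] <- apply_binning(scheme, scores[, d], d)
  }
  out
}

#' Standardize scores for the regression head
#'
#' Per-dimension z-scoring, `z = (score - mean) / sd`, with the statistics
#' computed on `fit_rows` so held-out subjects are transformed with
#' training statistics only. [invert_scores()] restores original units,
#' which is how regression error is reported.
#'
#' @inheritParams impute_missing
#' @return list with `z` (standardized matrix), `mean` and `sd`
#'   (per-dimension named vectors).
#' @export
standardize_scores <- function(scores, fit_rows = NULL) {
  fit_rows <- fit_rows %||% seq_len(nrow(scores))
  mu <- apply(scores[fit_rows, , drop = FALSE], 2, mean)
  # population (1/n) standard deviation
  sg <- sqrt(apply(scores[fit_rows, , drop = FALSE], 2,
                   function(v) mean((v - mean(v))^2)))
  if (any(!is.finite(sg)) || any(sg <= 0)) {
    abort(sprintf("zero-variance dimension(s): %s",
                  paste(colnames(scores)[!is.finite(sg) | sg <= 0], collapse = ", ")),
          class = "epcog_degenerate_error")
  }
  z <- sweep(sweep(scores, 2, mu, "-"), 2, sg, "/")
  list(z = z, mean = mu, sd = sg)
}

#' @rdname standardize_scores
#' @param z standardized matrix (or vector laid out as one row per subject).
#' @param stats the list returned by [standardize_scores()].
#' @export
invert_scores <- function(z, stats) {
  sweep(sweep(z, 2, stats$sd, "*"), 2, stats$mean, "+")
}
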