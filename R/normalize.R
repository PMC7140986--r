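#' Fit a z-score normaliser on a reference subset
#'
#' Per-feature mean and standard deviation are computed on the reference rows
#' only (in the grading pipeline: the AD and NC subjects), and later applied
#' unchanged to every partition, so the MCI rows are expressed on the
#' reference scale. The SD uses the population convention (divisor `N`);
#' either convention would do, this one is fixed for reproducibility.
#'
#' @param block A [feature_block()].
#' @param reference_rows Integer or logical index of the rows to fit on
#'   (at least 2).
#' @param fitted_on Short descriptor of the reference set, kept for audit.
#' @return An object of class `normalizer` with fields `mean`, `sd` (both
#'   length `M`, named by feature) and `fitted_on`.
#' @export
fit_normalizer <- function(block, reference_rows,
                           fitted_on = "reference rows") {
  stopifnot(inherits(block, "feature_block"))
  x <- block$values[reference_rows, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 reference rows to fit a normalizer")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2L, mu)^2))  # population SD, divisor N
  if (any(sdv == 0)) {
    stop("constant feature(s) on reference rows: ",
         paste(block$feature_names[sdv == 0], collapse = ", "))
  }
  names(mu) <- names(sdv) <- block$feature_names
  structure(list(mean = mu, sd = sdv, fitted_on = fitted_on),
            class = "normalizer")
}

#' @export
print.normalizer <- function(x, ...) {
  cat("<normalizer> ", length(x$mean), " features, fitted on ", x$fitted_on,
      "\n", sep = "")
  invisible(x)
}

#' Apply (or invert) a fitted normaliser
#'
#' Transforms every value to `(value - mean) / sd` using the parameters
#' stored in `params`, identically for reference and held-out rows. With
#' `invert = TRUE` the transform is undone, `value * sd + mean`.
#'
#' @param params A `normalizer` from [fit_normalizer()].
#' @param block A [feature_block()] with the same number of features.
#' @param invert Logical; undo the transform instead of applying it.
#' @return A [feature_block()] with transformed values.
#' @export
apply_normalizer <- function(params, block, invert = FALSE) {
  stopifnot(inherits(params, "normalizer"), inherits(block, "feature_block"))
  if (ncol(block$values) != length(params$mean)) {
    stop("block has ", ncol(block$values), " features but normalizer was ",
         "fitted on ", length(params$mean))
  }
  v <- if (invert) {
    sweep(sweep(block$values, 2L, params$sd, "*"), 2L, params$mean, "+")
  } else {
    sweep(sweep(block$values, 2L, params$mean), 2L, params$sd, "/")
  }
  feature_block(v, block$modality_name, block$feature_names)
}
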