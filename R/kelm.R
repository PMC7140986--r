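#' Gaussian kernel between two feature vectors
#'
#' `K(u, v) = exp(-||u - v||^2 / gamma)`. Note the width convention: the
#' squared Euclidean distance is divided by `gamma` directly (no factor 2,
#' no square), matching the grading model in which `gamma` defaults to ten
#' times the feature count.
#'
#' @param u,v Numeric vectors of equal length.
#' @param gamma Positive kernel width.
#' @return A scalar in `(0, 1]`.
#' @export
gaussian_kernel <- function(u, v, gamma) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("gamma must be a single positive number")
  }
  exp(-sum((u - v)^2) / gamma)
}

#' Gaussian kernel matrix of a sample set
#'
#' Computes the `N x N` matrix with entries `K(x_i, x_j, gamma)`; symmetric
#' with unit diagonal.
#'
#' @param X Numeric matrix, one sample per row.
#' @param gamma Positive kernel width.
#' @return An `N x N` symmetric matrix with unit diagonal.
#' @export
kernel_matrix <- function(X, gamma) {
  X <- as.matrix(X)
  K <- .cross_kernel(X, X, gamma)
  K <- (K + t(K)) / 2  # enforce exact symmetry against rounding
  diag(K) <- 1
  K
}

# Rectangular kernel block K[i, j] = K(A[i, ], B[j, ]); distances via the
# expansion |a|^2 + |b|^2 - 2 a.b, clipped at 0 against cancellation error.
.cross_kernel <- function(A, B, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("gamma must be a single positive number")
  }
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / gamma)
}

#' Fit a kernel extreme learning machine
#'
#' Two-class kernel ELM with Gaussian kernel. Training is a single
#' deterministic linear solve: with `Y` the `N x 2` label matrix whose row
#' for a sample carries `+1` in its own class channel and `-1` in the other,
#' the output weights are
#' \deqn{\beta = (\Omega + I/C)^{-1} Y,}
#' where `Omega` is the training kernel matrix. Prediction of a new point
#' `x` is `f(x) = [K(x, x_1), ..., K(x, x_N)] \beta`, a two-channel score;
#' per channel this is exactly kernel ridge regression with ridge `1/C`.
#' The solve uses a Cholesky factorisation (`Omega` is PSD and `I/C` makes
#' the system positive definite), never an explicit inverse; there are no
#' random hidden weights, so refitting the same data is bitwise
#' reproducible.
#'
#' @param x Numeric training matrix, one sample per row.
#' @param y Class labels (factor or character), exactly two classes.
#' @param C Positive regularisation coefficient; the reference value is 1.
#' @param gamma Positive Gaussian kernel width; defaults to `10 * ncol(x)`,
#'   tying the kernel scale to the input dimension.
#' @param class_order Length-2 character vector `(positive, negative)`
#'   fixing the channel order; defaults to the factor levels of `y`. The
#'   grading score [predict.kelm()] returns is positive when the model leans
#'   towards `class_order[1]`.
#' @return An object of class `kelm`: list with `train_x`, `coef` (`N x 2`),
#'   `gamma`, `C`, `class_order`.
#' @examples
#' x <- rbind(matrix(rnorm(20, -1), 10), matrix(rnorm(20, 1), 10))
#' m <- kelm(x, rep(c("NC", "AD"), each = 10), class_order = c("AD", "NC"))
#' predict(m, x[1:2, ], type = "grade")
#' @export
kelm <- function(x, y, C = 1, gamma = NULL, class_order = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (!is.numeric(C) || length(C) != 1 || C <= 0) {
    stop("C must be a single positive number")
  }
  classes <- unique(y)
  if (length(classes) != 2) {
    stop("kelm requires exactly 2 classes, got: ",
         paste(classes, collapse = ", "))
  }
  if (is.null(class_order)) class_order <- sort(classes)
  if (!setequal(class_order, classes) || length(class_order) != 2) {
    stop("class_order must be a permutation of the two classes in y")
  }
  if (is.null(gamma)) gamma <- 10 * ncol(x)
  # Label matrix: +1 in the true-class channel, -1 in the other.
  Y <- cbind(ifelse(y == class_order[1L], 1, -1),
             ifelse(y == class_order[2L], 1, -1))
  colnames(Y) <- class_order
  Omega <- kernel_matrix(x, gamma)
  A <- Omega + diag(1 / C, nrow(x))
  R <- tryCatch(chol(A), error = function(e) {
    warning("Cholesky failed; retrying with 1e-10 jitter on the diagonal")
    chol(A + diag(1e-10, nrow(A)))
  })
  coefs <- backsolve(R, backsolve(R, Y, transpose = TRUE))
  colnames(coefs) <- class_order
  structure(
    list(train_x = x, coef = coefs, gamma = gamma, C = C,
         class_order = class_order),
    class = "kelm"
  )
}

#' @export
print.kelm <- function(x, ...) {
  cat("<kelm> ", nrow(x$train_x), " training samples x ", ncol(x$train_x),
      " features; gamma = ", format(x$gamma), ", C = ", format(x$C),
      "; classes ", x$class_order[1L], " (+) vs ", x$class_order[2L],
      " (-)\n", sep = "")
  invisible(x)
}

#' @export
coef.kelm <- function(object, ...) object$coef

#' Predict from a kernel extreme learning machine
#'
#' @param object A [kelm()] model.
#' @param newdata Numeric matrix of query points (or a single vector).
#' @param type `"score"` returns the raw two-channel output `(s1, s2)` in
#'   `class_order`; `"grade"` returns the grading score `s = s1 - s2`, a
#'   continuous similarity that is positive when the point resembles the
#'   positive class; `"class"` returns the hard label, `class_order[1]` when
#'   `s1 > s2` and `class_order[2]` otherwise (an exact tie goes to the
#'   negative/reference class, a documented convention).
#' @param ... Unused.
#' @return A matrix (`type = "score"`), numeric vector (`"grade"`), or
#'   factor with levels `class_order` (`"class"`).
#' @export
predict.kelm <- function(object, newdata,
                         type = c("class", "grade", "score"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$train_x)) {
    stop("newdata has ", ncol(newdata), " features but model was trained on ",
         ncol(object$train_x))
  }
  f <- .cross_kernel(newdata, object$train_x, object$gamma) %*% object$coef
  rownames(f) <- rownames(newdata)
  switch(type,
    score = f,
    grade = {
      s <- f[, 1L] - f[, 2L]
      names(s) <- rownames(newdata)
      s
    },
    class = {
      cls <- ifelse(f[, 1L] > f[, 2L], object$class_order[1L],
                    object$class_order[2L])
      factor(cls, levels = object$class_order)
    }
  )
}

#' Serialise / restore a kernel ELM model
#'
#' A `kelm` object is a plain list of numeric matrices and scalars; it is
#' written with [saveRDS()] so the round-trip is lossless.
#'
#' @param model A [kelm()] model.
#' @param path File path.
#' @return `write_kelm` returns `path` invisibly; `read_kelm` returns the
#'   restored model.
#' @export
write_kelm <- function(model, path) {
  stopifnot(inherits(model, "kelm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_kelm
#' @export
read_kelm <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "kelm"))
  model
}
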