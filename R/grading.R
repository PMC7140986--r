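#' Define a modality for grading
#'
#' A modality is one grading unit: one or more cohort feature blocks merged
#' column-wise, optionally passed through LASSO feature selection before the
#' grading ELM is trained. The defaults mirror the reference design: MRI
#' (with LASSO, since whole-brain morphometry contains many AD-irrelevant
#' features), FDG-PET, and a biological modality combining the CSF proteins
#' with APOE e4 carrier status.
#'
#' @param name Modality name (becomes the score column name).
#' @param source_blocks Character vector of cohort block names merged
#'   column-wise into this modality.
#' @param apply_lasso Logical; fit a LASSO on the AD/NC reference rows and
#'   keep only selected features.
#' @return An object of class `modality_spec`.
#' @export
modality_spec <- function(name, source_blocks, apply_lasso = FALSE) {
  if (length(source_blocks) == 0) stop("source_blocks must be non-empty")
  structure(list(name = name, source_blocks = as.character(source_blocks),
                 apply_lasso = isTRUE(apply_lasso)),
            class = "modality_spec")
}

#' @rdname modality_spec
#' @export
default_modalities <- function() {
  list(modality_spec("MRI", "MRI", apply_lasso = TRUE),
       modality_spec("FDG-PET", "FDG-PET"),
       modality_spec("Bio", c("CSF", "APOE")))
}

#' Build normalised train/test blocks for each modality
#'
#' For every [modality_spec()]: merge its source blocks, fit a z-score
#' normaliser on the AD and NC rows only, apply it to both the AD/NC
#' partition and the MCI partition, and — where requested — fit a LASSO on
#' the normalised AD/NC rows (response AD = +1, NC = -1) and restrict both
#' partitions to the selected columns. All supervised fitting here sees only
#' AD/NC data; the MCI rows are passive.
#'
#' @param cohort A [cohort_table()] containing AD, NC and MCI rows.
#' @param specs List of [modality_spec()]; defaults to [default_modalities()].
#' @param lambda,lambda_scale,lasso_tol,lasso_max_iter LASSO settings, see
#'   [lasso_fit()].
#' @return A named list (one entry per modality) of lists with elements
#'   `train` / `test` ([feature_block()]s over AD/NC and MCI rows),
#'   `train_labels` (factor AD/NC), `normalizer`, and `lasso` (a
#'   [lasso_fit()] or `NULL`).
#' @export
build_modalities <- function(cohort, specs = default_modalities(),
                             lambda = 0.015,
                             lambda_scale = c("per_sample", "literal"),
                             lasso_tol = 1e-6, lasso_max_iter = 10000L) {
  stopifnot(inherits(cohort, "cohort_table"))
  lambda_scale <- match.arg(lambda_scale)
  grp <- cohort$diagnosis$baseline_group
  ref <- grp %in% c("AD", "NC")
  mci <- grp == "MCI"
  if (sum(ref) < 2) stop("cohort needs AD/NC reference rows")
  out <- list()
  for (spec in specs) {
    unknown <- setdiff(spec$source_blocks, names(cohort$blocks))
    if (length(unknown) > 0) {
      stop("modality '", spec$name, "' references unknown block(s): ",
           paste(unknown, collapse = ", "))
    }
    vals <- do.call(cbind, lapply(cohort$blocks[spec$source_blocks],
                                  function(b) b$values))
    merged <- feature_block(vals, spec$name)
    norm <- fit_normalizer(merged, ref, fitted_on = "AD/NC")
    normed <- apply_normalizer(norm, merged)
    train <- feature_block(normed$values[ref, , drop = FALSE], spec$name,
                           normed$feature_names)
    test <- feature_block(normed$values[mci, , drop = FALSE], spec$name,
                          normed$feature_names)
    lasso <- NULL
    if (spec$apply_lasso) {
      y <- ifelse(grp[ref] == "AD", 1, -1)
      lasso <- lasso_fit(train$values, y, lambda = lambda,
                         lambda_scale = lambda_scale, tol = lasso_tol,
                         max_iter = lasso_max_iter)
      train <- select_features(train, lasso)
      test <- select_features(test, lasso)
    }
    out[[spec$name]] <- list(
      train = train, test = test,
      train_labels = factor(grp[ref], levels = c("AD", "NC")),
      normalizer = norm, lasso = lasso
    )
  }
  out
}

#' Grade held-out subjects against the AD/NC reference for one modality
#'
#' Trains one kernel ELM on the full AD/NC reference set of a modality
#' (class order AD, NC; `gamma = 10 * M` by default) and returns the grading
#' score `s = s_AD - s_NC` for every test row. Higher scores mean the
#' subject's modality profile is more AD-like.
#'
#' @param train_block,test_block [feature_block()]s with identical features.
#' @param train_labels Factor/character of `"AD"`/`"NC"` over the training
#'   rows; both classes must be present.
#' @param C,gamma Kernel ELM settings, see [kelm()].
#' @return List with `scores` (named numeric vector over test rows) and
#'   `model` (the fitted [kelm()]).
#' @export
grade_modality <- function(train_block, train_labels, test_block,
                           C = 1, gamma = NULL) {
  stopifnot(inherits(train_block, "feature_block"),
            inherits(test_block, "feature_block"))
  labs <- as.character(train_labels)
  if (!setequal(unique(labs), c("AD", "NC"))) {
    stop("train_labels must contain both AD and NC")
  }
  model <- kelm(train_block$values, labs, C = C, gamma = gamma,
                class_order = c("AD", "NC"))
  scores <- predict(model, test_block$values, type = "grade")
  names(scores) <- rownames(test_block$values)
  list(scores = scores, model = model)
}

#' Fuse per-modality grading scores into one score matrix
#'
#' Concatenates the per-modality grading-score vectors column-wise into the
#' `N_MCI x K` matrix that feeds the final classifier. Optional extra
#' covariates (e.g. neuropsychological test scores) are z-scored using the
#' MCI cohort's own statistics before concatenation, so they enter on a
#' scale comparable to the grades.
#'
#' @param score_list Named list of equal-length named numeric vectors with
#'   identical subject order.
#' @param extra_covariates Optional numeric matrix/data frame with one row
#'   per MCI subject (aligned to the scores).
#' @return Numeric matrix with subject ids as row names, one column per
#'   modality (in `score_list` order) followed by any covariates.
#' @export
fuse_scores <- function(score_list, extra_covariates = NULL) {
  if (length(score_list) == 0) stop("score_list must be non-empty")
  ids <- names(score_list[[1L]])
  for (nm in names(score_list)) {
    if (!identical(names(score_list[[nm]]), ids)) {
      stop("subject ids of modality '", nm,
           "' are misaligned with the first modality")
    }
  }
  scores <- do.call(cbind, score_list)
  rownames(scores) <- ids
  if (!is.null(extra_covariates)) {
    ex <- as.matrix(extra_covariates)
    if (nrow(ex) != nrow(scores)) {
      stop("extra_covariates has ", nrow(ex), " rows but there are ",
           nrow(scores), " graded subjects")
    }
    if (!is.null(rownames(ex)) && !identical(rownames(ex), ids)) {
      stop("extra_covariates subject ids are misaligned with the scores")
    }
    mu <- colMeans(ex)
    sdv <- sqrt(colMeans(sweep(ex, 2L, mu)^2))
    if (any(sdv == 0)) stop("constant extra covariate cannot be z-scored")
    ex <- sweep(sweep(ex, 2L, mu), 2L, sdv, "/")
    if (is.null(colnames(ex))) {
      colnames(ex) <- paste0("cov", seq_len(ncol(ex)))
    }
    scores <- cbind(scores, ex)
  }
  scores
}

#' Fit the full multimodal grading model
#'
#' Runs the complete grading stage on a cohort: label the MCI subjects at
#' the conversion horizon, z-score every modality on the AD/NC reference,
#' LASSO-select the MRI features, train one grading ELM per modality on
#' AD/NC, grade every (non-excluded) MCI subject, and fuse the per-modality
#' scores into the `N_MCI x K` matrix used for pMCI/sMCI classification.
#' The AD/NC reference subjects are disjoint from the MCI evaluation set, so
#' the grading models are fitted once, outside any cross-validation loop.
#'
#' @param cohort A [cohort_table()].
#' @param specs List of [modality_spec()]; defaults to
#'   [default_modalities()].
#' @param horizon Conversion horizon in months defining pMCI (default 36,
#'   i.e. 3 years).
#' @param strict Logical; strict stable-MCI definition, see
#'   [assign_horizon_labels()].
#' @param C Kernel ELM regularisation coefficient (default 1).
#' @param lambda,lambda_scale LASSO penalty settings, see [lasso_fit()].
#' @param extra_covariates Optional matrix of additional per-MCI-subject
#'   covariates appended (z-scored) to the score matrix; rows must align
#'   with the cohort's MCI rows after exclusions.
#' @param gamma Optional fixed kernel width for the grading ELMs; by default
#'   each grading ELM uses `10 * M` with `M` that modality's (post-LASSO)
#'   feature count.
#' @return An object of class `elm_grading`: list with `scores` (fused
#'   matrix), `labels` (factor pMCI/sMCI over the scored subjects),
#'   `models` (per-modality [kelm()]s), `modalities` (per-modality metadata
#'   incl. the [lasso_fit()]), `horizon`, `strict`, `call`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(preset_adnilike())
#' fit <- elm_grading(cohort)
#' print(fit)
#' cv <- cv_evaluate(fit, runs = 5, seed = 1)
#' summary(cv)
#' }
#' @export
elm_grading <- function(cohort, specs = default_modalities(), horizon = 36,
                        strict = FALSE, C = 1, lambda = 0.015,
                        lambda_scale = c("per_sample", "literal"),
                        extra_covariates = NULL, gamma = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  lambda_scale <- match.arg(lambda_scale)
  labels <- assign_horizon_labels(cohort, horizon, strict = strict)
  keep <- labels != "excluded"
  if (sum(keep) < 2) stop("fewer than 2 MCI subjects remain after exclusions")
  mods <- build_modalities(cohort, specs, lambda = lambda,
                           lambda_scale = lambda_scale)
  graded <- list()
  models <- list()
  for (nm in names(mods)) {
    m <- mods[[nm]]
    test <- feature_block(m$test$values[keep, , drop = FALSE],
                          nm, m$test$feature_names)
    g <- grade_modality(m$train, m$train_labels, test, C = C, gamma = gamma)
    graded[[nm]] <- g$scores
    models[[nm]] <- g$model
  }
  scores <- fuse_scores(graded, extra_covariates)
  meta <- lapply(mods, function(m) {
    list(n_features = ncol(m$test$values),
         n_selected = if (is.null(m$lasso)) NA_integer_
                      else length(m$lasso$selected),
         lasso = m$lasso, normalizer = m$normalizer)
  })
  structure(
    list(scores = scores,
         labels = droplevels(labels[keep]),
         models = models,
         modalities = meta,
         horizon = horizon, strict = strict, C = C,
         call = match.call()),
    class = "elm_grading"
  )
}

#' @export
print.elm_grading <- function(x, ...) {
  tab <- table(x$labels)
  cat("<elm_grading> ", nrow(x$scores), " MCI subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "),
      ") at horizon ", x$horizon, " months",
      if (x$strict) " (strict sMCI)", "\n", sep = "")
  for (nm in names(x$modalities)) {
    m <- x$modalities[[nm]]
    cat("  ", format(nm, width = 10), m$n_features, "features",
        if (!is.na(m$n_selected))
          paste0("(LASSO-selected from ", length(m$lasso$alpha), ")"),
        "\n")
  }
  cat("  fused score matrix: ", nrow(x$scores), " x ", ncol(x$scores),
      " [", paste(colnames(x$scores), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' @export
summary.elm_grading <- function(object, ...) {
  print(object)
  by_lab <- vapply(levels(object$labels), function(l) {
    colMeans(object$scores[object$labels == l, , drop = FALSE])
  }, numeric(ncol(object$scores)))
  cat("  mean grading score by outcome:\n")
  print(round(t(by_lab), 3))
  invisible(object)
}

#' Cross-validated evaluation of a fitted grading model
#'
#' Convenience wrapper: runs [repeated_kfold()] on the fused score matrix
#' and horizon labels stored in an [elm_grading()] object.
#'
#' @param object An [elm_grading()] fit.
#' @param k,runs,seed,C See [repeated_kfold()].
#' @return A `cv_summary`, see [repeated_kfold()].
#' @export
cv_evaluate <- function(object, k = 10, runs = 100, seed = 1, C = 1) {
  stopifnot(inherits(object, "elm_grading"))
  repeated_kfold(object$scores, object$labels, k = k, runs = runs,
                 seed = seed, C = C)
}
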