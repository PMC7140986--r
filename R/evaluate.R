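`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confusion-matrix classification metrics
#'
#' Accuracy, sensitivity, specificity and balanced accuracy for a two-class
#' prediction. Sensitivity is the recall of the positive class (pMCI in the
#' conversion task), specificity the recall of the negative class, and
#' balanced accuracy their mean — the appropriate summary under the
#' pMCI/sMCI class imbalance.
#'
#' @param pred,truth Class vectors (factor or character) of equal length;
#'   `truth` must contain both classes.
#' @param positive_class Name of the positive class (default `"pMCI"`).
#' @return Named numeric vector `c(acc, sen, spe, bacc)`, all in `[0, 1]`.
#' @export
confusion_metrics <- function(pred, truth, positive_class = "pMCI") {
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  classes <- unique(truth)
  if (length(classes) != 2) {
    stop("truth must contain exactly 2 classes, got: ",
         paste(classes, collapse = ", "))
  }
  if (!positive_class %in% classes) {
    stop("positive_class '", positive_class, "' absent from truth")
  }
  pos <- truth == positive_class
  tp <- sum(pred == positive_class & pos)
  fn <- sum(pred != positive_class & pos)
  tn <- sum(pred != positive_class & !pos)
  fp <- sum(pred == positive_class & !pos)
  sen <- tp / (tp + fn)
  spe <- tn / (tn + fp)
  c(acc = (tp + tn) / length(truth), sen = sen, spe = spe,
    bacc = (sen + spe) / 2)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = P(score_pos > score_neg) + 0.5 * P(tie)`, computed from midranks,
#' which equals the area under the empirical ROC curve with tie
#' interpolation. In the conversion task the score is the final classifier's
#' grading score `s`.
#'
#' @param score Continuous scores, larger = more positive-leaning.
#' @param truth Class vector containing both classes.
#' @param positive_class Name of the positive class (default `"pMCI"`).
#' @return Scalar AUC in `[0, 1]`; constant scores give 0.5 with a warning.
#' @export
roc_auc <- function(score, truth, positive_class = "pMCI") {
  truth <- as.character(truth)
  if (length(score) != length(truth)) stop("score and truth lengths differ")
  pos <- truth == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (length(unique(score)) == 1L) {
    warning("constant scores; AUC undefined, returning 0.5")
    return(0.5)
  }
  r <- rank(score)  # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin over the k folds, so per-fold class proportions match
# the cohort's. Redrawn (logged) if any training set would be single-class.
.make_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  set.seed(seed)
  n <- length(labels)
  for (attempt in seq_len(100L)) {
    fold <- integer(n)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
    ok <- TRUE
    for (i in seq_len(k)) {
      if (length(unique(labels[fold != i])) < nlevels(labels)) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(fold)
    message("re-drawing fold assignment: training fold lacked a class")
  }
  stop("could not build folds with both classes in every training set")
}

#' Repeated stratified k-fold cross-validated classification
#'
#' The evaluation harness for pMCI/sMCI discrimination: in each of `runs`
#' repetitions, subjects are randomly split into `k` stratified folds; per
#' fold a kernel ELM classifier (`gamma = 10 * K` score columns, `C = 1` by
#' default) is trained on the other folds and applied to the held-out fold.
#' Predictions and grading scores are pooled over the k folds of a run to
#' give one set of metrics (ACC/SEN/SPE/BACC/AUC) per run; the summary is
#' the mean and SD (divisor `n - 1`) over runs. Subjects are first sorted by
#' id, so results depend only on the data and `seed`, not on input order.
#'
#' @param scores Numeric matrix of per-subject features (the fused grading
#'   scores, a single modality's score column, or a wide concatenated
#'   feature matrix for the baseline), with subject ids as row names.
#' @param labels Factor/character class labels aligned to `scores` rows.
#' @param k Number of folds (default 10); requires `nrow(scores) >= 2 * k`.
#' @param runs Number of repetitions (default 100).
#' @param seed Master seed; run `r` draws its folds from a seed derived from
#'   `(seed, r)`.
#' @param C Kernel ELM regularisation coefficient.
#' @param gamma Kernel width; defaults to `10 * ncol(scores)`.
#' @param positive_class Positive class; defaults to `"pMCI"` when present,
#'   otherwise the first factor level.
#' @return An object of class `cv_summary`: list with `per_run` (data frame
#'   of per-run metrics), `mean`, `sd`, `runs`, `k`, `seed`,
#'   `positive_class`, plus the first run's fold assignment (`folds_run1`)
#'   and pooled out-of-fold scores (`roc_run1`) for auditing and plotting.
#' @export
repeated_kfold <- function(scores, labels, k = 10, runs = 100, seed = 1,
                           C = 1, gamma = NULL, positive_class = NULL) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  if (nrow(scores) != length(labels)) {
    stop("scores rows and labels lengths differ")
  }
  if (nlevels(droplevels(labels)) != 2) stop("labels must have 2 classes")
  labels <- droplevels(labels)
  if (nrow(scores) < 2 * k) {
    stop("need at least 2*k = ", 2 * k, " subjects, got ", nrow(scores))
  }
  if (!is.null(rownames(scores))) {
    ord <- order(rownames(scores))
    scores <- scores[ord, , drop = FALSE]
    labels <- labels[ord]
  }
  positive_class <- positive_class %||%
    (if ("pMCI" %in% levels(labels)) "pMCI" else levels(labels)[1L])
  negative_class <- setdiff(levels(labels), positive_class)
  gamma <- gamma %||% (10 * ncol(scores))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  n <- nrow(scores)
  per_run <- vector("list", runs)
  folds_run1 <- NULL
  roc_run1 <- NULL
  for (r in seq_len(runs)) {
    run_seed <- as.integer((seed + 77003 * r) %% .Machine$integer.max)
    fold <- .make_folds(labels, k, run_seed)
    pred <- character(n)
    grade <- numeric(n)
    for (i in seq_len(k)) {
      test <- fold == i
      model <- kelm(scores[!test, , drop = FALSE], labels[!test],
                    C = C, gamma = gamma,
                    class_order = c(positive_class, negative_class))
      pred[test] <- as.character(predict(model, scores[test, , drop = FALSE],
                                         type = "class"))
      grade[test] <- predict(model, scores[test, , drop = FALSE],
                             type = "grade")
    }
    cm <- confusion_metrics(pred, labels, positive_class)
    auc <- roc_auc(grade, labels, positive_class)
    per_run[[r]] <- data.frame(run = r, acc = cm[["acc"]], sen = cm[["sen"]],
                               spe = cm[["spe"]], bacc = cm[["bacc"]],
                               auc = auc)
    if (r == 1L) {
      folds_run1 <- fold
      roc_run1 <- data.frame(score = grade, truth = as.character(labels))
    }
  }
  per_run <- do.call(rbind, per_run)
  metrics <- c("acc", "sen", "spe", "bacc", "auc")
  structure(
    list(per_run = per_run,
         mean = vapply(per_run[metrics], mean, numeric(1)),
         sd = vapply(per_run[metrics],
                     function(x) if (runs > 1) sd(x) else NA_real_,
                     numeric(1)),
         runs = runs, k = k, seed = seed,
         positive_class = positive_class,
         folds_run1 = folds_run1, roc_run1 = roc_run1),
    class = "cv_summary"
  )
}

#' @export
print.cv_summary <- function(x, digits = 1, ...) {
  cat("<cv_summary> ", x$runs, " x ", x$k, "-fold CV (positive class: ",
      x$positive_class, ", seed ", x$seed, ")\n", sep = "")
  labels <- c(acc = "ACC", sen = "SEN", spe = "SPE", bacc = "BACC",
              auc = "AUC")
  for (m in names(labels)) {
    cat(sprintf("  %-4s %5.*f +/- %.*f %%\n", labels[[m]], digits,
                100 * x$mean[[m]], digits,
                if (is.na(x$sd[[m]])) 0 else 100 * x$sd[[m]]))
  }
  invisible(x)
}

#' @export
summary.cv_summary <- function(object, ...) {
  data.frame(metric = names(object$mean),
             mean = as.numeric(object$mean),
             sd = as.numeric(object$sd))
}

#' @describeIn repeated_kfold Plot the pooled out-of-fold ROC curve of the
#'   first CV run.
#' @param x A `cv_summary`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cv_summary <- function(x, ...) {
  sc <- x$roc_run1$score
  pos <- x$roc_run1$truth == x$positive_class
  th <- sort(unique(sc), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(sc[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(sc[!pos] >= t), numeric(1))
  graphics::plot(c(0, fpr, 1), c(0, tpr, 1), type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (run 1), mean AUC = %.1f%%",
                                100 * x$mean[["auc"]]), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Direct-concatenation fusion baseline
#'
#' The comparison method that skips grading entirely: the normalised (and,
#' where configured, LASSO-selected) feature blocks of the MCI subjects are
#' concatenated column-wise into one wide matrix and fed to the same
#' repeated k-fold harness (`gamma = 10 *` total column count). Because the
#' wide matrix is dominated by the largest block, this baseline exhibits the
#' modality-imbalance bias that per-modality grading avoids.
#'
#' @inheritParams elm_grading
#' @inheritParams repeated_kfold
#' @return A `cv_summary`, see [repeated_kfold()]. At an equal `seed` the
#'   fold assignments are identical to the grading pipeline's, so the two
#'   methods are compared on the same splits.
#' @export
direct_concat_baseline <- function(cohort, specs = default_modalities(),
                                   horizon = 36, strict = FALSE,
                                   k = 10, runs = 100, seed = 1, C = 1,
                                   lambda = 0.015,
                                   lambda_scale = c("per_sample", "literal")) {
  lambda_scale <- match.arg(lambda_scale)
  labels <- assign_horizon_labels(cohort, horizon, strict = strict)
  keep <- labels != "excluded"
  mods <- build_modalities(cohort, specs, lambda = lambda,
                           lambda_scale = lambda_scale)
  wide <- do.call(cbind, lapply(mods, function(m) {
    v <- m$test$values[keep, , drop = FALSE]
    colnames(v) <- paste(m$test$modality_name, m$test$feature_names,
                         sep = ".")
    v
  }))
  repeated_kfold(wide, droplevels(labels[keep]), k = k, runs = runs,
                 seed = seed, C = C)
}
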