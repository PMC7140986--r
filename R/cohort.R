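#' Construct a feature block
#'
#' A feature block is one modality's measurements for a set of subjects: an
#' `N x M` numeric matrix plus the modality and feature names. Blocks are the
#' unit on which normalisation, feature selection and grading operate.
#'
#' @param values Numeric matrix, one row per subject, one column per feature.
#'   All entries must be finite; cohorts are assumed complete (subjects with a
#'   missing modality are excluded upstream, never imputed).
#' @param modality_name Single string naming the modality (e.g. `"MRI"`).
#' @param feature_names Character vector of length `ncol(values)`; defaults to
#'   the column names of `values`.
#' @return An object of class `feature_block`: a list with elements
#'   `modality_name`, `feature_names` and `values`.
#' @export
feature_block <- function(values, modality_name, feature_names = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("feature block '", modality_name, "' must be numeric")
  }
  if (is.null(feature_names)) {
    feature_names <- paste0(modality_name, "_f", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length (", length(feature_names),
         ") does not match number of columns (", ncol(values), ")")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value in block '", modality_name, "' at row ", bad[1L],
         ", column '", feature_names[bad[2L]], "'")
  }
  colnames(values) <- feature_names
  structure(
    list(modality_name = modality_name,
         feature_names = as.character(feature_names),
         values = values),
    class = "feature_block"
  )
}

#' @export
print.feature_block <- function(x, ...) {
  cat("<feature_block> ", x$modality_name, ": ", nrow(x$values), " subjects x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

#' Construct a multimodal cohort table
#'
#' Bundles the per-subject diagnosis metadata with one [feature_block()] per
#' modality. All blocks must cover exactly the same subjects in the same
#' order. Rows are sorted by subject id so that downstream seeded computation
#' is independent of input file order.
#'
#' @param diagnosis Data frame with columns `subject_id`, `baseline_group`
#'   (one of `"AD"`, `"NC"`, `"MCI"`), `months_to_AD` (`NA` when no conversion
#'   to AD was observed), `months_last_followup`, and `reverted_to_NC`
#'   (logical).
#' @param blocks Named list of [feature_block()] objects, one per modality,
#'   with rows aligned to `diagnosis`.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(diagnosis, blocks) {
  required <- c("subject_id", "baseline_group", "months_to_AD",
                "months_last_followup", "reverted_to_NC")
  missing_cols <- setdiff(required, names(diagnosis))
  if (length(missing_cols) > 0) {
    stop("diagnosis table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  diagnosis <- as.data.frame(diagnosis)[required]
  diagnosis$subject_id <- as.character(diagnosis$subject_id)
  diagnosis$baseline_group <- as.character(diagnosis$baseline_group)
  diagnosis$reverted_to_NC <- as.logical(diagnosis$reverted_to_NC)
  if (anyDuplicated(diagnosis$subject_id)) {
    stop("duplicated subject_id in diagnosis table")
  }
  bad_grp <- setdiff(unique(diagnosis$baseline_group), c("AD", "NC", "MCI"))
  if (length(bad_grp) > 0) {
    stop("unknown baseline_group value(s): ", paste(bad_grp, collapse = ", "))
  }
  if (any(diagnosis$months_to_AD < 0, na.rm = TRUE)) {
    stop("months_to_AD must be nonnegative")
  }
  if (!is.list(blocks) || length(blocks) == 0 || is.null(names(blocks))) {
    stop("blocks must be a non-empty named list of feature_block objects")
  }
  n <- nrow(diagnosis)
  for (nm in names(blocks)) {
    if (!inherits(blocks[[nm]], "feature_block")) {
      stop("block '", nm, "' is not a feature_block")
    }
    if (nrow(blocks[[nm]]$values) != n) {
      stop("block '", nm, "' has ", nrow(blocks[[nm]]$values),
           " rows but diagnosis has ", n)
    }
  }
  ord <- order(diagnosis$subject_id)
  diagnosis <- diagnosis[ord, , drop = FALSE]
  rownames(diagnosis) <- NULL
  for (nm in names(blocks)) {
    v <- blocks[[nm]]$values[ord, , drop = FALSE]
    rownames(v) <- diagnosis$subject_id
    blocks[[nm]] <- feature_block(v, blocks[[nm]]$modality_name,
                                  blocks[[nm]]$feature_names)
  }
  structure(list(diagnosis = diagnosis, blocks = blocks),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  grp <- table(factor(x$diagnosis$baseline_group, levels = c("AD", "NC", "MCI")))
  cat("<cohort_table> ", nrow(x$diagnosis), " subjects (",
      paste(names(grp), grp, sep = "=", collapse = ", "), ")\n", sep = "")
  for (b in x$blocks) {
    cat("  ", format(b$modality_name, width = 10), ncol(b$values), "features\n")
  }
  invisible(x)
}

# Delimiter by file extension: .csv -> comma, anything else -> tab.
.read_delimited <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
}

#' Read a multimodal cohort from delimited text files
#'
#' Reads one feature file per modality plus a diagnosis file and assembles a
#' [cohort_table()]. Each feature file must have a header row and a subject-id
#' first column; every subject in the diagnosis file must be present in every
#' modality file (cohorts are complete by construction; no imputation).
#'
#' @param feature_paths Named character vector of file paths, one per
#'   modality; names become the modality names. `.csv` files are read as
#'   comma-separated, anything else as tab-separated.
#' @param diagnosis_path Path to the diagnosis file with columns
#'   `subject_id`, `baseline_group`, `months_to_AD` (empty cell = no observed
#'   conversion), `months_last_followup`, `reverted_to_NC`.
#' @return A [cohort_table()] with blocks in the order of `feature_paths` and
#'   rows sorted by subject id.
#' @export
read_cohort <- function(feature_paths, diagnosis_path) {
  if (is.null(names(feature_paths)) || any(names(feature_paths) == "")) {
    stop("feature_paths must be a named vector (names are modality names)")
  }
  diag_df <- .read_delimited(diagnosis_path)
  if (!"subject_id" %in% names(diag_df)) {
    stop("diagnosis file lacks a subject_id column")
  }
  diag_df$subject_id <- as.character(diag_df$subject_id)
  diag_df$months_to_AD <- suppressWarnings(as.numeric(diag_df$months_to_AD))
  blocks <- list()
  for (modality in names(feature_paths)) {
    df <- .read_delimited(feature_paths[[modality]])
    ids <- as.character(df[[1L]])
    missing <- setdiff(diag_df$subject_id, ids)
    if (length(missing) > 0) {
      stop("subject '", missing[1L], "' is missing from modality file '",
           modality, "'")
    }
    df <- df[match(diag_df$subject_id, ids), -1L, drop = FALSE]
    for (j in seq_along(df)) {
      col <- df[[j]]
      if (!is.numeric(col)) {
        num <- suppressWarnings(as.numeric(col))
        if (any(is.na(num) & !is.na(col))) {
          i <- which(is.na(num) & !is.na(col))[1L]
          stop("non-numeric value '", col[i], "' in modality '", modality,
               "', row ", i, " (subject ", diag_df$subject_id[i],
               "), column '", names(df)[j], "'")
        }
        df[[j]] <- num
      }
    }
    blocks[[modality]] <- feature_block(as.matrix(df), modality)
  }
  cohort_table(diag_df, blocks)
}

#' Write a cohort back to delimited text files
#'
#' Inverse of [read_cohort()]: writes one `<modality>.csv` per block plus
#' `diagnosis.csv` into `dir`. Numeric values are written with enough digits
#' to round-trip, so `read_cohort(write_cohort(x))` reproduces `x`.
#'
#' @param cohort A [cohort_table()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the feature-file paths plus the
#'   diagnosis path as attribute `"diagnosis"`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else sprintf("%.17g", v)
    }, character(1L))
    out
  }
  paths <- character(0)
  for (nm in names(cohort$blocks)) {
    b <- cohort$blocks[[nm]]
    out <- data.frame(subject_id = cohort$diagnosis$subject_id,
                      check.names = FALSE)
    for (j in seq_along(b$feature_names)) {
      out[[b$feature_names[j]]] <- fmt(b$values[, j])
    }
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(out, p, row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  d <- cohort$diagnosis
  d$months_to_AD <- fmt(d$months_to_AD)
  d$months_last_followup <- fmt(d$months_last_followup)
  diag_path <- file.path(dir, "diagnosis.csv")
  write.csv(d, diag_path, row.names = FALSE, quote = FALSE)
  attr(paths, "diagnosis") <- diag_path
  invisible(paths)
}

#' Label MCI subjects as progressive or stable at a conversion horizon
#'
#' A subject with mild cognitive impairment is *progressive* (pMCI) if AD
#' conversion was observed within `horizon_months` of baseline, and *stable*
#' (sMCI) otherwise. Under the strict definition, subjects who converted
#' beyond the horizon or whose diagnosis reverted to normal are `excluded`
#' rather than counted as stable.
#'
#' @param cohort A [cohort_table()] containing MCI rows.
#' @param horizon_months Positive number of months defining conversion.
#' @param strict Logical; if `TRUE`, late converters and reverters are marked
#'   `excluded`.
#' @return A factor over the cohort's MCI rows (named by subject id) with
#'   levels `pMCI`, `sMCI`, `excluded`. Stable subjects whose last follow-up
#'   is shorter than the horizon are still labelled `sMCI` but their ids are
#'   attached as attribute `"short_followup"` so callers can audit them.
#' @export
assign_horizon_labels <- function(cohort, horizon_months, strict = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!is.numeric(horizon_months) || length(horizon_months) != 1 ||
      horizon_months <= 0) {
    stop("horizon_months must be a single positive number")
  }
  d <- cohort$diagnosis
  mci <- d$baseline_group == "MCI"
  if (!any(mci)) stop("cohort contains no MCI rows to label")
  d <- d[mci, , drop = FALSE]
  lab <- .horizon_label(d$months_to_AD, d$reverted_to_NC, horizon_months, strict)
  names(lab) <- d$subject_id
  short <- d$subject_id[lab == "sMCI" & d$months_last_followup < horizon_months]
  attr(lab, "short_followup") <- short
  lab
}

# Vectorised labelling rule; months NA = conversion never observed.
.horizon_label <- function(months_to_AD, reverted, horizon, strict) {
  converted_within <- !is.na(months_to_AD) & months_to_AD <= horizon
  lab <- ifelse(converted_within, "pMCI", "sMCI")
  if (strict) {
    late <- !is.na(months_to_AD) & months_to_AD > horizon
    lab[late | (!converted_within & reverted)] <- "excluded"
  }
  factor(lab, levels = c("pMCI", "sMCI", "excluded"))
}
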