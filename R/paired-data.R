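#' Paired two-class expression data
#'
#' A `paired_expr` object holds positive, non-log expression intensities for
#' `M` features measured in two matched classes (X = normal/adjacent tissue,
#' Y = tumour) across `N` patients. Every patient contributes exactly one
#' sample per class; tests in this package always compare within-patient
#' differences, so patient-level confounders cancel.
#'
#' @param x,y Numeric `M x N` matrices of class-X (normal) and class-Y
#'   (tumour) intensities. Rows are features, columns are patients.
#' @param feature_ids Character vector of unique feature identifiers
#'   (length `M`). Defaults to the rownames of `x`.
#' @param patient_ids Character vector of unique patient identifiers
#'   (length `N`). Defaults to the colnames of `x`.
#' @param floor_eps Strictly positive flooring value. Intensities below
#'   `floor_eps` (including zeros and negatives, which summarised microarray
#'   output can produce) are replaced by `floor_eps` with a warning, keeping
#'   downstream ratios finite. Set to `NULL` to forbid non-positive values
#'   outright.
#'
#' @return A `paired_expr` object: a list with elements `x`, `y`
#'   (matrices), `feature_ids`, `patient_ids`, and `n_floored` (number of
#'   cells floored during validation).
#' @examples
#' x <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE)
#' y <- x * 2
#' pe <- paired_expression(x, y, feature_ids = c("f1", "f2"),
#'                         patient_ids = c("p1", "p2", "p3"))
#' dim(pe)
#' @export
paired_expression <- function(x, y, feature_ids = rownames(x),
                              patient_ids = colnames(x), floor_eps = 0.01) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("invalid intensity: expression values must be numeric", call. = FALSE)
  }
  if (!identical(dim(x), dim(y))) {
    stop("class X and class Y matrices must have identical dimensions",
         call. = FALSE)
  }
  m <- nrow(x)
  n <- ncol(x)
  if (m < 1L || n < 2L) {
    stop("need at least 1 feature and 2 patients", call. = FALSE)
  }
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(m))
  if (is.null(patient_ids)) patient_ids <- paste0("patient_", seq_len(n))
  feature_ids <- as.character(feature_ids)
  patient_ids <- as.character(patient_ids)
  if (length(feature_ids) != m || anyDuplicated(feature_ids)) {
    stop("feature_ids must be unique and match the number of rows",
         call. = FALSE)
  }
  if (length(patient_ids) != n || anyDuplicated(patient_ids)) {
    stop("patient_ids must be unique and match the number of columns",
         call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    bad <- which(is.na(x) | is.na(y), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid intensity: missing value at feature %s, patient %s",
                 feature_ids[bad[1L]], patient_ids[bad[2L]]), call. = FALSE)
  }
  n_floored <- 0L
  if (is.null(floor_eps)) {
    if (any(x <= 0) || any(y <= 0)) {
      bad <- which(x <= 0 | y <= 0, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "invalid intensity: non-positive value at feature %s, patient %s",
        feature_ids[bad[1L]], patient_ids[bad[2L]]), call. = FALSE)
    }
  } else {
    stopifnot(is.numeric(floor_eps), floor_eps > 0)
    n_floored <- sum(x < floor_eps) + sum(y < floor_eps)
    if (n_floored > 0L) {
      x[x < floor_eps] <- floor_eps
      y[y < floor_eps] <- floor_eps
      warning(sprintf("floored %d non-positive or sub-threshold intensities at %g",
                      n_floored, floor_eps), call. = FALSE)
    }
  }
  dimnames(x) <- dimnames(y) <- list(feature_ids, patient_ids)
  structure(
    list(x = x, y = y, feature_ids = feature_ids, patient_ids = patient_ids,
         n_floored = n_floored),
    class = "paired_expr"
  )
}

#' @export
dim.paired_expr <- function(x) dim(x$x)

#' @export
print.paired_expr <- function(x, ...) {
  cat(sprintf("<paired_expr> %d features x %d patient pairs\n",
              nrow(x$x), ncol(x$x)))
  cat("  classes: X (normal/adjacent), Y (tumour)\n")
  if (x$n_floored > 0L) {
    cat(sprintf("  %d intensities floored during validation\n", x$n_floored))
  }
  invisible(x)
}

#' Subset a paired expression object by feature
#'
#' @param x A [paired_expression()] object.
#' @param features Character vector of feature ids (or integer indices).
#' @return A `paired_expr` restricted to the requested features.
#' @export
filter_features <- function(x, features) {
  stopifnot(inherits(x, "paired_expr"))
  if (is.character(features)) {
    missing <- setdiff(features, x$feature_ids)
    if (length(missing) > 0L) {
      stop("unknown feature ids: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(x = x$x[features, , drop = FALSE], y = x$y[features, , drop = FALSE],
         feature_ids = rownames(x$x[features, , drop = FALSE]),
         patient_ids = x$patient_ids, n_floored = x$n_floored),
    class = "paired_expr"
  )
}

# canonical class-label vocabulary; matching is case-insensitive
.x_labels <- c("normal", "adjacent", "control")
.y_labels <- c("tumour", "tumor", "cancer", "case")

#' Read a pairing manifest
#'
#' The manifest maps each sample to a patient and a class. It is a
#' tab-separated file with columns `sample_id`, `patient_id`, `class`.
#' Class labels are matched case-insensitively: normal/adjacent/control are
#' class X, tumour/tumor/cancer/case are class Y.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with columns `sample_id`, `patient_id`, `class`
#'   (`"X"` or `"Y"`), validated so that each patient appears exactly once
#'   per class.
#' @export
read_pairing_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("sample_id", "patient_id", "class")
  if (!all(required %in% names(man))) {
    stop("manifest must have columns sample_id, patient_id, class",
         call. = FALSE)
  }
  man <- dplyr::select(man, dplyr::all_of(required))
  cls <- tolower(trimws(man$class))
  man$class <- dplyr::case_when(
    cls %in% .x_labels ~ "X",
    cls %in% .y_labels ~ "Y",
    TRUE ~ NA_character_
  )
  if (anyNA(man$class)) {
    stop("unrecognised class label(s): ",
         paste(unique(cls[is.na(man$class)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(man$sample_id)) {
    stop("duplicate sample_id in manifest", call. = FALSE)
  }
  counts <- tidyr::pivot_wider(
    dplyr::count(man, .data$patient_id, .data$class),
    names_from = "class", values_from = "n", values_fill = 0L
  )
  if (!"X" %in% names(counts)) counts$X <- 0L
  if (!"Y" %in% names(counts)) counts$Y <- 0L
  bad <- dplyr::filter(counts, .data$X != 1L | .data$Y != 1L)
  if (nrow(bad) > 0L) {
    stop("unpaired sample: patient(s) ",
         paste(bad$patient_id, collapse = ", "),
         " do not have exactly one sample per class", call. = FALSE)
  }
  man
}

#' Read a paired expression matrix with its pairing manifest
#'
#' The expression file is a TSV with a header row of sample ids and a first
#' column (named `feature_id`) of feature identifiers; intensities are
#' non-log, positive values (for example MAS5-summarised microarray signal).
#' Samples are matched into patient pairs through the manifest, so the column
#' order in the matrix file is irrelevant.
#'
#' @param matrix_path Path to the expression TSV.
#' @param manifest_path Path to the pairing manifest TSV
#'   (see [read_pairing_manifest()]).
#' @inheritParams paired_expression
#' @return A validated [paired_expression()] object.
#' @export
read_paired_matrix <- function(matrix_path, manifest_path, floor_eps = 0.01) {
  man <- read_pairing_manifest(manifest_path)
  expr <- readr::read_tsv(matrix_path, col_types = readr::cols(
    .default = "d", feature_id = "c"
  ), progress = FALSE)
  if (names(expr)[1L] != "feature_id") {
    stop("first column of the expression matrix must be 'feature_id'",
         call. = FALSE)
  }
  feature_ids <- expr$feature_id
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(expr[, -1L, drop = FALSE])
  rownames(mat) <- feature_ids
  missing <- setdiff(man$sample_id, colnames(mat))
  if (length(missing) > 0L) {
    stop("manifest sample(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  man <- dplyr::arrange(man, .data$patient_id)
  x_samples <- dplyr::filter(man, .data$class == "X")
  y_samples <- dplyr::filter(man, .data$class == "Y")
  stopifnot(identical(x_samples$patient_id, y_samples$patient_id))
  paired_expression(
    x = mat[, x_samples$sample_id, drop = FALSE],
    y = mat[, y_samples$sample_id, drop = FALSE],
    feature_ids = feature_ids,
    patient_ids = x_samples$patient_id,
    floor_eps = floor_eps
  )
}

# fixed column contract of the per-feature results table
results_columns <- c(
  "feature_id", "n_pairs", "t_plus", "t_minus", "n_zero_diffs",
  "misclassification_count", "misclassification_rate", "r_plus", "r_minus",
  "z_value", "p_mwt", "p_bootstrap", "fold_change", "direction", "cds_flag",
  "selected_strict", "selected_relaxed"
)

#' Write a per-feature results table
#'
#' Writes the scored feature table as TSV with a fixed column set, sorted by
#' ascending modified-Wilcoxon p-value, then descending `|z|`, then feature
#' id (a deterministic ordering even under ties).
#'
#' @param table A results tibble as produced by [run_ecd()] (the `results`
#'   element) or [mwt_test()] after selection columns are filled.
#' @param path Output file path.
#' @return The (sorted) table, invisibly.
#' @export
write_results <- function(table, path) {
  missing <- setdiff(results_columns, names(table))
  if (length(missing) > 0L) {
    stop("results table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::arrange(
    dplyr::select(table, dplyr::all_of(results_columns)),
    .data$p_mwt, dplyr::desc(abs(.data$z_value)), .data$feature_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the results TSV.
#' @return A tibble with the full results column set.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    feature_id = "c", direction = "c", cds_flag = "c",
    selected_strict = "l", selected_relaxed = "l",
    n_pairs = "i", t_plus = "i", t_minus = "i", n_zero_diffs = "i",
    misclassification_count = "i", .default = "d"
  ), progress = FALSE)
}
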