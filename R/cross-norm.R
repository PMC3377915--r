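#' Per-feature class means
#'
#' Arithmetic mean of each feature across patients, separately for the two
#' classes. These are the normalising denominators of [cross_normalize()]
#' and the numerator/denominator of [fold_change()].
#'
#' @param pem A [paired_expression()] object.
#' @return A tibble with columns `feature_id`, `x_bar`, `y_bar`.
#' @export
class_means <- function(pem) {
  stopifnot(inherits(pem, "paired_expr"))
  tibble::tibble(
    feature_id = pem$feature_ids,
    x_bar = unname(rowMeans(pem$x)),
    y_bar = unname(rowMeans(pem$y))
  )
}

#' Cross-normalize paired expression values
#'
#' Cross-normalization (CN) rescales each class by the *opposite* class's
#' per-feature mean: tumour values are divided by the normal-tissue mean and
#' vice versa. For a feature with a genuine disease effect this inflates the
#' tumour ratios and deflates the normal ratios simultaneously, widening the
#' gap between the classes before paired differences are taken. The
#' transform is dimensionless and invariant to multiplying all raw
#' intensities by a common positive scalar.
#'
#' @param pem A [paired_expression()] object (strictly positive values).
#' @param method CN strategy. `"divide_opposite_mean"` (default) divides
#'   each value by the opposite class's feature mean;
#'   `"subtract_opposite_mean"` subtracts it instead;
#'   `"divide_opposite_pair"` divides by the patient's own opposite-class
#'   value.
#' @return A `cn_matrix` object: list with `x_cn`, `y_cn` (M x N matrices),
#'   `feature_ids`, `patient_ids`, `method`.
#' @examples
#' pe <- paired_expression(matrix(c(1, 2, 3), 1), matrix(c(2, 4, 6), 1),
#'                         "f1", c("p1", "p2", "p3"))
#' cn <- cross_normalize(pe)
#' cn$y_cn  # (1, 2, 3): y divided by x_bar = 2
#' @export
cross_normalize <- function(pem,
                            method = c("divide_opposite_mean",
                                       "subtract_opposite_mean",
                                       "divide_opposite_pair")) {
  stopifnot(inherits(pem, "paired_expr"))
  method <- match.arg(method)
  x_bar <- rowMeans(pem$x)
  y_bar <- rowMeans(pem$y)
  if (any(x_bar <= 0) || any(y_bar <= 0)) {
    stop("class means must be strictly positive for cross-normalization",
         call. = FALSE)
  }
  switch(method,
    divide_opposite_mean = {
      y_cn <- pem$y / x_bar  # column-wise recycling over the M-vector
      x_cn <- pem$x / y_bar
    },
    subtract_opposite_mean = {
      y_cn <- pem$y - x_bar
      x_cn <- pem$x - y_bar
    },
    divide_opposite_pair = {
      y_cn <- pem$y / pem$x
      x_cn <- pem$x / pem$y
    }
  )
  structure(
    list(x_cn = x_cn, y_cn = y_cn, feature_ids = pem$feature_ids,
         patient_ids = pem$patient_ids, method = method),
    class = "cn_matrix"
  )
}

#' Per-pair differences of cross-normalized values
#'
#' For each feature and patient, the difference `d_ij = y_cn_ij - x_cn_ij`
#' between the cross-normalized tumour and normal values. The sign of
#' `d_ij` is the per-pair classification vote that the downstream
#' signed-rank and misclassification machinery consumes.
#'
#' @param cn A `cn_matrix` from [cross_normalize()].
#' @return A `diff_matrix` object: list with `d` (M x N matrix of
#'   differences), `d_bar` (per-feature mean difference), `feature_ids`,
#'   `patient_ids`.
#' @export
paired_differences <- function(cn) {
  stopifnot(inherits(cn, "cn_matrix"))
  d <- cn$y_cn - cn$x_cn
  if (!all(is.finite(d))) {
    stop("non-finite paired differences; check input positivity",
         call. = FALSE)
  }
  structure(
    list(d = d, d_bar = unname(rowMeans(d)), feature_ids = cn$feature_ids,
         patient_ids = cn$patient_ids),
    class = "diff_matrix"
  )
}
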