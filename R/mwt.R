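#' Signed-rank sums for one feature
#'
#' Ranks `|d|` ascending (average ranks for ties) after dropping exact
#' zeros, then sums the ranks of the positive and of the negative
#' differences. `r_plus + r_minus = n_eff(n_eff+1)/2` with
#' `n_eff = length(d) - #zeros`.
#'
#' @param d Numeric vector of paired differences for one feature.
#' @return A list with `r_plus`, `r_minus`, `n_eff`.
#' @examples
#' signed_rank_sums(c(0.75, 1.5, 2.25))  # r_plus 6, r_minus 0
#' @export
signed_rank_sums <- function(d) {
  stopifnot(is.numeric(d), length(d) >= 2L)
  nz <- d[d != 0]
  n_eff <- length(nz)
  if (n_eff == 0L) {
    return(list(r_plus = 0, r_minus = 0, n_eff = 0L))
  }
  rk <- rank(abs(nz))
  list(r_plus = sum(rk[nz > 0]), r_minus = sum(rk[nz < 0]), n_eff = n_eff)
}

#' Signed-rank Z statistic
#'
#' Standardises the smaller rank sum against its null mean
#' `n(n+1)/4` and standard deviation `sqrt(n(n+1)(2n+1)/24)`. Because the
#' smaller sum is used, the statistic is non-positive by construction.
#'
#' @param r_min The smaller of the two rank sums.
#' @param n_eff Number of non-zero differences.
#' @return The raw Z value (<= 0).
#' @examples
#' z_value(0, 10)  # -2.8031
#' @export
z_value <- function(r_min, n_eff) {
  if (n_eff < 2L) {
    stop("degenerate feature: need at least 2 non-zero differences",
         call. = FALSE)
  }
  mu <- n_eff * (n_eff + 1) / 4
  sigma <- sqrt(n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24)
  (r_min - mu) / sigma
}

# parse a correction policy string into list(name, c)
parse_z_policy <- function(policy) {
  if (policy %in% c("continuity", "none")) {
    return(list(name = policy, c = NA_integer_))
  }
  m <- regmatches(policy, regexec("^shrink[:(]([0-9]+)\\)?$", policy))[[1L]]
  if (length(m) == 2L) {
    return(list(name = "shrink", c = as.integer(m[2L])))
  }
  stop("unknown z-correction policy: ", policy,
       " (use 'continuity', 'none' or 'shrink:c')", call. = FALSE)
}

#' Apply a small-sample correction to the Z statistic
#'
#' The default `"continuity"` policy recomputes the statistic with the
#' smaller rank sum moved half a unit toward its null mean (clamped at 0 so
#' a perfectly balanced feature keeps Z = 0). `"none"` returns the raw
#' value. `"shrink:c"` multiplies by `sqrt((n_eff - c)/n_eff)`, a
#' degrees-of-freedom style deflation with integer `c`.
#'
#' @param z_raw Raw Z from [z_value()].
#' @param n_eff Number of non-zero differences.
#' @param r_min Smaller rank sum (needed by the continuity policy).
#' @param policy Policy string: `"continuity"`, `"none"`, or `"shrink:c"`.
#' @return The corrected Z value (<= 0).
#' @examples
#' corrected_z(z_value(0, 10), 10, 0, "continuity")  # -2.7521
#' @export
corrected_z <- function(z_raw, n_eff, r_min, policy = "continuity") {
  pol <- parse_z_policy(policy)
  switch(pol$name,
    none = z_raw,
    continuity = min(0, z_value(r_min + 0.5, n_eff)),
    shrink = {
      if (pol$c >= n_eff) {
        stop("shrink constant must be smaller than n_eff", call. = FALSE)
      }
      z_raw * sqrt((n_eff - pol$c) / n_eff)
    }
  )
}

#' Two-sided normal p-value for a signed-rank Z
#'
#' @param z Corrected Z statistic (non-positive).
#' @return `min(1, 2 * pnorm(-|z|))`.
#' @examples
#' mwt_pvalue(-2.8031)  # about 0.00506
#' @export
mwt_pvalue <- function(z) {
  pmin(1, 2 * stats::pnorm(-abs(z)))
}

#' Misclassification count and rate for one feature
#'
#' In a paired design a feature "votes" once per patient through the sign of
#' its difference; the minority sign count is the number of patients the
#' feature would misclassify.
#'
#' @param d Numeric vector of paired differences.
#' @return A list with `t_plus`, `t_minus`, `n_zero`, `count`
#'   (`min(t_plus, t_minus)`), and `rate` (`count / length(d)`).
#' @examples
#' misclassification(c(1, 2, -0.5, 3, 4, 5))  # count 1, rate 1/6
#' @export
misclassification <- function(d) {
  t_plus <- sum(d > 0)
  t_minus <- sum(d < 0)
  n_zero <- sum(d == 0)
  count <- min(t_plus, t_minus)
  list(t_plus = t_plus, t_minus = t_minus, n_zero = n_zero,
       count = count, rate = count / length(d))
}

#' Completely vs incompletely discriminative signal
#'
#' A feature is a completely discriminative signal (CDS) when every patient
#' pair carries the same strict sign of the cross-normalized difference —
#' zero misclassifications and no zero differences. Anything else is an
#' incomplete discriminative signal (IDS).
#'
#' @param d Numeric vector of paired differences.
#' @return `"CDS"` or `"IDS"`.
#' @export
classify_cds <- function(d) {
  n <- length(d)
  if (all(d > 0) || all(d < 0)) "CDS" else "IDS"
}

#' Symmetrized fold change between class means
#'
#' Ratio of tumour to normal per-feature means, folded to be >= 1 with an
#' up/down direction (`up` when the tumour mean is the larger).
#'
#' @param x_bar,y_bar Per-feature class means (positive).
#' @return A tibble with columns `fold_change` and `direction`.
#' @examples
#' fold_change(2, 4)  # fc 2, up
#' @export
fold_change <- function(x_bar, y_bar) {
  stopifnot(all(x_bar > 0), all(y_bar > 0))
  r <- y_bar / x_bar
  tibble::tibble(
    fold_change = pmax(r, 1 / r),
    direction = ifelse(r > 1, "up", "down")
  )
}

#' Modified Wilcoxon test over all features
#'
#' The modified Wilcoxon test (MWT) chains cross-normalization, per-pair
#' differences, a signed-rank Z statistic with a small-sample correction,
#' and per-feature misclassification accounting. Features whose differences
#' are all exactly zero are flagged degenerate (`p_mwt = 1`, `z = NA`).
#'
#' @param pem A [paired_expression()] object.
#' @param z_correction Correction policy, see [corrected_z()].
#' @param cn_method Cross-normalization strategy, see [cross_normalize()].
#' @return A tibble with one row per feature and columns `feature_id`,
#'   `n_pairs`, `t_plus`, `t_minus`, `n_zero_diffs`,
#'   `misclassification_count`, `misclassification_rate`, `r_plus`,
#'   `r_minus`, `z_value`, `p_mwt`, `fold_change`, `direction`, `cds_flag`,
#'   `mean_difference`, `degenerate`.
#' @examples
#' pe <- paired_expression(matrix(c(1, 2, 3), 1), matrix(c(2, 4, 6), 1),
#'                         "f1", c("p1", "p2", "p3"))
#' mwt_test(pe)
#' @export
mwt_test <- function(pem, z_correction = "continuity",
                     cn_method = "divide_opposite_mean") {
  stopifnot(inherits(pem, "paired_expr"))
  pol <- parse_z_policy(z_correction)  # fail fast on bad policy
  cn <- cross_normalize(pem, method = cn_method)
  dm <- paired_differences(cn)
  d <- dm$d
  n <- ncol(d)

  t_plus <- unname(rowSums(d > 0))
  t_minus <- unname(rowSums(d < 0))
  n_zero <- unname(rowSums(d == 0))
  n_eff <- n - n_zero

  # per-feature signed-rank sums on |d| with zeros dropped
  rank_row <- function(di) {
    nz <- di[di != 0]
    if (length(nz) == 0L) return(c(0, 0))
    rk <- rank(abs(nz))
    c(sum(rk[nz > 0]), sum(rk[nz < 0]))
  }
  sums <- t(apply(d, 1L, rank_row))
  r_plus <- unname(sums[, 1L])
  r_minus <- unname(sums[, 2L])
  r_min <- pmin(r_plus, r_minus)

  ok <- n_eff >= 2L
  z <- rep(NA_real_, nrow(d))
  mu <- n_eff * (n_eff + 1) / 4
  sigma <- sqrt(n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24)
  z_raw <- (r_min - mu) / sigma
  z[ok] <- switch(pol$name,
    none = z_raw[ok],
    continuity = pmin(0, (r_min[ok] + 0.5 - mu[ok]) / sigma[ok]),
    shrink = {
      if (any(pol$c >= n_eff[ok])) {
        stop("shrink constant must be smaller than n_eff", call. = FALSE)
      }
      z_raw[ok] * sqrt((n_eff[ok] - pol$c) / n_eff[ok])
    }
  )
  p <- ifelse(ok, mwt_pvalue(z), 1)

  cm <- class_means(pem)
  fc <- fold_change(cm$x_bar, cm$y_bar)

  tibble::tibble(
    feature_id = pem$feature_ids,
    n_pairs = n,
    t_plus = as.integer(t_plus),
    t_minus = as.integer(t_minus),
    n_zero_diffs = as.integer(n_zero),
    misclassification_count = as.integer(pmin(t_plus, t_minus)),
    misclassification_rate = pmin(t_plus, t_minus) / n,
    r_plus = r_plus,
    r_minus = r_minus,
    z_value = z,
    p_mwt = p,
    fold_change = fc$fold_change,
    direction = fc$direction,
    cds_flag = ifelse(t_plus == n | t_minus == n, "CDS", "IDS"),
    mean_difference = unname(dm$d_bar),
    degenerate = !ok
  )
}
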