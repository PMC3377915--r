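# fast internal path: per-row MWT p-values for given class matrices
mwt_p_rows <- function(x, y, pol, cn_method) {
  x_bar <- rowMeans(x)
  y_bar <- rowMeans(y)
  d <- switch(cn_method,
    divide_opposite_mean = y / x_bar - x / y_bar,
    subtract_opposite_mean = (y - x_bar) - (x - y_bar),
    divide_opposite_pair = y / x - x / y
  )
  n <- ncol(d)
  rank_min <- function(di) {
    nz <- di[di != 0]
    n_eff <- length(nz)
    if (n_eff < 2L) return(c(NA_real_, n_eff))
    rk <- rank(abs(nz))
    rp <- sum(rk[nz > 0])
    c(min(rp, n_eff * (n_eff + 1) / 2 - rp), n_eff)
  }
  rm_ne <- t(apply(d, 1L, rank_min))
  r_min <- rm_ne[, 1L]
  n_eff <- rm_ne[, 2L]
  ok <- !is.na(r_min)
  mu <- n_eff * (n_eff + 1) / 4
  sigma <- sqrt(n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24)
  z <- rep(NA_real_, nrow(d))
  z[ok] <- switch(pol$name,
    none = (r_min[ok] - mu[ok]) / sigma[ok],
    continuity = pmin(0, (r_min[ok] + 0.5 - mu[ok]) / sigma[ok]),
    shrink = (r_min[ok] - mu[ok]) / sigma[ok] *
      sqrt((n_eff[ok] - pol$c) / n_eff[ok])
  )
  unname(ifelse(ok, pmin(1, 2 * stats::pnorm(-abs(z))), 1))
}

#' Pair-resampling bootstrap filter
#'
#' For each feature, patient pairs are resampled with replacement `n_boot`
#' times; cross-normalization and the modified Wilcoxon test are recomputed
#' on every replicate (class means change under resampling), giving a
#' replicate p-value `Pboot`. The reported statistic is
#' `p_boot = #(Pboot < Ptest) / n_boot` with a strict inequality, where
#' `Ptest` is the observed MWT p-value. A zero-misclassification feature
#' can never yield a strictly smaller replicate p (its observed p is the
#' minimum attainable at the full pair count), so its `p_boot` is exactly 0.
#'
#' @param pem A [paired_expression()] object.
#' @param features Optional character vector of feature ids to bootstrap
#'   (default: all).
#' @param n_boot Number of replicates (default 9999).
#' @param seed Integer seed; required for reproducibility.
#' @param null Resampling scheme: `"resample"` (default) draws patient
#'   pairs with replacement, preserving the paired dependence structure;
#'   `"signflip"` instead swaps the two class values within a random subset
#'   of patients, a classical symmetric-null permutation.
#' @param z_correction,cn_method Passed to the MWT recomputation.
#' @return A tibble with columns `feature_id`, `p_test`, `n_boot`,
#'   `n_less`, `p_boot`, `seed`.
#' @export
bootstrap_filter <- function(pem, features = NULL, n_boot = 9999, seed,
                             null = c("resample", "signflip"),
                             z_correction = "continuity",
                             cn_method = "divide_opposite_mean") {
  stopifnot(inherits(pem, "paired_expr"), n_boot >= 1)
  null <- match.arg(null)
  if (missing(seed) || is.null(seed)) {
    stop("bootstrap_filter() requires an explicit seed", call. = FALSE)
  }
  pol <- parse_z_policy(z_correction)
  if (!is.null(features)) pem <- filter_features(pem, features)
  n <- ncol(pem$x)
  p_test <- mwt_p_rows(pem$x, pem$y, pol, cn_method)
  n_less <- integer(nrow(pem$x))

  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_boot)) {
      if (null == "resample") {
        repeat {  # guard against degenerate draws with < 2 distinct patients
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(idx)) >= 2L) break
        }
        xb <- pem$x[, idx, drop = FALSE]
        yb <- pem$y[, idx, drop = FALSE]
      } else {
        flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
        xb <- pem$x
        yb <- pem$y
        xb[, flip] <- pem$y[, flip]
        yb[, flip] <- pem$x[, flip]
      }
      p_b <- mwt_p_rows(xb, yb, pol, cn_method)
      n_less <- n_less + (p_b < p_test)
    }
  })

  tibble::tibble(
    feature_id = pem$feature_ids,
    p_test = p_test,
    n_boot = as.integer(n_boot),
    n_less = as.integer(n_less),
    p_boot = n_less / n_boot,
    seed = as.integer(seed)
  )
}
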