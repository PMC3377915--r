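#' Paired Student's t-test per feature
#'
#' Classical paired t-test on the raw (not cross-normalized) differences
#' `D = y - x`: `t = mean(D) * sqrt(N) / sd(D)` on `N - 1` degrees of
#' freedom, two-sided. Features with zero difference variance are flagged
#' degenerate (`p = 0` if the mean difference is non-zero, else `p = 1`).
#'
#' @param pem A [paired_expression()] object.
#' @return A tibble: `feature_id`, `t_statistic`, `df`, `p_value`,
#'   `degenerate`.
#' @export
paired_t_test <- function(pem) {
  stopifnot(inherits(pem, "paired_expr"))
  d <- pem$y - pem$x
  n <- ncol(d)
  d_bar <- unname(rowMeans(d))
  sd_d <- unname(sqrt(rowSums((d - d_bar)^2) / (n - 1)))
  degenerate <- sd_d == 0
  t_stat <- ifelse(degenerate, NA_real_, d_bar * sqrt(n) / sd_d)
  p <- ifelse(degenerate, ifelse(d_bar != 0, 0, 1),
              2 * stats::pt(-abs(t_stat), df = n - 1))
  tibble::tibble(
    feature_id = pem$feature_ids, t_statistic = t_stat, df = n - 1,
    p_value = p, degenerate = degenerate
  )
}

#' Standard Wilcoxon signed-rank test per feature
#'
#' The same signed-rank machinery as [mwt_test()] but applied to raw paired
#' differences, without cross-normalization — the canonical baseline the
#' modified test is compared against. Uses the continuity-corrected normal
#' approximation.
#'
#' @param pem A [paired_expression()] object.
#' @param z_correction Correction policy (default `"continuity"`).
#' @return A tibble: `feature_id`, `r_plus`, `r_minus`, `z_value`,
#'   `p_value`, `n_eff`, `degenerate`.
#' @export
standard_wilcoxon <- function(pem, z_correction = "continuity") {
  stopifnot(inherits(pem, "paired_expr"))
  pol <- parse_z_policy(z_correction)
  d <- pem$y - pem$x
  stats_row <- function(di) {
    s <- signed_rank_sums(di)
    c(s$r_plus, s$r_minus, s$n_eff)
  }
  sums <- t(apply(d, 1L, stats_row))
  r_plus <- unname(sums[, 1L])
  r_minus <- unname(sums[, 2L])
  n_eff <- unname(sums[, 3L])
  r_min <- pmin(r_plus, r_minus)
  ok <- n_eff >= 2L
  mu <- n_eff * (n_eff + 1) / 4
  sigma <- sqrt(n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24)
  z <- rep(NA_real_, nrow(d))
  z[ok] <- switch(pol$name,
    none = (r_min[ok] - mu[ok]) / sigma[ok],
    continuity = pmin(0, (r_min[ok] + 0.5 - mu[ok]) / sigma[ok]),
    shrink = (r_min[ok] - mu[ok]) / sigma[ok] *
      sqrt((n_eff[ok] - pol$c) / n_eff[ok])
  )
  tibble::tibble(
    feature_id = pem$feature_ids, r_plus = r_plus, r_minus = r_minus,
    z_value = z, p_value = ifelse(ok, mwt_pvalue(z), 1),
    n_eff = as.integer(n_eff), degenerate = !ok
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Deterministic top-k feature selection
#'
#' Orders features by an ascending ranking key (ties broken by feature id)
#' and returns the first `k` ids — how same-size gene lists are drawn from
#' different methods for overlap comparisons.
#'
#' @param results A tibble with at least `feature_id` and the key column.
#' @param k Number of features to keep.
#' @param key Name of the ranking column (default `"fdr"`).
#' @return Character vector of at most `k` feature ids.
#' @export
top_k <- function(results, k, key = "fdr") {
  stopifnot(k >= 0, key %in% names(results))
  if (k > nrow(results)) {
    warning("k exceeds the number of features; returning all", call. = FALSE)
    k <- nrow(results)
  }
  ord <- dplyr::arrange(results, .data[[key]], .data$feature_id)
  utils::head(ord$feature_id, k)
}

#' Hypergeometric test of gene-list overlap
#'
#' Upper-tail probability that two lists of sizes `n` and `m`, drawn at
#' random from a universe of `n_universe` features, share `k` or more
#' members — the significance test behind Venn-diagram overlaps. The
#' default universe, 13074, is the number of RefSeq genes non-redundantly
#' represented on the U133A microarray. A two-sided mode sums all
#' overlap counts whose probability does not exceed that of the observed
#' one (the Fisher-exact two-tail convention).
#'
#' @param k Observed overlap count.
#' @param n,m Sizes of the two lists.
#' @param n_universe Universe size (default 13074).
#' @param alternative `"greater"` (default, over-representation) or
#'   `"two.sided"`.
#' @return A one-row tibble: `k`, `n`, `m`, `n_universe`, `p_value`,
#'   `fold_enrichment` (`k / (n m / N)`), `alternative`.
#' @examples
#' overlap_test(3, 4, 5, 10)  # p = 55/210
#' @export
overlap_test <- function(k, n, m, n_universe = 13074,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n <= n_universe, m <= n_universe, k >= 0)
  if (k > min(n, m)) {
    stop("impossible overlap geometry: k exceeds min(n, m)", call. = FALSE)
  }
  # overlap ~ Hypergeometric(white = m, black = N - m, drawn = n)
  if (alternative == "greater") {
    p <- stats::phyper(k - 1, m, n_universe - m, n, lower.tail = FALSE)
  } else {
    support <- max(0, n + m - n_universe):min(n, m)
    dens <- stats::dhyper(support, m, n_universe - m, n)
    p_obs <- stats::dhyper(k, m, n_universe - m, n)
    p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  }
  tibble::tibble(
    k = k, n = n, m = m, n_universe = n_universe,
    p_value = min(1, p),
    fold_enrichment = k / (n * m / n_universe),
    alternative = alternative
  )
}
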