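#' Sign-symmetry binomial tail probability
#'
#' Probability of observing at most `s` minority signs among `n_pairs`
#' independent pairs when positive and negative differences are equally
#' likely (sign probability 0.5): the lower binomial tail
#' `sum_{k=0}^{s} C(n, k) 0.5^n`. This quantifies how unlikely a feature
#' with few misclassifications is under pure chance.
#'
#' @param s Misclassification count (0 <= s <= n_pairs).
#' @param n_pairs Number of patient pairs.
#' @param alternative `"less"` (default, lower tail) or `"two.sided"`
#'   (doubled, capped at 1).
#' @return The tail probability.
#' @examples
#' sign_test_pvalue(2, 27)   # 379 / 2^27 = 2.8237e-06
#' sign_test_pvalue(0, 4)    # 1/16
#' @export
sign_test_pvalue <- function(s, n_pairs, alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(s) == 1L, length(n_pairs) == 1L, n_pairs >= 1)
  if (s < 0 || s > n_pairs) {
    stop("misclassification count must lie in [0, n_pairs]", call. = FALSE)
  }
  p <- stats::pbinom(s, size = n_pairs, prob = 0.5)
  if (alternative == "two.sided") p <- min(1, 2 * p)
  p
}

#' Bonferroni adjustment
#'
#' @param p_raw Raw probability.
#' @param m_tests Number of tests (e.g. the number of features screened).
#' @return `min(1, p_raw * m_tests)`.
#' @examples
#' bonferroni(sign_test_pvalue(2, 27), 22283)  # 0.0629
#' @export
bonferroni <- function(p_raw, m_tests) {
  stopifnot(m_tests >= 1)
  pmin(1, p_raw * m_tests)
}

#' Sign-symmetry test with multiplicity correction
#'
#' Convenience wrapper: binomial tail probability of at most `s`
#' misclassifications in `n_pairs` pairs, Bonferroni-adjusted over
#' `m_tests` features. Used as a plausibility bound on how many
#' low-error features chance alone would supply in a genome-wide screen.
#'
#' @inheritParams sign_test_pvalue
#' @param m_tests Bonferroni multiplier (number of features screened).
#' @return A one-row tibble: `s`, `n_pairs`, `p_raw`, `m_tests`,
#'   `p_adjusted`.
#' @examples
#' sign_symmetry_test(2, 27, 22283)
#' @export
sign_symmetry_test <- function(s, n_pairs, m_tests = 1,
                               alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  p_raw <- sign_test_pvalue(s, n_pairs, alternative)
  tibble::tibble(
    s = as.integer(s), n_pairs = as.integer(n_pairs), p_raw = p_raw,
    m_tests = as.integer(m_tests), p_adjusted = bonferroni(p_raw, m_tests)
  )
}
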