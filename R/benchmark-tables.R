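#' Bundled benchmark tables
#'
#' Three small published benchmark tables for a 27-pair lung
#' adenocarcinoma (tumour vs adjacent tissue) microarray screen ship with
#' the package as plain TSV under `inst/extdata`:
#'
#' * `lung_ac_marker_coverage.tsv` — 28 early-diagnosis lung AC marker
#'   genes with YES/NO membership in the default (zero-error)
#'   discriminative signature, its relaxed extension (up to 3 errors), and
#'   an alternative method's list; genes lacking a U133A probe set are
#'   marked `no_probe`.
#' * `misclassification_distribution.tsv` — per-method counts of features
#'   by misclassified-pair level, split by regulation direction, for
#'   equal-size (2,829-feature) signatures.
#' * `mutagenesis_subsets.tsv` — protein-ID and mutagenesis-site counts in
#'   the common and unique subsets of the discriminative signature and a
#'   literature meta-signature.
#'
#' @param name File name of the bundled table.
#' @return A tibble.
#' @export
ecd_example_table <- function(name = c("lung_ac_marker_coverage",
                                       "misclassification_distribution",
                                       "mutagenesis_subsets")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "ecdselect",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' Marker coverage of a signature column
#'
#' Fraction (as a percentage) of marker genes covered by a signature,
#' counting only genes that have at least one probe set on the platform:
#' `100 * #YES / #(YES or NO)`.
#'
#' @param coverage A tibble in the layout of
#'   `ecd_example_table("lung_ac_marker_coverage")`: one row per marker
#'   gene, columns holding `"YES"`, `"NO"` or `"no_probe"`.
#' @param column Which signature column to score.
#' @return A one-row tibble: `n_covered`, `n_evaluable`, `coverage_pct`.
#' @examples
#' marker_coverage(ecd_example_table(), "ecd_default")
#' @export
marker_coverage <- function(coverage, column) {
  stopifnot(column %in% names(coverage))
  status <- coverage[[column]]
  evaluable <- status %in% c("YES", "NO")
  n_cov <- sum(status == "YES")
  tibble::tibble(
    n_covered = n_cov,
    n_evaluable = sum(evaluable),
    coverage_pct = 100 * n_cov / sum(evaluable)
  )
}

#' Fraction of features with at least a given misclassification level
#'
#' Summarises a per-method misclassification distribution (layout of
#' `ecd_example_table("misclassification_distribution")`) into the
#' fraction of features misclassifying at least `min_errors` pairs.
#'
#' @param distribution Tibble with columns `direction`, `errors`, and one
#'   count column per method.
#' @param method Name of the method count column.
#' @param min_errors Error threshold (default 2).
#' @return A one-row tibble: `n_at_or_above`, `n_total`, `fraction`.
#' @examples
#' error_fraction(ecd_example_table("misclassification_distribution"), "pam")
#' @export
error_fraction <- function(distribution, method, min_errors = 2L) {
  stopifnot(method %in% names(distribution),
            all(c("errors") %in% names(distribution)))
  n_total <- sum(distribution[[method]])
  n_ge <- sum(distribution[[method]][distribution$errors >= min_errors])
  tibble::tibble(
    n_at_or_above = n_ge, n_total = n_total, fraction = n_ge / n_total
  )
}
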