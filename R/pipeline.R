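#' Configuration for the extreme-class-discrimination pipeline
#'
#' The strict selection keeps features that separate every patient pair
#' (zero misclassifications), are MWT-significant, survive the bootstrap at
#' `boot_alpha_strict`, and exceed `min_fc_strict` fold change. The relaxed
#' selection tolerates up to `max_errors` misclassified pairs but demands a
#' stricter bootstrap level and applies its own fold-change floor — the
#' trade the relaxation makes to contain false positives.
#'
#' @param max_errors Maximum misclassified pairs tolerated by the relaxed
#'   selection (default 2; must stay below half the pair count).
#' @param min_fc_strict,min_fc_relaxed Fold-change floors (defaults 1.35
#'   and 1.2).
#' @param mwt_alpha Per-feature MWT p-value threshold (default 0.05).
#' @param boot_alpha_strict,boot_alpha_relaxed Bootstrap p thresholds
#'   (defaults 0.05 and 0.01).
#' @param n_boot Bootstrap replicates (default 9999).
#' @param seed Integer seed driving the bootstrap.
#' @param z_correction,cn_method See [corrected_z()] and
#'   [cross_normalize()].
#' @param bonferroni_m Multiplier for the annotated sign-symmetry p-value
#'   (default `NULL`: use the number of features tested).
#' @return An `ecd_config` list.
#' @export
ecd_config <- function(max_errors = 2L, min_fc_strict = 1.35,
                       min_fc_relaxed = 1.2, mwt_alpha = 0.05,
                       boot_alpha_strict = 0.05, boot_alpha_relaxed = 0.01,
                       n_boot = 9999L, seed = 1L,
                       z_correction = "continuity",
                       cn_method = "divide_opposite_mean",
                       bonferroni_m = NULL) {
  stopifnot(max_errors >= 0, min_fc_strict >= 1, min_fc_relaxed >= 1,
            mwt_alpha > 0, mwt_alpha <= 1,
            boot_alpha_strict > 0, boot_alpha_strict <= 1,
            boot_alpha_relaxed > 0, boot_alpha_relaxed <= 1, n_boot >= 1)
  parse_z_policy(z_correction)
  structure(
    list(max_errors = as.integer(max_errors), min_fc_strict = min_fc_strict,
         min_fc_relaxed = min_fc_relaxed, mwt_alpha = mwt_alpha,
         boot_alpha_strict = boot_alpha_strict,
         boot_alpha_relaxed = boot_alpha_relaxed, n_boot = as.integer(n_boot),
         seed = as.integer(seed), z_correction = z_correction,
         cn_method = cn_method, bonferroni_m = bonferroni_m),
    class = "ecd_config"
  )
}

#' Run the extreme-class-discrimination selection pipeline
#'
#' Orchestrates cross-normalization, the modified Wilcoxon test,
#' misclassification accounting, the pair-resampling bootstrap, and the
#' fold-change filter. The bootstrap is computed only for features that
#' survive the misclassification and MWT filters (the end result is
#' identical to bootstrapping everything, at a fraction of the cost);
#' features never bootstrapped carry `p_bootstrap = NA` and are unselected.
#'
#' @param pem A [paired_expression()] object.
#' @param config An [ecd_config()].
#' @param verbose Log per-stage feature counts to stderr.
#' @return An `ecd_result` object with elements `results` (full per-feature
#'   tibble, including `selected_strict` / `selected_relaxed` flags and an
#'   annotated Bonferroni sign-symmetry p-value), `histogram` (the
#'   misclassification distribution by direction), `config`, and
#'   `n_features`, `n_pairs`.
#' @examples
#' sim <- simulate_paired(n_features = 50, n_patients = 8,
#'                        effect_fraction = 0.2, seed = 1)
#' fit <- run_ecd(sim$data, ecd_config(n_boot = 99, seed = 1))
#' glance(fit)
#' @export
run_ecd <- function(pem, config = ecd_config(), verbose = FALSE) {
  stopifnot(inherits(pem, "paired_expr"), inherits(config, "ecd_config"))
  n <- length(pem$patient_ids)
  m <- length(pem$feature_ids)
  if (config$max_errors >= n / 2) {
    warning("max_errors >= N/2 makes the relaxed error filter vacuous",
            call. = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))

  res <- mwt_test(pem, z_correction = config$z_correction,
                  cn_method = config$cn_method)
  say("MWT scored %d features over %d pairs", m, n)

  pass_error_relaxed <- res$misclassification_count <= config$max_errors &
    !res$degenerate
  pass_mwt <- res$p_mwt < config$mwt_alpha
  boot_candidates <- res$feature_id[pass_error_relaxed & pass_mwt]
  say("error filter (<= %d) and MWT alpha %.3g kept %d features",
      config$max_errors, config$mwt_alpha, length(boot_candidates))

  res$p_bootstrap <- NA_real_
  if (length(boot_candidates) > 0L) {
    boot <- bootstrap_filter(
      pem, features = boot_candidates, n_boot = config$n_boot,
      seed = config$seed, z_correction = config$z_correction,
      cn_method = config$cn_method
    )
    res$p_bootstrap[match(boot$feature_id, res$feature_id)] <- boot$p_boot
  }

  pass_boot_strict <- !is.na(res$p_bootstrap) &
    res$p_bootstrap < config$boot_alpha_strict
  pass_boot_relaxed <- !is.na(res$p_bootstrap) &
    res$p_bootstrap < config$boot_alpha_relaxed
  res$selected_strict <- res$misclassification_count == 0L & !res$degenerate &
    pass_mwt & pass_boot_strict & res$fold_change > config$min_fc_strict
  res$selected_relaxed <- pass_error_relaxed & pass_mwt & pass_boot_relaxed &
    res$fold_change > config$min_fc_relaxed
  say("selected %d strict / %d relaxed features",
      sum(res$selected_strict), sum(res$selected_relaxed))

  # annotation only: chance-level bound on each feature's error count
  m_bonf <- if (is.null(config$bonferroni_m)) m else config$bonferroni_m
  by_count <- vapply(
    sort(unique(res$misclassification_count)),
    function(s) bonferroni(sign_test_pvalue(s, n), m_bonf), numeric(1)
  )
  names(by_count) <- sort(unique(res$misclassification_count))
  res$p_sign_adjusted <- unname(
    by_count[as.character(res$misclassification_count)]
  )

  structure(
    list(results = res,
         histogram = misclassification_histogram(res),
         config = config, n_features = m, n_pairs = n),
    class = "ecd_result"
  )
}

#' Misclassification histogram by regulation direction
#'
#' Tabulates how many features misclassify 0, 1, 2, ... patient pairs,
#' split by up/down fold-change direction, together with the overall
#' fraction of features misclassifying two or more pairs — the accounting
#' used to compare selection methods.
#'
#' @param results A scored results tibble (from [mwt_test()] or the
#'   `results` element of [run_ecd()]).
#' @return A list with `counts` (tibble: `direction`, `errors`, `n`) and
#'   `fraction_ge2` (fraction of features with >= 2 errors).
#' @export
misclassification_histogram <- function(results) {
  counts <- dplyr::count(
    results, .data$direction, errors = .data$misclassification_count
  )
  list(
    counts = counts,
    fraction_ge2 = mean(results$misclassification_count >= 2L)
  )
}

#' @export
print.ecd_result <- function(x, ...) {
  cat(sprintf("<ecd_result> %d features, %d patient pairs\n",
              x$n_features, x$n_pairs))
  cat(sprintf("  strict selection:  %d features (0 errors, boot p < %.3g, fc > %.3g)\n",
              sum(x$results$selected_strict), x$config$boot_alpha_strict,
              x$config$min_fc_strict))
  cat(sprintf("  relaxed selection: %d features (<= %d errors, boot p < %.3g, fc > %.3g)\n",
              sum(x$results$selected_relaxed), x$config$max_errors,
              x$config$boot_alpha_relaxed, x$config$min_fc_relaxed))
  cat(sprintf("  features with >= 2 misclassified pairs: %.3g%%\n",
              100 * x$histogram$fraction_ge2))
  invisible(x)
}

#' Tidy an ECD selection result
#'
#' @param x An `ecd_result` from [run_ecd()].
#' @param ... Unused.
#' @return The per-feature results tibble.
#' @method tidy ecd_result
#' @export
tidy.ecd_result <- function(x, ...) x$results

#' One-row summary of an ECD selection result
#'
#' @param x An `ecd_result` from [run_ecd()].
#' @param ... Unused.
#' @return A one-row tibble with feature/pair counts, numbers of CDS and
#'   selected features, and the >= 2-error fraction.
#' @method glance ecd_result
#' @export
glance.ecd_result <- function(x, ...) {
  tibble::tibble(
    n_features = x$n_features,
    n_pairs = x$n_pairs,
    n_cds = sum(x$results$cds_flag == "CDS"),
    n_selected_strict = sum(x$results$selected_strict),
    n_selected_relaxed = sum(x$results$selected_relaxed),
    fraction_ge2_errors = x$histogram$fraction_ge2
  )
}

#' Plot the misclassification distribution of an ECD result
#'
#' @param object An `ecd_result` from [run_ecd()].
#' @param ... Unused.
#' @return A ggplot: feature counts per misclassification level, split by
#'   up/down regulation direction.
#' @method autoplot ecd_result
#' @export
autoplot.ecd_result <- function(object, ...) {
  ggplot2::ggplot(
    object$histogram$counts,
    ggplot2::aes(x = factor(.data$errors), y = .data$n,
                 fill = .data$direction)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "misclassified patient pairs",
      y = "features",
      fill = "direction",
      title = "Misclassification distribution after cross-normalized MWT"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-pair separation of one feature
#'
#' Shows tumour and normal values for each patient (rank-ordered by the
#' tumour value) before or after cross-normalization — the visual check of
#' how completely a candidate marker separates the matched classes.
#'
#' @param pem A [paired_expression()] object.
#' @param feature A single feature id.
#' @param cross_normalized Plot cross-normalized ratios (default) or raw
#'   intensities.
#' @return A ggplot.
#' @export
plot_pair_separation <- function(pem, feature, cross_normalized = TRUE) {
  stopifnot(inherits(pem, "paired_expr"), length(feature) == 1L)
  sub <- filter_features(pem, feature)
  if (cross_normalized) {
    cn <- cross_normalize(sub)
    xv <- cn$x_cn[1L, ]
    yv <- cn$y_cn[1L, ]
    ylab <- "cross-normalized intensity"
  } else {
    xv <- sub$x[1L, ]
    yv <- sub$y[1L, ]
    ylab <- "intensity"
  }
  ord <- order(yv)
  df <- tibble::tibble(
    patient = factor(sub$patient_ids[ord], levels = sub$patient_ids[ord]),
    normal = xv[ord], tumour = yv[ord]
  )
  long <- tidyr::pivot_longer(df, c("normal", "tumour"),
                              names_to = "class", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient, y = .data$value,
                                     colour = .data$class,
                                     group = .data$patient)) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "patient (ordered by tumour value)", y = ylab,
                  title = feature) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
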