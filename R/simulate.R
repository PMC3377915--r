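#' Simulate paired expression data with known ground truth
#'
#' Generates matched two-class intensities under an additive random-effects
#' model on the latent (log) scale:
#' `x_ij = mu_j + alpha_i + eps^x_ij` and
#' `y_ij = mu_j + theta_j + alpha_i + eps^y_ij`, where `alpha_i` is a
#' patient effect shared by both members of a pair (the "stable
#' confounder" a paired design cancels), `mu_j` a per-feature baseline,
#' `theta_j` a disease effect carried by a designated fraction of features
#' (random up/down direction), and the residuals are independent normals.
#' With `intensity_transform = TRUE` (default) both matrices are
#' exponentiated, producing strictly positive, MAS5-like log-normal
#' intensities; the linear-scale mode serves closed-form unit checks.
#'
#' Defaults mirror a tumour/adjacent-tissue microarray screen: 27 patient
#' pairs, baseline centred at `log(500)` (the conventional scaling target
#' of MAS5 output), patient effects comparable to the baseline spread, and
#' residual noise at half that.
#'
#' @param n_features Number of features M (default 1000).
#' @param n_patients Number of patient pairs N (default 27).
#' @param effect_fraction Fraction of features given a non-zero effect
#'   (default 0.01).
#' @param theta_mean,theta_sd Mean and spread of the effect magnitude on
#'   the log scale (defaults 2 and 0; signs are assigned at random).
#' @param alpha_sd SD of the shared per-patient effect (default 1).
#' @param eps_sd SD of the residual noise, same for both classes
#'   (default 0.5); `eps_sd_y` may override the tumour class.
#' @param mu_mean,mu_sd Mean and SD of the per-feature baseline (defaults
#'   `log(500)` and 1).
#' @param intensity_transform Exponentiate to positive intensities
#'   (default `TRUE`).
#' @param eps_sd_y Optional residual SD for class Y (defaults to `eps_sd`).
#' @param seed Integer seed; the whole draw is scoped with
#'   [withr::with_seed()] so calls are deterministic and order-independent.
#' @return A list with `data` (a [paired_expression()] object) and `truth`
#'   (tibble: `feature_id`, `theta`, `direction` with `"null"` for
#'   unaffected features, and the realized `alpha` vector as an attribute).
#' @examples
#' sim <- simulate_paired(n_features = 100, n_patients = 10,
#'                        effect_fraction = 0.1, seed = 42)
#' table(sim$truth$direction)
#' @export
simulate_paired <- function(n_features = 1000L, n_patients = 27L,
                            effect_fraction = 0.01, theta_mean = 2,
                            theta_sd = 0, alpha_sd = 1, eps_sd = 0.5,
                            mu_mean = log(500), mu_sd = 1,
                            intensity_transform = TRUE, eps_sd_y = eps_sd,
                            seed) {
  stopifnot(n_features >= 1, n_patients >= 2,
            effect_fraction >= 0, effect_fraction <= 1,
            theta_sd >= 0, alpha_sd >= 0, eps_sd >= 0, eps_sd_y >= 0)
  if (missing(seed) || is.null(seed)) {
    stop("simulate_paired() requires an explicit seed", call. = FALSE)
  }
  m <- as.integer(n_features)
  n <- as.integer(n_patients)
  n_spiked <- round(effect_fraction * m)

  withr::with_seed(as.integer(seed), {
    mu <- stats::rnorm(m, mu_mean, mu_sd)
    alpha <- stats::rnorm(n, 0, alpha_sd)
    theta <- numeric(m)
    if (n_spiked > 0L) {
      spiked <- sample.int(m, n_spiked)
      magnitude <- abs(stats::rnorm(n_spiked, theta_mean, theta_sd))
      sign <- sample(c(1, -1), n_spiked, replace = TRUE)
      theta[spiked] <- sign * magnitude
    }
    lat_x <- outer(mu, alpha, `+`) +
      matrix(stats::rnorm(m * n, 0, eps_sd), m, n)
    lat_y <- outer(mu + theta, alpha, `+`) +
      matrix(stats::rnorm(m * n, 0, eps_sd_y), m, n)
  })

  if (intensity_transform) {
    lat_x <- exp(lat_x)
    lat_y <- exp(lat_y)
  }
  feature_ids <- sprintf("feature_%05d", seq_len(m))
  patient_ids <- sprintf("patient_%03d", seq_len(n))
  if (intensity_transform) {
    pem <- paired_expression(lat_x, lat_y, feature_ids, patient_ids,
                             floor_eps = 0.01)
  } else {
    # linear-scale mode keeps the latent values as-is (they may be
    # non-positive); it serves closed-form checks of differences, not CN
    dimnames(lat_x) <- dimnames(lat_y) <- list(feature_ids, patient_ids)
    pem <- structure(
      list(x = lat_x, y = lat_y, feature_ids = feature_ids,
           patient_ids = patient_ids, n_floored = 0L),
      class = "paired_expr"
    )
  }

  truth <- tibble::tibble(
    feature_id = feature_ids,
    theta = theta,
    direction = dplyr::case_when(theta > 0 ~ "up", theta < 0 ~ "down",
                                 TRUE ~ "null")
  )
  attr(truth, "alpha") <- alpha
  attr(truth, "seed") <- as.integer(seed)
  list(data = pem, truth = truth)
}

#' Evaluate a selection against simulated ground truth
#'
#' @param selection Either an `ecd_result` (its strict selection is used
#'   unless `mode = "relaxed"`), or a tibble with columns `feature_id`,
#'   `selected` (logical) and optionally `direction`.
#' @param truth The `truth` tibble from [simulate_paired()].
#' @param mode Which selection of an `ecd_result` to score.
#' @return A one-row tibble: `n_selected`, `n_true`, `power` (selected true
#'   effects / true effects), `type_i_error` (selected nulls / nulls),
#'   `fdp` (selected nulls / selected, 0 when nothing is selected), and
#'   `direction_accuracy` on true positives (`NA` when there are none or
#'   directions are unavailable).
#' @export
evaluate_selection <- function(selection, truth,
                               mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  if (inherits(selection, "ecd_result")) {
    sel <- tibble::tibble(
      feature_id = selection$results$feature_id,
      selected = if (mode == "strict") selection$results$selected_strict
                 else selection$results$selected_relaxed,
      direction = selection$results$direction
    )
  } else {
    sel <- tibble::as_tibble(selection)
    stopifnot(all(c("feature_id", "selected") %in% names(sel)))
    if (!"direction" %in% names(sel)) sel$direction <- NA_character_
  }
  if (!setequal(sel$feature_id, truth$feature_id)) {
    stop("selection and truth refer to different feature ids", call. = FALSE)
  }
  j <- dplyr::inner_join(sel, truth, by = "feature_id",
                         suffix = c("_called", "_true"))
  is_true <- j$theta != 0
  tp <- j$selected & is_true
  fp <- j$selected & !is_true
  dir_acc <- if (any(tp) && !all(is.na(j$direction_called[tp]))) {
    mean(j$direction_called[tp] == j$direction_true[tp])
  } else {
    NA_real_
  }
  tibble::tibble(
    n_selected = sum(j$selected),
    n_true = sum(is_true),
    power = if (any(is_true)) sum(tp) / sum(is_true) else NA_real_,
    type_i_error = if (any(!is_true)) sum(fp) / sum(!is_true) else NA_real_,
    fdp = if (any(j$selected)) sum(fp) / sum(j$selected) else 0,
    direction_accuracy = dir_acc
  )
}
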