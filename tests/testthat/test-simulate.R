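test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_paired(n_features = 50, n_patients = 6,
                       effect_fraction = 0.1, seed = 202)
  b <- simulate_paired(n_features = 50, n_patients = 6,
                       effect_fraction = 0.1, seed = 202)
  expect_identical(a$data$x, b$data$x)
  expect_identical(a$data$y, b$data$y)
  expect_identical(a$truth, b$truth)
  expect_error(simulate_paired(n_features = 5, n_patients = 4,
                               effect_fraction = 0), "seed")
})

test_that("the spiked-feature count honours effect_fraction", {
  sim <- simulate_paired(n_features = 500, n_patients = 8,
                         effect_fraction = 0.03, seed = 205)
  expect_equal(sum(sim$truth$theta != 0), round(0.03 * 500))
  expect_true(all(sim$truth$direction[sim$truth$theta > 0] == "up"))
  expect_true(all(sim$truth$direction[sim$truth$theta == 0] == "null"))
  expect_true(all(sim$data$x > 0) && all(sim$data$y > 0))
})

test_that("null features have exchangeable classes: all-same-sign rate is 2/2^N", {
  # raw paired differences carry independent fair-coin signs under the
  # null, so the all-same-sign count is binomial with rate 2 * 0.5^8
  m <- 20000
  sim <- simulate_paired(n_features = m, n_patients = 8,
                         effect_fraction = 0, alpha_sd = 0, seed = 211)
  d_raw <- sim$data$y - sim$data$x
  all_same <- rowSums(d_raw > 0) %in% c(0L, 8L)
  p_cds <- 2 * 0.5^8
  expected <- m * p_cds
  se <- sqrt(m * p_cds * (1 - p_cds))
  expect_lt(abs(sum(all_same) - expected), 3 * se)
  # cross-normalization couples the signs through the estimated class
  # means, so its complete-separation rate under the null exceeds the
  # independent-sign binomial rate — the strict pipeline relies on the
  # MWT/bootstrap/fold-change filters, not on this rate alone
  res <- mwt_test(sim$data)
  expect_gt(sum(res$cds_flag == "CDS"), sum(all_same))
})

test_that("strong spikes are essentially always CDS", {
  eps_sd <- 0.5
  sim <- simulate_paired(n_features = 1000, n_patients = 27,
                         effect_fraction = 1, theta_mean = 10 * eps_sd,
                         eps_sd = eps_sd, seed = 223)
  res <- mwt_test(sim$data)
  expect_gte(mean(res$cds_flag == "CDS"), 0.999)
})

test_that("mean paired difference recovers theta on the latent scale", {
  eps_sd <- 0.5
  n <- 20
  sim <- simulate_paired(n_features = 200, n_patients = n,
                         effect_fraction = 0.5, theta_mean = 1.5,
                         eps_sd = eps_sd, intensity_transform = FALSE,
                         seed = 227)
  d_bar <- rowMeans(sim$data$y - sim$data$x)
  spiked <- sim$truth$theta != 0
  err <- d_bar[spiked] - sim$truth$theta[spiked]
  expect_lt(max(abs(err)), 3 * eps_sd * sqrt(2 / n) * 1.6)  # ~200 draws
  expect_lt(abs(mean(d_bar[!spiked])), 0.1)
})

test_that("patient effects cancel in paired tests but hurt unpaired ones", {
  run_at_alpha_sd <- function(alpha_sd) {
    sim <- simulate_paired(n_features = 300, n_patients = 10,
                           effect_fraction = 0.5, theta_mean = 0.8,
                           alpha_sd = alpha_sd, eps_sd = 0.5,
                           intensity_transform = FALSE, seed = 229)
    spiked <- sim$truth$theta != 0
    # paired analysis on the per-patient differences
    d <- sim$data$y - sim$data$x
    d_bar <- rowMeans(d)
    sd_d <- sqrt(rowSums((d - d_bar)^2) / (10 - 1))
    t_paired <- d_bar * sqrt(10) / sd_d
    paired_p <- 2 * stats::pt(-abs(t_paired), df = 9)
    # unpaired Welch analysis ignores the pairing
    unpaired_p <- vapply(seq_len(300), function(j) {
      stats::t.test(sim$data$y[j, ], sim$data$x[j, ])$p.value
    }, numeric(1))
    c(paired = mean(paired_p[spiked] < 0.05),
      unpaired = mean(unpaired_p[spiked] < 0.05))
  }
  low <- run_at_alpha_sd(0.2)
  high <- run_at_alpha_sd(3)
  # the paired test is insensitive to the shared patient effect
  expect_gte(high["paired"], low["paired"] - 0.1)
  # the unpaired test loses most of its power when alpha dominates
  expect_gt(low["unpaired"], high["unpaired"] + 0.2)
})

test_that("selection metrics follow their definitions and conventions", {
  truth <- tibble::tibble(
    feature_id = paste0("f", 1:10),
    theta = c(rep(2, 3), rep(0, 7)),
    direction = c(rep("up", 3), rep("null", 7))
  )
  perfect <- tibble::tibble(
    feature_id = truth$feature_id,
    selected = truth$theta != 0,
    direction = truth$direction
  )
  m <- evaluate_selection(perfect, truth)
  expect_equal(m$power, 1)
  expect_equal(m$type_i_error, 0)
  expect_equal(m$fdp, 0)
  expect_equal(m$direction_accuracy, 1)

  empty <- dplyr::mutate(perfect, selected = FALSE)
  e <- evaluate_selection(empty, truth)
  expect_equal(e$power, 0)
  expect_equal(e$fdp, 0)  # documented convention for empty selections

  expect_error(
    evaluate_selection(dplyr::mutate(perfect, feature_id = paste0("g", 1:10)),
                       truth),
    "different feature ids"
  )
})

test_that("a random half-selection scores near 0.5 power and type-I error", {
  m <- 2000
  truth <- tibble::tibble(
    feature_id = sprintf("f%04d", 1:m),
    theta = rep(c(1, 0), each = m / 2),
    direction = rep(c("up", "null"), each = m / 2)
  )
  withr::with_seed(233, sel <- sample(c(TRUE, FALSE), m, replace = TRUE))
  r <- evaluate_selection(
    tibble::tibble(feature_id = truth$feature_id, selected = sel), truth
  )
  se <- 3 * sqrt(0.25 / (m / 2))
  expect_lt(abs(r$power - 0.5), se)
  expect_lt(abs(r$type_i_error - 0.5), se)
})
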