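test_that("well-formed matrix and manifest round-trip into a paired matrix", {
  dir <- withr::local_tempdir()
  paths <- fixture_files_2x3(dir)
  pem <- read_paired_matrix(paths$matrix, paths$manifest)
  expect_s3_class(pem, "paired_expr")
  expect_equal(dim(pem), c(2L, 3L))
  expect_equal(pem$feature_ids, c("fA", "fB"))
  expect_equal(sort(pem$patient_ids), c("P1", "P2", "P3"))
  expect_equal(unname(pem$x["fA", ]), c(1, 2, 3))
  expect_equal(unname(pem$y["fA", ]), c(2, 4, 6))
})

test_that("pairing comes only from the manifest: column order is irrelevant", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- fixture_files_2x3(dir1, shuffle_cols = FALSE)
  p2 <- fixture_files_2x3(dir2, shuffle_cols = TRUE)
  r1 <- mwt_test(read_paired_matrix(p1$matrix, p1$manifest))
  r2 <- mwt_test(read_paired_matrix(p2$matrix, p2$manifest))
  expect_equal(r1, r2)
})

test_that("a patient with only one class half is rejected by name", {
  dir <- withr::local_tempdir()
  values <- tibble::tibble(feature_id = "fA", s1 = 1, s2 = 2, s3 = 3)
  manifest <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    patient_id = c("P1", "P1", "P2"),
    class = c("normal", "tumour", "tumour")
  )
  paths <- write_fixture_files(dir, values, manifest)
  expect_error(read_paired_matrix(paths$matrix, paths$manifest),
               "unpaired sample.*P2")
})

test_that("class labels are accepted case-insensitively across synonyms", {
  dir <- withr::local_tempdir()
  values <- tibble::tibble(feature_id = "fA", a = 1, b = 2, c = 3, d = 4)
  manifest <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    patient_id = c("P1", "P1", "P2", "P2"),
    class = c("Adjacent", "CANCER", "control", "Tumor")
  )
  paths <- write_fixture_files(dir, values, manifest)
  pem <- read_paired_matrix(paths$matrix, paths$manifest)
  expect_equal(unname(pem$x[1, ]), c(1, 3))
  expect_equal(unname(pem$y[1, ]), c(2, 4))
})

test_that("zero intensities are floored at epsilon with a warning count", {
  dir <- withr::local_tempdir()
  values <- tibble::tibble(
    feature_id = "fA", n1 = 0, n2 = 2, t1 = 3, t2 = 4
  )
  manifest <- tibble::tibble(
    sample_id = c("n1", "n2", "t1", "t2"),
    patient_id = c("P1", "P2", "P1", "P2"),
    class = c("normal", "normal", "tumour", "tumour")
  )
  paths <- write_fixture_files(dir, values, manifest)
  expect_warning(
    pem <- read_paired_matrix(paths$matrix, paths$manifest, floor_eps = 0.01),
    "floored 1"
  )
  expect_equal(unname(pem$x[1, "P1"]), 0.01)
  expect_equal(pem$n_floored, 1L)
  # with flooring disabled the same file is an invalid-intensity error
  expect_error(read_paired_matrix(paths$matrix, paths$manifest,
                                  floor_eps = NULL),
               "invalid intensity")
})

test_that("duplicate feature ids are rejected", {
  dir <- withr::local_tempdir()
  values <- tibble::tibble(
    feature_id = c("fA", "fA"), n1 = c(1, 2), t1 = c(3, 4),
    n2 = c(1, 2), t2 = c(3, 4)
  )
  manifest <- tibble::tibble(
    sample_id = c("n1", "n2", "t1", "t2"),
    patient_id = c("P1", "P2", "P1", "P2"),
    class = c("normal", "normal", "tumour", "tumour")
  )
  paths <- write_fixture_files(dir, values, manifest)
  expect_error(read_paired_matrix(paths$matrix, paths$manifest),
               "duplicate feature id")
})

test_that("results tables write sorted, round-trip, and handle edge cases", {
  skeleton <- tibble::tibble(
    feature_id = character(), n_pairs = integer(), t_plus = integer(),
    t_minus = integer(), n_zero_diffs = integer(),
    misclassification_count = integer(), misclassification_rate = double(),
    r_plus = double(), r_minus = double(), z_value = double(),
    p_mwt = double(), p_bootstrap = double(), fold_change = double(),
    direction = character(), cds_flag = character(),
    selected_strict = logical(), selected_relaxed = logical()
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(skeleton, path)
  expect_equal(length(readLines(path)), 1L)  # header only

  # equal p_mwt: ordered by |z| descending then feature_id
  tab <- dplyr::bind_rows(
    skeleton,
    tibble::tibble(
      feature_id = c("b", "a", "c"), n_pairs = 5L, t_plus = 5L, t_minus = 0L,
      n_zero_diffs = 0L, misclassification_count = 0L,
      misclassification_rate = 0, r_plus = 15, r_minus = 0,
      z_value = c(-2.0, -2.5, -2.5), p_mwt = 0.01, p_bootstrap = 0,
      fold_change = 2, direction = "up", cds_flag = "CDS",
      selected_strict = TRUE, selected_relaxed = TRUE
    )
  )
  out <- write_results(tab, path)
  expect_equal(out$feature_id, c("a", "c", "b"))

  back <- read_results(path)
  expect_equal(back$z_value, out$z_value, tolerance = 1e-6)
  expect_equal(back$p_mwt, out$p_mwt, tolerance = 1e-6)
  expect_equal(back$feature_id, out$feature_id)
})

test_that("validation enforces dimension and positivity invariants", {
  expect_error(paired_expression(matrix(1, 1, 1), matrix(1, 1, 1)),
               "at least 1 feature and 2 patients")
  expect_error(
    paired_expression(matrix(c(1, -2, 3, 4), 2), matrix(1, 2, 2),
                      floor_eps = NULL),
    "invalid intensity"
  )
  expect_error(
    paired_expression(matrix(1, 2, 2), matrix(1, 2, 2),
                      feature_ids = c("a", "a")),
    "unique"
  )
})
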