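# Shared fixtures and independent oracles for the test suite.

# build a paired_expr from per-feature value lists (rows)
make_pem <- function(x_rows, y_rows, feature_ids = NULL, floor_eps = NULL) {
  x <- do.call(rbind, x_rows)
  y <- do.call(rbind, y_rows)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(x)))
  paired_expression(x, y, feature_ids,
                    paste0("p", seq_len(ncol(x))), floor_eps = floor_eps)
}

# random strictly positive paired matrix
random_pem <- function(m, n, seed) {
  withr::with_seed(seed, {
    x <- matrix(exp(rnorm(m * n, log(500), 1)), m, n)
    y <- matrix(exp(rnorm(m * n, log(500), 1)), m, n)
  })
  paired_expression(x, y, sprintf("f%04d", seq_len(m)),
                    sprintf("p%03d", seq_len(n)), floor_eps = NULL)
}

# Independent signed-rank-sum oracle: average ranks computed by sorting
# positions, not via rank().
oracle_rank_sums <- function(d) {
  nz <- d[d != 0]
  a <- abs(nz)
  s <- sort(a)
  rk <- vapply(a, function(v) mean(which(s == v)), numeric(1))
  list(r_plus = sum(rk[nz > 0]), r_minus = sum(rk[nz < 0]))
}

# Exact two-sided signed-rank p-value at an observed smaller rank sum,
# by full enumeration of the 2^n equiprobable sign assignments of the
# (tie-free) ranks 1..n.
exact_signed_rank_p <- function(r_min, n) {
  stopifnot(n <= 16)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  r_plus <- as.vector(signs %*% seq_len(n))
  total <- n * (n + 1) / 2
  mean(r_plus <= r_min) + mean((total - r_plus) <= r_min)
}

# write a tiny expression matrix + manifest pair of TSV files; returns paths
write_fixture_files <- function(dir, values, manifest_rows) {
  matrix_path <- file.path(dir, "expr.tsv")
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(values, matrix_path, progress = FALSE)
  readr::write_tsv(manifest_rows, manifest_path, progress = FALSE)
  list(matrix = matrix_path, manifest = manifest_path)
}

# standard 2-feature, 3-patient fixture in file form
fixture_files_2x3 <- function(dir, shuffle_cols = FALSE) {
  values <- tibble::tibble(
    feature_id = c("fA", "fB"),
    n1 = c(1, 10), n2 = c(2, 20), n3 = c(3, 30),
    t1 = c(2, 15), t2 = c(4, 35), t3 = c(6, 50)
  )
  if (shuffle_cols) {
    values <- values[, c("feature_id", "t2", "n1", "t3", "n2", "t1", "n3")]
  }
  manifest <- tibble::tibble(
    sample_id = c("n1", "n2", "n3", "t1", "t2", "t3"),
    patient_id = rep(c("P1", "P2", "P3"), 2),
    class = c(rep("normal", 3), rep("tumour", 3))
  )
  write_fixture_files(dir, values, manifest)
}
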