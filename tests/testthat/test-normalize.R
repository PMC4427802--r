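test_that("log2 transform follows the closed form and guards its domain", {
  m <- make_intensity(matrix(c(8, 1, 0.5, 2, 4, 16), nrow = 3), stages = character())
  out <- log2_transform(m)
  expect_equal(unname(intensity_matrix(out)), matrix(c(3, 0, -1, 1, 2, 4), nrow = 3))
  expect_true("log2" %in% intensity_stages(out))
  # double application refused
  expect_error(log2_transform(out), "already", class = "serodiff_stage_error")
  # non-positive values named by protein and sample
  bad <- make_intensity(matrix(c(1, -2, 3, 4), nrow = 2,
    dimnames = list(c("pA", "pB"), c("s1", "s2"))
  ), stages = character())
  expect_error(log2_transform(bad), "pB.*s1", class = "serodiff_data_error")
  # missing entries pass through untouched
  wna <- make_intensity(matrix(c(8, NA, 2, 4), nrow = 2), stages = character())
  expect_equal(unname(intensity_matrix(log2_transform(wna))[2, 1]), NA_real_)
})

test_that("median normalization centres every sample and is idempotent", {
  m <- make_intensity(matrix(c(1, 2, 6, 1, 3, NA), nrow = 3))
  out <- median_normalize(m)
  mat <- intensity_matrix(out)
  expect_equal(unname(mat[, 1]), c(-1, 0, 4))
  expect_equal(unname(mat[, 2]), c(-1, 1, NA)) # even count: mean of middle two
  expect_true(all(abs(apply(mat, 2, median, na.rm = TRUE)) < 1e-9))
  # idempotent
  expect_equal(intensity_matrix(median_normalize(out)), mat)
  # all-missing column is an error
  allna <- make_intensity(matrix(c(1, 2, NA, NA), nrow = 2))
  expect_error(median_normalize(allna), "no observed", class = "serodiff_data_error")
})

test_that("quantile normalization matches the brute-force oracle", {
  # the 3x2 worked instance: columns {2,0,4} and {10,8,12} share sorted
  # reference {4,6,8}
  m <- make_intensity(matrix(c(2, 0, 4, 10, 8, 12), nrow = 3))
  out <- intensity_matrix(rank_normalize(m))
  expect_equal(unname(out), matrix(c(6, 4, 8, 6, 4, 8), nrow = 3))

  withr::with_seed(7, {
    for (i in 1:20) {
      mat <- matrix(rnorm(8 * 5), nrow = 8)
      got <- intensity_matrix(rank_normalize(make_intensity(mat)))
      expect_equal(unname(got), unname(quantile_normalize_oracle(mat)), tolerance = 1e-12)
    }
  })
})

test_that("rank normalization is rank-invariant, idempotent and tie-safe", {
  withr::with_seed(3, {
    mat <- matrix(rnorm(30), nrow = 10)
    # a strictly increasing per-sample transform leaves the rank structure of
    # the normalized values unchanged in every sample
    warped <- mat
    warped[, 1] <- exp(mat[, 1])
    warped[, 2] <- 2 * mat[, 2] + 5
    a <- intensity_matrix(rank_normalize(make_intensity(mat)))
    b <- intensity_matrix(rank_normalize(make_intensity(warped)))
    for (j in 1:3) expect_equal(rank(a[, j]), rank(b[, j]), ignore_attr = TRUE)
    # two samples that are monotone transforms of each other come out
    # identical after normalization
    pair <- cbind(mat[, 1], exp(mat[, 1]), mat[, 3])
    p_out <- intensity_matrix(rank_normalize(make_intensity(pair)))
    expect_equal(p_out[, 1], p_out[, 2], ignore_attr = TRUE, tolerance = 1e-12)
    # idempotence on complete matrices
    once <- rank_normalize(make_intensity(mat))
    twice <- rank_normalize(once)
    expect_equal(intensity_matrix(twice), intensity_matrix(once), tolerance = 1e-12)
    # complete samples end with identical sorted value multisets
    sorted <- apply(intensity_matrix(once), 2, sort)
    expect_equal(sorted[, 1], sorted[, 2], ignore_attr = TRUE)
    expect_equal(sorted[, 1], sorted[, 3], ignore_attr = TRUE)
  })
  # a constant sample maps to tie-averaged reference values
  m <- make_intensity(matrix(c(5, 5, 5, 1, 2, 3), nrow = 3))
  out <- intensity_matrix(rank_normalize(m))
  expect_equal(unname(out[, 1]), rep(mean(out[, 2]), 3))
})

test_that("the chain preserves shape, missingness and within-sample order", {
  withr::with_seed(11, {
    mat <- matrix(rnorm(200), nrow = 20)
    mat[sample(length(mat), 30)] <- NA
    m <- make_intensity(mat)
    out <- normalize_intensity(m)
    omat <- intensity_matrix(out)
    expect_equal(dim(omat), dim(mat))
    expect_identical(unname(is.na(omat)), is.na(mat))
    # monotonicity within each sample at every stage
    med <- intensity_matrix(median_normalize(m))
    rnk <- intensity_matrix(rank_normalize(median_normalize(m)))
    for (j in seq_len(ncol(mat))) {
      obs <- !is.na(mat[, j])
      expect_equal(order(mat[obs, j]), order(med[obs, j]), ignore_attr = TRUE)
      expect_equal(rank(mat[obs, j]), rank(rnk[obs, j]), ignore_attr = TRUE)
    }
  })
})

test_that("the per-protein rank alternative replaces values by ranks", {
  m <- make_intensity(matrix(c(3, 10, 1, 20, 2, 30), nrow = 2, byrow = TRUE))
  out <- intensity_matrix(rank_normalize(m, method = "protein_rank"))
  expect_equal(unname(out[1, ]), c(2, 3, 1))
  expect_equal(unname(out[2, ]), c(2, 1, 3))
})
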