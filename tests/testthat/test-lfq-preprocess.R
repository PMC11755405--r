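test_that("detection filter applies the unique-peptide and coverage rules", {
  meta <- two_group_metadata(15, 15)
  mk_row <- function(n_obs_a, n_obs_b) {
    c(ifelse(seq_len(15) <= n_obs_a, 100, NA),
      ifelse(seq_len(15) <= n_obs_b, 100, NA))
  }
  mat <- rbind(p_60_in_a = mk_row(9, 0),    # 60% in A -> retained
               p_53_both = mk_row(8, 8),    # 53.3% everywhere -> removed
               p_no_unique = mk_row(15, 15),# full coverage, 0 unique pep
               p_full = mk_row(15, 15))
  colnames(mat) <- meta$sample_id
  data <- abundance_from_matrix(mat, unique_peptides = c(3L, 3L, 0L, 2L))

  kept <- filter_by_detection(data, meta)
  expect_identical(kept$protein_id, c("p_60_in_a", "p_full"))

  # idempotent, order preserved
  expect_identical(filter_by_detection(kept, meta), kept)

  # a referenced group with no samples errors by name
  expect_error(filter_by_detection(data, meta, groups = c("A", "C")), "C")

  # zero intensities do not count as detected
  mat2 <- rbind(pz = c(rep(0, 15), rep(100, 8)[c(1:8)], rep(NA, 7)))
  colnames(mat2) <- meta$sample_id
  d2 <- abundance_from_matrix(mat2, unique_peptides = 5L)
  expect_identical(nrow(filter_by_detection(d2, meta)), 0L)
})

test_that("summed-intensity normalization equalizes sample sums, preserves ratios", {
  meta <- two_group_metadata(1, 1)
  mat <- rbind(p1 = c(30, 150), p2 = c(70, 50))  # sums 100, 200; median 150
  colnames(mat) <- meta$sample_id
  norm <- normalize_sum(abundance_from_matrix(mat))

  f <- norm_factors(norm)
  expect_equal(f$factor, c(1.5, 0.75))
  post <- as.matrix(norm[sample_cols_of(norm)])
  expect_equal(unname(colSums(post)), c(150, 150), tolerance = 1e-9)
  # within-sample ratios untouched (row 1 = p1, row 2 = p2)
  expect_equal(unname(post[1, 1] / post[2, 1]), 30 / 70, tolerance = 1e-12)

  # already-equal sums: identity with unit factors
  mat_eq <- rbind(p1 = c(40, 60), p2 = c(60, 40))
  colnames(mat_eq) <- meta$sample_id
  norm_eq <- normalize_sum(abundance_from_matrix(mat_eq))
  expect_equal(norm_factors(norm_eq)$factor, c(1, 1))
  expect_equal(as.matrix(norm_eq[sample_cols_of(norm_eq)]),
               mat_eq, ignore_attr = TRUE)

  # all-missing sample errors
  mat_bad <- rbind(p1 = c(10, NA), p2 = c(20, NA))
  colnames(mat_bad) <- meta$sample_id
  expect_error(normalize_sum(abundance_from_matrix(mat_bad)), "b1")
})

test_that("imputation fills per-sample with factor x the sample minimum", {
  meta <- two_group_metadata(1, 1)
  mat <- rbind(p1 = c(100, 40), p2 = c(500, 80), p3 = c(NA, NA))
  colnames(mat) <- meta$sample_id
  imp <- impute_missing(abundance_from_matrix(mat))
  post <- as.matrix(imp[sample_cols_of(imp)])
  expect_equal(unname(post[3, ]), c(150, 60))  # 1.5 x per-sample minima
  expect_false(anyNA(post))

  mask <- imputed_cells(imp)
  expect_identical(mask$protein_id, c("p3", "p3"))
  expect_setequal(mask$sample_id, c("a1", "b1"))

  # no missing cells: unchanged, empty mask
  complete <- abundance_from_matrix(mat[1:2, ])
  imp2 <- impute_missing(complete)
  expect_equal(as.matrix(imp2[sample_cols_of(imp2)]), mat[1:2, ],
               ignore_attr = TRUE)
  expect_identical(nrow(imputed_cells(imp2)), 0L)

  expect_error(impute_missing(complete, factor = 0), "positive")
})

test_that("log2 view transforms elementwise and rejects non-positive cells", {
  meta <- two_group_metadata(1, 1)
  mat <- rbind(p1 = c(8, 1), p2 = c(2, 1024))
  colnames(mat) <- meta$sample_id
  lg <- log2_view(abundance_from_matrix(mat))
  expect_equal(as.matrix(lg[sample_cols_of(lg)]),
               rbind(p1 = c(3, 0), p2 = c(1, 10)), ignore_attr = TRUE)
  # round trip
  expect_equal(2^as.matrix(lg[sample_cols_of(lg)]), mat,
               ignore_attr = TRUE, tolerance = 1e-12)

  bad_mat <- rbind(p1 = c(0, 5))
  colnames(bad_mat) <- meta$sample_id
  expect_error(log2_view(abundance_from_matrix(bad_mat)), "p1.*a1")
})

test_that("normalize-then-impute preserves within-sample rank order of observed cells", {
  set.seed(11)
  meta <- two_group_metadata(4, 4)
  mat <- matrix(2^rnorm(160, 20, 2), 20, 8,
                dimnames = list(sprintf("p%02d", 1:20), meta$sample_id))
  mat[sample(length(mat), 30)] <- NA
  data <- abundance_from_matrix(mat)
  out <- data |> normalize_sum() |> impute_missing()
  post <- as.matrix(out[sample_cols_of(out)])
  for (s in seq_len(8)) {
    obs <- which(!is.na(mat[, s]))
    expect_identical(order(post[obs, s]), order(mat[obs, s]))
  }
})

test_that("NSAF is length-normalized and sums to one per sample", {
  # single protein: NSAF 1 everywhere
  one <- tibble::tibble(protein_id = "a", s1 = 5L, s2 = 9L)
  expect_equal(unlist(compute_nsaf(one, c(a = 123))[, c("s1", "s2")]),
               c(s1 = 1, s2 = 1))

  # equal counts, equal lengths: symmetric split
  two <- tibble::tibble(protein_id = c("a", "b"), s1 = c(7L, 7L))
  expect_equal(compute_nsaf(two, c(a = 50, b = 50))$s1, c(0.5, 0.5))

  # counts (10, 10) with lengths (100, 200): (2/3, 1/3)
  expect_equal(
    compute_nsaf(tibble::tibble(protein_id = c("a", "b"),
                                s1 = c(10L, 10L)),
                 c(a = 100, b = 200))$s1,
    c(2 / 3, 1 / 3))

  # columns sum to 1; invariant under per-sample count rescaling
  set.seed(2)
  counts <- tibble::tibble(protein_id = sprintf("p%d", 1:30),
                           s1 = rpois(30, 40), s2 = rpois(30, 40))
  lens <- setNames(sample(100:900, 30), counts$protein_id)
  nsaf <- compute_nsaf(counts, lens)
  expect_equal(sum(nsaf$s1), 1, tolerance = 1e-12)
  expect_equal(sum(nsaf$s2), 1, tolerance = 1e-12)
  scaled <- dplyr::mutate(counts, s1 = s1 * 7L)
  expect_equal(compute_nsaf(scaled, lens)$s1, nsaf$s1, tolerance = 1e-12)

  expect_error(compute_nsaf(tibble::tibble(protein_id = "a", s1 = 0L),
                            c(a = 10)), "all-zero")
})
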