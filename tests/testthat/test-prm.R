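test_that("1/x^2-weighted fit equals OLS on the transformed model", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    x <- exp(runif(n, log(0.3), log(300)))
    y <- 0.02 * x + rnorm(n, 0, 0.02 * x * 0.1) + 0.001
    mine <- wls_inverse_x2(x, y)
    ref <- lm(I(y / x) ~ I(1 / x))
    expect_equal(mine$slope, unname(coef(ref)[1]), tolerance = 1e-8)
    expect_equal(mine$intercept, unname(coef(ref)[2]), tolerance = 1e-8)
  }
  expect_error(wls_inverse_x2(c(-1, 2, 3), 1:3), "x > 0")
})

test_that("noiseless series is recovered exactly with all levels accepted", {
  fit <- fit_response_curve(noiseless_series(slope = 0.02))
  expect_true(fit$valid)
  expect_equal(fit$slope, 0.02, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$accepted_levels, default_calibration_levels())
  expect_equal(fit$loq_fmol, 0.41, tolerance = 1e-9)
  expect_true(all(fit$level_qc$accepted))
})

test_that("levels failing precision or accuracy are excluded, LOQ moves up", {
  levels <- c(1, 3, 10, 30, 100, 300, 1000)

  # lowest level with 25% replicate CV -> excluded, valid on remaining 6
  noisy_low <- noiseless_series(slope = 0.05, levels = levels) |>
    dplyr::mutate(ratio = replace(ratio, nominal_fmol == 1,
                                  0.05 * c(0.75, 1.0, 1.25)))
  fit <- fit_response_curve(noisy_low)
  expect_true(fit$valid)
  expect_equal(fit$accepted_levels, levels[-1])
  expect_false(fit$level_qc$accepted[1])
  expect_gt(fit$level_qc$cv_percent[1], 20)

  # lowest level back-calculating to ~130% of nominal -> excluded,
  # LOQ becomes the next accepted level
  biased_low <- noiseless_series(slope = 0.05, levels = levels) |>
    dplyr::mutate(ratio = dplyr::if_else(nominal_fmol == 1, ratio * 1.3, ratio))
  fit2 <- fit_response_curve(biased_low)
  expect_true(fit2$valid)
  expect_equal(fit2$loq_fmol, 3)
  expect_gt(fit2$level_qc$accuracy_percent[1], 120)

  # a failing middle level splits the ladder: the run containing the
  # highest level is kept
  mid_bad <- noiseless_series(slope = 0.05, levels = levels) |>
    dplyr::mutate(ratio = dplyr::if_else(nominal_fmol == 30, ratio * 1.5, ratio))
  fit3 <- fit_response_curve(mid_bad)
  expect_true(fit3$valid)
  expect_equal(fit3$accepted_levels, c(100, 300, 1000))
  expect_equal(fit3$loq_fmol, 100)

  # fewer than 3 consecutive surviving levels -> invalid, not an error
  sparse <- noiseless_series(slope = 0.05, levels = c(1, 3, 10, 30)) |>
    dplyr::mutate(ratio = replace(ratio, nominal_fmol == 10,
                                  0.05 * 10 * c(0.7, 1.0, 1.3)))
  fit4 <- fit_response_curve(sparse)
  expect_false(fit4$valid)
  expect_match(fit4$reason, "consecutive")

  # decreasing response -> invalid with reason
  neg <- noiseless_series(slope = 0.05, levels = levels) |>
    dplyr::mutate(ratio = rev(ratio))
  expect_false(fit_response_curve(neg)$valid)
})

test_that("LOD follows blank mean + 3.3 SD, back-calculated through the curve", {
  fit <- fit_response_curve(noiseless_series(slope = 1))  # identity curve
  expect_equal(compute_lod(fit, c(0.9, 1.0, 1.1)), 1.33, tolerance = 1e-12)
  expect_equal(compute_lod(fit, c(0.5, 0.5, 0.5)), 0.5, tolerance = 1e-12)

  # monotone in blank SD at fixed mean
  lod_narrow <- compute_lod(fit, c(0.95, 1.0, 1.05))
  lod_wide <- compute_lod(fit, c(0.8, 1.0, 1.2))
  expect_gt(lod_wide, lod_narrow)

  # scales through a non-unit slope: ratios 0.02*(0.9, 1.0, 1.1)
  fit2 <- fit_response_curve(noiseless_series(slope = 0.02))
  expect_equal(compute_lod(fit2, 0.02 * c(0.9, 1.0, 1.1)), 1.33,
               tolerance = 1e-9)

  expect_error(compute_lod(fit, 0.9), "blank")
  bad <- fit_response_curve(
    noiseless_series(slope = 0.05) |> dplyr::mutate(ratio = rev(ratio)))
  expect_error(compute_lod(bad, c(0.9, 1.0)), "invalid")
})

test_that("endogenous quantitation round-trips the simulator and censors correctly", {
  # noiseless round trip through simulate -> fit -> quantify
  pc <- prm_sim_config(seed = 21, n_peptides = 4, ratio_cv = 0,
                       blank_mean_fmol = 0.05, blank_sd_fmol = 0)
  cal <- simulate_calibration_set(pc)
  fits <- fit_response_curves(cal$report)
  for (k in seq_len(nrow(fits))) {
    fit <- fits$fit[[k]]
    truth <- cal$truth$slope[cal$truth$peptide_id == fit$peptide_id]
    true_fmol <- c(5, 50, 180)
    res <- quantify_endogenous(fit, truth * true_fmol)
    expect_equal(res$fmol_per_ug, true_fmol, tolerance = 1e-9)
    expect_identical(res$censoring, rep("quantified", 3))
  }

  # censoring bands around an LOD of 1 fmol and LOQ of 2 fmol
  fit <- fit_response_curve(
    noiseless_series(slope = 0.02, levels = c(2, 5, 10, 50, 100)),
    sis_fmol = 50)
  fit$lod_fmol <- 1.0
  res <- quantify_endogenous(
    fit, c(a = 0.02 * 50, b = 0, c = NA, d = 0.02 * 1.5, e = -0.004),
    protein_input_ug = 1)
  expect_equal(res$fmol_per_ug[1], 50, tolerance = 1e-12)
  expect_identical(res$censoring,
                   c("quantified", "below_LOD", "not_detected",
                     "below_LOQ", "below_LOD"))
  # negative back-calculation reports 0
  expect_equal(res$fmol[5], 0)
  # halving the input protein doubles the per-ug concentration
  expect_equal(quantify_endogenous(fit, 0.02 * 50,
                                   protein_input_ug = 0.5)$fmol_per_ug,
               100, tolerance = 1e-12)
  expect_error(quantify_endogenous(fit, 1, sis_spike_fmol = 25), "SIS")
  expect_error(quantify_endogenous(fit, 1, protein_input_ug = 0), "positive")
})

test_that("peptides over the missingness ceiling are dropped, boundary retained", {
  conc <- tidyr::expand_grid(peptide_id = c("p61", "p60", "p0"),
                             sample_id = sprintf("s%03d", 1:100)) |>
    dplyr::mutate(
      fmol_per_ug = 10,
      censoring = dplyr::case_when(
        peptide_id == "p61" & sample_id <= "s061" ~ "not_detected",
        peptide_id == "p60" & sample_id <= "s060" ~ "not_detected",
        .default = "quantified"))
  kept <- filter_prm_matrix(conc)
  expect_setequal(unique(kept$peptide_id), c("p60", "p0"))
})

test_that("PRM differential testing mirrors the LFQ machinery on concentrations", {
  meta <- two_group_metadata(3, 3)
  base <- tidyr::expand_grid(peptide_id = sprintf("pep%02d", 1:12),
                             sample_id = meta$sample_id) |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::mutate(fmol_per_ug = 10, censoring = "quantified")

  # identical concentrations: nothing significant
  none <- prm_differential(dplyr::select(base, -group, -patient_id),
                           meta, "A", "B")
  expect_false(any(none$is_dep))

  # noise-free 4-fold difference in one peptide: log2fc exactly 2
  spiked <- base |>
    dplyr::mutate(fmol_per_ug = dplyr::if_else(
      peptide_id == "pep01" & group == "B", 40, fmol_per_ug)) |>
    dplyr::select(-group, -patient_id)
  res <- prm_differential(spiked, meta, "A", "B")
  expect_equal(res$log2fc[res$peptide_id == "pep01"], 2, tolerance = 1e-12)
  expect_identical(res$peptide_id[res$is_dep], "pep01")
})

test_that("tidy and glance summarize a curve fit", {
  fit <- fit_response_curve(noiseless_series(slope = 0.02), peptide_id = "P")
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], 0.02, tolerance = 1e-12)
  gl <- glance(fit)
  expect_identical(gl$peptide_id, "P")
  expect_true(gl$valid)
  expect_identical(gl$n_accepted, 7L)
})
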