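#' Weighted least squares with 1/x^2 weighting
#'
#' Linear calibration fit `y = intercept + slope * x` with weights
#' `1/x^2`, the standard bioanalytical weighting when the response SD is
#' proportional to the level. Equivalent to ordinary least squares on the
#' transformed model `y/x = intercept * (1/x) + slope`.
#'
#' @param x Positive predictor (nominal fmol).
#' @param y Response (light/heavy ratio).
#' @return List with `slope`, `intercept`, `r_squared` (weighted).
#' @export
wls_inverse_x2 <- function(x, y) {
  if (any(x <= 0)) stop_pq("1/x^2 weighting requires all x > 0")
  if (length(x) < 2) stop_pq("need at least 2 points to fit a line")
  w <- 1 / x^2
  fit <- stats::lm.wfit(cbind(intercept = 1, x = x), y, w)
  coefs <- fit$coefficients
  ybar_w <- sum(w * y) / sum(w)
  sse <- sum(w * fit$residuals^2)
  sst <- sum(w * (y - ybar_w)^2)
  list(slope = unname(coefs["x"]), intercept = unname(coefs["intercept"]),
       r_squared = if (sst > 0) 1 - sse / sst else 1)
}

#' Fit a PRM response curve with calibration-level acceptance
#'
#' Fits the calibration line of one peptide by 1/x^2-weighted least
#' squares on the per-level mean light/heavy ratios, iterating level
#' acceptance to stability: a level is accepted when its replicate CV is
#' below `cv_max` percent and its mean back-calculated concentration
#' falls within `accuracy_range` percent of nominal. Accuracy is judged
#' leave-one-out — each level is back-calculated through the curve fit
#' to the other currently included levels — because under 1/x^2
#' weighting the lowest level dominates the fit, and a fit that includes
#' the level under scrutiny absorbs its bias into the intercept, making
#' a deviating anchor point undetectable. Since accuracy depends on the
#' fit, exclusion and refitting alternate (at most `max_iter` rounds,
#' levels may re-enter); the reported per-level QC is computed against
#' the final fit. The curve is valid only if
#' the stable accepted set contains a run of at least `min_consecutive`
#' consecutive ladder levels; when several disjoint runs qualify, the
#' run containing the highest level is kept (preserving dynamic range
#' toward the top of the ladder), and the reported coefficients are
#' refit on that run. The limit of quantitation is the lowest accepted
#' level.
#'
#' @param data Long tibble for one peptide: columns `sample_type`
#'   (`"calibrant"`/`"blank"`), `nominal_fmol`, `ratio`. Blank rows, if
#'   present, are used for the limit of detection via [compute_lod()].
#' @param peptide_id Optional id recorded in the fit (taken from a
#'   `peptide_id` column if present).
#' @param sis_fmol Constant internal-standard amount the curve was
#'   acquired with (fmol).
#' @param cv_max Per-level precision limit, percent CV (default 20).
#' @param accuracy_range Per-level accuracy window, percent of nominal
#'   (default 80--120).
#' @param min_consecutive Minimum run of consecutive accepted ladder
#'   levels for a valid curve (default 3).
#' @param max_iter Maximum acceptance/refit rounds (default 10).
#' @return An object of class `response_curve_fit`: fields `peptide_id`,
#'   `slope`, `intercept`, `r_squared`, `accepted_levels`, `ladder`,
#'   `level_qc` (tibble `nominal_fmol`, `cv_percent`, `accuracy_percent`,
#'   `accepted`), `lod_fmol` (from blank rows, else `NA`), `loq_fmol`,
#'   `sis_fmol`, `valid`, `reason`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' cal <- tidyr::expand_grid(nominal_fmol = c(1, 3, 10, 30, 100),
#'                           rep = 1:3) |>
#'   dplyr::mutate(sample_type = "calibrant", ratio = 0.02 * nominal_fmol)
#' fit_response_curve(cal, peptide_id = "PEP1")
#' @export
fit_response_curve <- function(data, peptide_id = NULL, sis_fmol = 50,
                               cv_max = 20, accuracy_range = c(80, 120),
                               min_consecutive = 3L, max_iter = 10L) {
  peptide_id <- peptide_id %||%
    (if ("peptide_id" %in% names(data)) data$peptide_id[1] else NA_character_)
  if (!"sample_type" %in% names(data)) data$sample_type <- "calibrant"
  cal <- data[data$sample_type == "calibrant", ]
  blanks <- data$ratio[data$sample_type == "blank"]
  if (anyNA(cal$nominal_fmol)) stop_pq("calibrant rows must carry nominal_fmol")

  by_level <- cal |>
    dplyr::summarise(mean_ratio = mean(.data$ratio),
                     sd_ratio = sd(.data$ratio),
                     n = dplyr::n(),
                     .by = "nominal_fmol") |>
    dplyr::arrange(.data$nominal_fmol)
  if (nrow(by_level) < min_consecutive)
    stop_pq("need at least %d calibration levels, got %d",
            min_consecutive, nrow(by_level))
  if (any(by_level$n < 2))
    stop_pq("every calibration level needs >= 2 replicates")
  ladder <- by_level$nominal_fmol

  invalid <- function(reason, qc = NULL) {
    structure(list(peptide_id = peptide_id, slope = NA_real_,
                   intercept = NA_real_, r_squared = NA_real_,
                   accepted_levels = numeric(0), ladder = ladder,
                   level_qc = qc, lod_fmol = NA_real_, loq_fmol = NA_real_,
                   sis_fmol = sis_fmol, valid = FALSE, reason = reason),
              class = "response_curve_fit")
  }

  cv_percent <- 100 * by_level$sd_ratio / by_level$mean_ratio
  back_calc <- function(coefs, i) {
    100 * ((by_level$mean_ratio[i] - coefs$intercept) / coefs$slope) /
      ladder[i]
  }
  # leave-one-out accuracy: level i judged against the fit to the other
  # included levels (for excluded i, against the full included fit)
  loo_accuracy <- function(included) {
    vapply(seq_along(ladder), function(i) {
      idx <- included
      idx[i] <- FALSE
      if (sum(idx) < 2) idx <- included
      if (sum(idx) < 2) return(NA_real_)
      cf <- wls_inverse_x2(ladder[idx], by_level$mean_ratio[idx])
      if (is.na(cf$slope) || cf$slope <= 0) return(NA_real_)
      back_calc(cf, i)
    }, numeric(1))
  }
  qc_table <- function(accuracy) {
    tibble::tibble(nominal_fmol = ladder, cv_percent = cv_percent,
                   accuracy_percent = accuracy) |>
      dplyr::mutate(accepted = dplyr::coalesce(
        .data$cv_percent < cv_max &
          .data$accuracy_percent >= accuracy_range[1] &
          .data$accuracy_percent <= accuracy_range[2], FALSE))
  }

  included <- rep(TRUE, nrow(by_level))
  qc <- NULL
  for (iter in seq_len(max_iter)) {
    if (sum(included) < 2) return(invalid("fewer than 2 usable levels", qc))
    coefs <- wls_inverse_x2(ladder[included], by_level$mean_ratio[included])
    if (is.na(coefs$slope) || coefs$slope <= 0)
      return(invalid("non-positive slope", qc))
    qc <- qc_table(loo_accuracy(included))
    if (identical(qc$accepted, included)) break
    included <- qc$accepted
  }

  runs <- consecutive_runs(which(included))
  runs <- runs[lengths(runs) >= min_consecutive]
  if (length(runs) == 0)
    return(invalid(sprintf("no run of >= %d consecutive accepted levels",
                           min_consecutive), qc))
  run <- runs[[length(runs)]]  # the run containing the highest level
  accepted <- ladder[run]

  final <- wls_inverse_x2(accepted, by_level$mean_ratio[run])
  if (final$slope <= 0) return(invalid("non-positive slope", qc))
  qc <- qc_table(vapply(seq_along(ladder), function(i) back_calc(final, i),
                        numeric(1)))

  fit <- structure(
    list(peptide_id = peptide_id, slope = final$slope,
         intercept = final$intercept, r_squared = final$r_squared,
         accepted_levels = accepted, ladder = ladder, level_qc = qc,
         lod_fmol = NA_real_, loq_fmol = min(accepted),
         sis_fmol = sis_fmol, valid = TRUE, reason = "ok"),
    class = "response_curve_fit")
  if (length(blanks) >= 2) fit$lod_fmol <- compute_lod(fit, blanks)
  fit
}

# Split a sorted integer vector into maximal runs of consecutive values.
consecutive_runs <- function(idx) {
  if (length(idx) == 0) return(list())
  unname(split(idx, cumsum(c(1, diff(idx) != 1))))
}

#' @export
print.response_curve_fit <- function(x, ...) {
  cat(sprintf("<response_curve_fit> %s: %s\n", x$peptide_id,
              if (x$valid) "valid" else paste("invalid -", x$reason)))
  if (x$valid)
    cat(sprintf("  slope %.5g, intercept %.5g, r^2 %.5f\n  %d/%d levels accepted, LOQ %.3g fmol, LOD %.3g fmol\n",
                x$slope, x$intercept, x$r_squared,
                length(x$accepted_levels), length(x$ladder),
                x$loq_fmol, x$lod_fmol))
  invisible(x)
}

#' Limit of detection from double-blank replicates
#'
#' Each blank light/heavy ratio is back-calculated to a concentration
#' through the fitted curve; the LOD is the blank mean plus 3.3 times
#' the blank SD (sample SD, n-1 denominator), floored at zero.
#'
#' @param fit A valid [fit_response_curve()] result.
#' @param blank_ratios Numeric vector of at least 2 blank ratios.
#' @return LOD in fmol.
#' @examples
#' # blanks back-calculating to 0.9, 1.0, 1.1 fmol give LOD 1.33 fmol
#' @export
compute_lod <- function(fit, blank_ratios) {
  stopifnot(inherits(fit, "response_curve_fit"))
  if (!fit$valid) stop_pq("cannot compute LOD from an invalid fit (%s)", fit$reason)
  if (length(blank_ratios) < 2) stop_pq("need >= 2 blank replicates")
  conc <- (blank_ratios - fit$intercept) / fit$slope
  max(0, mean(conc) + 3.3 * sd(conc))
}

#' Absolute quantitation of endogenous peptide from an observed ratio
#'
#' Back-calculates `fmol = (ratio - intercept) / slope` through a valid
#' response curve and normalizes to the protein input, giving fmol per
#' microgram of digested protein. Censoring levels: `not_detected`
#' (missing ratio), `below_LOD` (back-calculated amount under the limit
#' of detection; negative amounts report 0), `below_LOQ` (between LOD
#' and the lowest accepted calibration level), else `quantified`.
#'
#' @param fit A valid [fit_response_curve()] with `lod_fmol` set (fit
#'   with blank rows, or [compute_lod()] first).
#' @param observed_ratio Numeric vector of light/heavy ratios (`NA` =
#'   not detected). Names, if any, become `sample_id`.
#' @param protein_input_ug Micrograms of digested protein per injection.
#' @param sis_spike_fmol SIS amount spiked into the unknowns; must equal
#'   the curve's `sis_fmol` (curves are specific to their internal
#'   standard level).
#' @return Tibble: `peptide_id`, `sample_id`, `fmol`, `fmol_per_ug`,
#'   `censoring`.
#' @export
quantify_endogenous <- function(fit, observed_ratio, protein_input_ug = 1,
                                sis_spike_fmol = fit$sis_fmol) {
  stopifnot(inherits(fit, "response_curve_fit"))
  if (!fit$valid) stop_pq("cannot quantify with an invalid fit (%s)", fit$reason)
  if (protein_input_ug <= 0) stop_pq("protein_input_ug must be positive")
  if (!isTRUE(all.equal(sis_spike_fmol, fit$sis_fmol)))
    stop_pq("SIS spike (%g fmol) differs from the curve's (%g fmol)",
            sis_spike_fmol, fit$sis_fmol)
  if (fit$slope == 0) stop_pq("zero slope")
  if (is.na(fit$lod_fmol))
    stop_pq("fit has no LOD; supply blank ratios or run compute_lod()")
  if (fit$lod_fmol > fit$loq_fmol)
    warn(sprintf("%s: LOD (%.3g fmol) exceeds LOQ (%.3g fmol)",
                 fit$peptide_id, fit$lod_fmol, fit$loq_fmol))

  fmol <- unname((observed_ratio - fit$intercept) / fit$slope)
  censoring <- dplyr::case_when(
    is.na(observed_ratio) ~ "not_detected",
    fmol < fit$lod_fmol ~ "below_LOD",
    fmol < fit$loq_fmol ~ "below_LOQ",
    .default = "quantified")
  fmol <- ifelse(!is.na(fmol) & fmol < 0, 0, fmol)
  ids <- names(observed_ratio) %||%
    sprintf("sample_%02d", seq_along(observed_ratio))
  tibble::tibble(peptide_id = fit$peptide_id, sample_id = ids,
                 fmol = fmol, fmol_per_ug = fmol / protein_input_ug,
                 censoring = censoring)
}

#' Drop peptides with excessive missingness across samples
#'
#' Removes peptides whose fraction of `not_detected` cells across
#' samples is strictly greater than `max_missing_frac` (a peptide
#' missing in exactly that fraction is retained).
#'
#' @param conc Long concentration tibble (`peptide_id`, `sample_id`,
#'   `fmol_per_ug`, `censoring`), as stacked [quantify_endogenous()]
#'   output.
#' @param max_missing_frac Maximum tolerated missing fraction,
#'   in (0, 1] (default 0.6).
#' @return The filtered tibble.
#' @export
filter_prm_matrix <- function(conc, max_missing_frac = 0.6) {
  if (max_missing_frac <= 0 || max_missing_frac > 1)
    stop_pq("max_missing_frac must be in (0, 1]")
  conc |>
    dplyr::mutate(
      .missing_frac = mean(.data$censoring == "not_detected"),
      .by = "peptide_id") |>
    dplyr::filter(.data$.missing_frac <= max_missing_frac) |>
    dplyr::select(-".missing_frac")
}

#' Differential abundance of PRM concentrations
#'
#' Runs the label-free differential-expression machinery on
#' `log2(fmol_per_ug)`: cells censored as `not_detected` or `below_LOD`
#' are treated as missing and imputed by the per-sample minimum rule
#' before testing; concentrations being absolute, no loading
#' normalization is applied.
#'
#' @param conc Long concentration tibble as in [filter_prm_matrix()].
#' @param metadata Sample metadata with `sample_id` and `group`.
#' @inheritParams run_comparison
#' @param impute_factor Multiplier of the per-sample minimum used for
#'   censored cells.
#' @return Differential records as from [run_comparison()], with
#'   `peptide_id` in place of `protein_id`.
#' @export
prm_differential <- function(conc, metadata, group_a, group_b,
                             q_threshold = 0.01, log2fc_threshold = 1,
                             fdr_level = 0.01, impute_factor = 1.5) {
  wide <- conc |>
    dplyr::mutate(value = ifelse(
      .data$censoring %in% c("not_detected", "below_LOD"),
      NA_real_, .data$fmol_per_ug)) |>
    dplyr::select("peptide_id", "sample_id", "value") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value") |>
    dplyr::rename(protein_id = "peptide_id")
  if (nrow(wide) == 0) stop_pq("no peptides to test")
  res <- wide |>
    impute_missing(factor = impute_factor) |>
    log2_view() |>
    run_comparison(metadata, group_a, group_b,
                   q_threshold = q_threshold,
                   log2fc_threshold = log2fc_threshold,
                   fdr_level = fdr_level)
  dplyr::rename(res, peptide_id = "protein_id")
}

#' Fit response curves for every peptide of a long PRM report
#'
#' @param report Long PRM tibble (`peptide_id`, `sample_type`,
#'   `nominal_fmol`, `ratio`), e.g. from [read_prm_report_csv()] or
#'   [simulate_calibration_set()].
#' @inheritParams fit_response_curve
#' @return Tibble with one row per peptide: `peptide_id`, `slope`,
#'   `intercept`, `r_squared`, `n_accepted`, `loq_fmol`, `lod_fmol`,
#'   `valid`, `reason`, plus list-columns `fit` (the
#'   `response_curve_fit` objects) and `level_qc`.
#' @export
fit_response_curves <- function(report, sis_fmol = 50, cv_max = 20,
                                accuracy_range = c(80, 120),
                                min_consecutive = 3L, max_iter = 10L) {
  report |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::group_map(function(d, key) {
      fit <- fit_response_curve(d, peptide_id = key$peptide_id,
                                sis_fmol = sis_fmol, cv_max = cv_max,
                                accuracy_range = accuracy_range,
                                min_consecutive = min_consecutive,
                                max_iter = max_iter)
      dplyr::mutate(glance.response_curve_fit(fit),
                    fit = list(fit), level_qc = list(fit$level_qc))
    }) |>
    purrr::list_rbind()
}
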