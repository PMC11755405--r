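#' Configuration for the LFQ cohort simulator
#'
#' Defines the statistical structure of a simulated label-free cohort:
#' log-normal protein abundances, a fixed group effect on a designated set
#' of differential proteins, per-sample loading offsets, and
#' intensity-dependent (missing-not-at-random) dropout.
#'
#' Defaults emulate the FFPE breast-lesion cohort the pipeline was built
#' for: 29 pure-DCIS and 18 pure-IDC cases and on the order of 2,800
#' quantified proteins. The distributional parameters (between-protein
#' spread, within-group noise, dropout curve) are stand-ins with no
#' empirical counterpart in that study; see the methods vignette.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param group_sizes Named integer vector, group label -> number of
#'   samples (each >= 2). The group effect of differential proteins is
#'   applied to the *second* group, so positive `true_log2fc` means
#'   higher abundance in the second group.
#' @param n_proteins Number of proteins (> 0).
#' @param n_true_deps Number of truly differential proteins (>= 0,
#'   <= `n_proteins`).
#' @param true_log2fc Group effect in log2 units applied to differential
#'   proteins.
#' @param baseline_log2_mean Grand mean of latent log2 intensity.
#' @param between_protein_sd SD of per-protein abundance offsets (log2).
#' @param within_group_sd SD of residual within-group noise (log2).
#' @param loading_sd SD of the per-sample systematic loading offset (log2).
#' @param dropout_midpoint Latent log2 intensity at which a cell is
#'   missing with probability 0.5. `-Inf` disables dropout.
#' @param dropout_steepness Slope of the logistic dropout curve (> 0).
#' @return A validated `lfq_sim_config` list.
#' @examples
#' cfg <- lfq_sim_config(seed = 1, group_sizes = c(A = 3, B = 3),
#'                       n_proteins = 50, n_true_deps = 5)
#' @export
lfq_sim_config <- function(seed = 1L,
                           group_sizes = c(pure_DCIS = 29L, pure_IDC = 18L),
                           n_proteins = 2800L,
                           n_true_deps = 100L,
                           true_log2fc = 2,
                           baseline_log2_mean = 20,
                           between_protein_sd = 2,
                           within_group_sd = 0.5,
                           loading_sd = 0.2,
                           dropout_midpoint = -Inf,
                           dropout_steepness = 1) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop_pq("group_sizes must be a named vector of group labels")
  if (any(group_sizes < 2))
    stop_pq("every group needs at least 2 samples (got: %s)",
            paste(group_sizes, collapse = ", "))
  if (n_proteins <= 0) stop_pq("n_proteins must be positive")
  if (n_true_deps < 0 || n_true_deps > n_proteins)
    stop_pq("n_true_deps must lie in [0, n_proteins]")
  if (between_protein_sd < 0 || within_group_sd < 0 || loading_sd < 0)
    stop_pq("standard deviations must be non-negative")
  if (dropout_steepness <= 0) stop_pq("dropout_steepness must be positive")
  structure(
    list(seed = as.integer(seed),
         group_sizes = setNames(as.integer(group_sizes), names(group_sizes)),
         n_proteins = as.integer(n_proteins),
         n_true_deps = as.integer(n_true_deps),
         true_log2fc = true_log2fc,
         baseline_log2_mean = baseline_log2_mean,
         between_protein_sd = between_protein_sd,
         within_group_sd = within_group_sd,
         loading_sd = loading_sd,
         dropout_midpoint = dropout_midpoint,
         dropout_steepness = dropout_steepness),
    class = "lfq_sim_config")
}

#' Simulate a label-free quantitation cohort
#'
#' Draws a proteins-by-samples intensity table with the structure the
#' downstream analysis assumes. The latent log2 intensity of protein i in
#' sample s is
#' \deqn{baseline + b_i + \delta_i \, [s \in g_2] + l_s + \epsilon_{is}}
#' with protein offset \eqn{b_i}, group effect \eqn{\delta_i} (non-zero
#' only for the designated differential proteins and only in the second
#' group), sample loading offset \eqn{l_s}, and within-group noise
#' \eqn{\epsilon_{is}}. A cell is observed with probability
#' \eqn{1 - \mathrm{logit}^{-1}(k\,(m - x))} where x is the latent log2
#' intensity, m the dropout midpoint and k the steepness — lower
#' intensity means higher dropout. Observed linear intensity is
#' \eqn{2^x}.
#'
#' @param config An [lfq_sim_config()].
#' @return A list with components:
#'   * `abundance` — wide tibble: `protein_id`, `unique_peptides`,
#'     `length_aa`, `description`, then one linear-intensity column per
#'     sample (`NA` = missing).
#'   * `metadata` — tibble: `sample_id`, `patient_id`, `group`.
#'   * `truth` — list: `dep_protein_ids`, `true_log2fc` (named vector,
#'     non-zero only for differential proteins), `effect_group` (label of
#'     the group carrying the effect), `latent_log2` (matrix of latent
#'     log2 intensities before dropout).
#' @examples
#' sim <- simulate_lfq_dataset(lfq_sim_config(
#'   seed = 7, group_sizes = c(A = 3, B = 3), n_proteins = 20,
#'   n_true_deps = 2))
#' dim(sim$abundance)
#' @export
simulate_lfq_dataset <- function(config) {
  stopifnot(inherits(config, "lfq_sim_config"))
  set.seed(derive_seed(config$seed, "lfq"))

  groups <- names(config$group_sizes)
  n_samp <- sum(config$group_sizes)
  sample_group <- rep(groups, times = config$group_sizes)
  sample_ids <- sprintf("S%02d_%s", seq_len(n_samp), sample_group)
  patient_ids <- sprintf("P%03d", seq_len(n_samp))

  np <- config$n_proteins
  protein_ids <- sprintf("PROT%04d", seq_len(np))
  dep_ids <- head(protein_ids, config$n_true_deps)
  effect <- setNames(rep(0, np), protein_ids)
  effect[dep_ids] <- config$true_log2fc
  effect_group <- if (length(groups) >= 2) groups[2] else groups[1]

  protein_off <- rnorm(np, 0, config$between_protein_sd)
  loading <- rnorm(n_samp, 0, config$loading_sd)
  in_effect <- as.numeric(sample_group == effect_group)

  latent <- config$baseline_log2_mean + protein_off +
    outer(effect, in_effect) +
    matrix(loading, np, n_samp, byrow = TRUE) +
    matrix(rnorm(np * n_samp, 0, config$within_group_sd), np, n_samp)
  dimnames(latent) <- list(protein_ids, sample_ids)

  p_missing <- plogis(config$dropout_steepness *
                        (config$dropout_midpoint - latent))
  observed <- matrix(runif(np * n_samp), np, n_samp) >= p_missing
  intensity <- 2^latent
  intensity[!observed] <- NA_real_

  abundance <- dplyr::bind_cols(
    tibble::tibble(
      protein_id = protein_ids,
      unique_peptides = 1L + rpois(np, 4),
      length_aa = as.integer(round(exp(rnorm(np, log(450), 0.4)))),
      description = sprintf("Simulated protein %s", protein_ids)),
    tibble::as_tibble(intensity))

  metadata <- tibble::tibble(sample_id = sample_ids,
                             patient_id = patient_ids,
                             group = sample_group)

  list(abundance = abundance,
       metadata = metadata,
       truth = list(dep_protein_ids = dep_ids,
                    true_log2fc = effect,
                    effect_group = effect_group,
                    latent_log2 = latent))
}

#' Simulate a spectral-count table matched to an LFQ configuration
#'
#' Counts are Poisson with expectation proportional to the latent linear
#' abundance times the protein length, scaled so the expected per-sample
#' total equals `mean_depth`. Feeds NSAF computation ([compute_nsaf()]).
#'
#' @param config An [lfq_sim_config()].
#' @param lengths Named numeric vector protein_id -> amino-acid length
#'   (all positive); must cover every simulated protein.
#' @param mean_depth Expected total spectral counts per sample.
#' @return A list with `counts` (wide tibble: `protein_id` then one
#'   integer column per sample) and `metadata` (as in
#'   [simulate_lfq_dataset()]).
#' @export
simulate_spectral_counts <- function(config, lengths, mean_depth = 1e5) {
  stopifnot(inherits(config, "lfq_sim_config"))
  if (any(lengths <= 0)) stop_pq("all protein lengths must be positive")
  sim <- simulate_lfq_dataset(config)
  protein_ids <- sim$abundance$protein_id
  missing_len <- setdiff(protein_ids, names(lengths))
  if (length(missing_len) > 0)
    stop_pq("missing length for protein(s): %s",
            paste(head(missing_len, 5), collapse = ", "))
  set.seed(derive_seed(config$seed, "counts"))
  linear <- 2^sim$truth$latent_log2
  lam_raw <- linear * lengths[protein_ids]
  # scale each sample so expected total counts = mean_depth
  lam <- sweep(lam_raw, 2, colSums(lam_raw) / mean_depth, "/")
  counts <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam),
                   dimnames = dimnames(lam))
  list(counts = dplyr::bind_cols(tibble::tibble(protein_id = protein_ids),
                                 tibble::as_tibble(counts)),
       metadata = sim$metadata)
}

#' Configuration for the PRM calibration simulator
#'
#' @param seed Integer master seed.
#' @param n_peptides Number of peptides (> 0).
#' @param level_fmol Strictly increasing positive calibrant amounts
#'   (fmol of light peptide). Default: seven-point geometric ladder from
#'   0.41 to 250 fmol against a constant internal standard.
#' @param replicates_per_level Replicates per calibration level (>= 2).
#' @param sis_fmol Constant heavy (SIS) spike per injection (fmol).
#' @param slope_range Length-2 positive interval; each peptide's true
#'   response slope (ratio per fmol) is drawn uniformly from it.
#' @param ratio_cv Proportional noise on observed ratios (SD/mean); the
#'   replicate SD grows with the level, which is what motivates 1/x^2
#'   weighting in the fit.
#' @param blank_mean_fmol Mean apparent concentration of double-blank
#'   injections (fmol).
#' @param blank_sd_fmol SD of the blank apparent concentration (fmol).
#' @param n_blanks Number of double-blank replicates (>= 2).
#' @return A validated `prm_sim_config` list.
#' @export
prm_sim_config <- function(seed = 1L,
                           n_peptides = 10L,
                           level_fmol = default_calibration_levels(),
                           replicates_per_level = 3L,
                           sis_fmol = 50,
                           slope_range = c(0.005, 0.05),
                           ratio_cv = 0.05,
                           blank_mean_fmol = 0.2,
                           blank_sd_fmol = 0.05,
                           n_blanks = 3L) {
  if (n_peptides <= 0) stop_pq("n_peptides must be positive")
  if (any(diff(level_fmol) <= 0) || min(level_fmol) <= 0)
    stop_pq("level_fmol must be strictly increasing and positive")
  if (replicates_per_level < 2) stop_pq("need >= 2 replicates per level")
  if (sis_fmol <= 0) stop_pq("sis_fmol must be positive")
  if (length(slope_range) != 2 || any(slope_range <= 0) ||
      slope_range[1] > slope_range[2])
    stop_pq("slope_range must be a positive interval")
  if (ratio_cv < 0) stop_pq("ratio_cv must be non-negative")
  if (blank_mean_fmol < 0 || blank_sd_fmol < 0)
    stop_pq("blank parameters must be non-negative")
  if (n_blanks < 2) stop_pq("need >= 2 blank replicates")
  structure(
    list(seed = as.integer(seed), n_peptides = as.integer(n_peptides),
         level_fmol = as.numeric(level_fmol),
         replicates_per_level = as.integer(replicates_per_level),
         sis_fmol = sis_fmol, slope_range = slope_range,
         ratio_cv = ratio_cv, blank_mean_fmol = blank_mean_fmol,
         blank_sd_fmol = blank_sd_fmol, n_blanks = as.integer(n_blanks)),
    class = "prm_sim_config")
}

#' Default seven-point calibration ladder
#'
#' Geometric series from 0.41 to 250 fmol (three orders of magnitude),
#' seven points.
#'
#' @return Numeric vector of length 7.
#' @export
default_calibration_levels <- function() {
  exp(seq(log(0.41), log(250), length.out = 7))
}

#' Simulate PRM calibration series
#'
#' For each peptide the true response ratio at calibrant amount x is
#' `slope * x + intercept` (intercept 0 here). Observed replicate ratios
#' are `true * (1 + eps)` with `eps ~ Normal(0, ratio_cv)`, so the
#' replicate SD is proportional to the level. Blank injections draw an
#' apparent concentration from `Normal(blank_mean_fmol, blank_sd_fmol)`
#' and map it through the true curve; negative draws clamp to ratio 0.
#'
#' @param config A [prm_sim_config()].
#' @return A list with:
#'   * `report` — long tibble in the PRM report layout: `peptide_id`,
#'     `sample_id`, `sample_type` (`"blank"`/`"calibrant"`),
#'     `nominal_fmol` (`NA` for blanks), `light_area`, `heavy_area`,
#'     `ratio`.
#'   * `truth` — tibble: `peptide_id`, `slope`, `intercept`.
#' @export
simulate_calibration_set <- function(config) {
  stopifnot(inherits(config, "prm_sim_config"))
  set.seed(derive_seed(config$seed, "prm"))
  peptides <- sprintf("PEP%03d", seq_len(config$n_peptides))
  slopes <- runif(config$n_peptides, config$slope_range[1],
                  config$slope_range[2])
  heavy_area <- 1e6  # arbitrary constant SIS response

  one_peptide <- function(pid, slope) {
    cal <- tidyr::expand_grid(
      nominal_fmol = config$level_fmol,
      replicate = seq_len(config$replicates_per_level))
    true_ratio <- slope * cal$nominal_fmol
    obs <- true_ratio * (1 + rnorm(nrow(cal), 0, config$ratio_cv))
    obs <- pmax(obs, 0)
    blank_conc <- rnorm(config$n_blanks, config$blank_mean_fmol,
                        config$blank_sd_fmol)
    blank_ratio <- pmax(slope * blank_conc, 0)
    dplyr::bind_rows(
      tibble::tibble(
        peptide_id = pid,
        sample_id = sprintf("cal_%g_r%d", cal$nominal_fmol, cal$replicate),
        sample_type = "calibrant",
        nominal_fmol = cal$nominal_fmol,
        ratio = obs),
      tibble::tibble(
        peptide_id = pid,
        sample_id = sprintf("blank_r%d", seq_len(config$n_blanks)),
        sample_type = "blank",
        nominal_fmol = NA_real_,
        ratio = blank_ratio))
  }

  report <- purrr::map2(peptides, slopes, one_peptide) |>
    purrr::list_rbind() |>
    dplyr::mutate(heavy_area = heavy_area,
                  light_area = .data$ratio * heavy_area,
                  .before = "ratio")

  list(report = report,
       truth = tibble::tibble(peptide_id = peptides, slope = slopes,
                              intercept = 0))
}
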