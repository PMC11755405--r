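#' Filter proteins by unique-peptide evidence and detection coverage
#'
#' Keeps a protein only if it was identified with at least
#' `min_unique_peptides` protein-unique peptides and quantified (observed
#' with a positive intensity) in at least `min_frac` of the samples of at
#' least one of the stated study groups. Row order is preserved and the
#' filter is idempotent.
#'
#' @param data Wide abundance tibble: `protein_id`, optional metadata
#'   columns (`unique_peptides`, `length_aa`, `description`), then one
#'   linear-intensity column per sample (`NA` = missing).
#' @param metadata Sample metadata tibble with `sample_id` and `group`;
#'   every sample column of `data` must appear exactly once.
#' @param groups Group labels over which coverage is assessed (each must
#'   have at least one sample). Defaults to all groups present among the
#'   samples of `data`.
#' @param min_frac Minimum detected fraction within a group, in (0, 1].
#' @param min_unique_peptides Minimum unique-peptide count.
#' @return The filtered tibble (same columns).
#' @examples
#' sim <- simulate_lfq_dataset(lfq_sim_config(
#'   seed = 1, group_sizes = c(A = 3, B = 3), n_proteins = 10,
#'   n_true_deps = 0, dropout_midpoint = 18))
#' filter_by_detection(sim$abundance, sim$metadata)
#' @export
filter_by_detection <- function(data, metadata, groups = NULL,
                                min_frac = 0.6, min_unique_peptides = 1L) {
  if (min_frac <= 0 || min_frac > 1) stop_pq("min_frac must be in (0, 1]")
  check_metadata(data, metadata)
  samples <- sample_cols(data)
  grp <- setNames(metadata$group, metadata$sample_id)[samples]
  groups <- groups %||% unique(grp)
  empty <- setdiff(groups, grp)
  if (length(empty) > 0)
    stop_pq("group(s) with zero samples: %s", paste(empty, collapse = ", "))

  mat <- as.matrix(data[samples])
  detected <- !is.na(mat) & mat > 0
  covered <- rep(FALSE, nrow(data))
  for (g in groups) {
    cols <- samples[grp == g]
    covered <- covered |
      rowMeans(detected[, cols, drop = FALSE]) >= min_frac
  }
  enough_peptides <- if ("unique_peptides" %in% names(data)) {
    data$unique_peptides >= min_unique_peptides
  } else {
    rep(TRUE, nrow(data))
  }
  data[covered & enough_peptides, , drop = FALSE]
}

#' Normalize by summed protein intensities
#'
#' Corrects for differences in sample loading: each sample's observed
#' intensities are scaled by `median(per-sample sums) / (sum of sample)`,
#' so every per-sample sum over observed cells equals the cohort median
#' afterwards. Within-sample intensity ratios are unchanged. Sums are
#' taken over observed (non-missing) cells only.
#'
#' @param data Wide abundance tibble (see [filter_by_detection()]).
#' @return The normalized tibble, with attribute `norm_factors`
#'   (tibble `sample_id`, `raw_sum`, `factor`) retrievable via
#'   [norm_factors()].
#' @export
normalize_sum <- function(data) {
  samples <- sample_cols(data)
  mat <- as.matrix(data[samples])
  sums <- colSums(mat, na.rm = TRUE)
  if (any(sums <= 0) || any(colSums(!is.na(mat)) == 0))
    stop_pq("sample(s) with no observed intensity: %s",
            paste(samples[sums <= 0 | colSums(!is.na(mat)) == 0],
                  collapse = ", "))
  factors <- median(sums) / sums
  data[samples] <- tibble::as_tibble(sweep(mat, 2, factors, "*"))
  attr(data, "norm_factors") <- tibble::tibble(
    sample_id = samples, raw_sum = unname(sums), factor = unname(factors))
  data
}

#' Per-sample normalization factors of a normalized table
#'
#' @param data A tibble returned by [normalize_sum()].
#' @return Tibble with `sample_id`, `raw_sum`, `factor`.
#' @export
norm_factors <- function(data) {
  f <- attr(data, "norm_factors")
  if (is.null(f)) stop_pq("data carries no normalization factors; run normalize_sum() first")
  f
}

#' Impute missing intensities with a multiple of the per-sample minimum
#'
#' Every missing cell in a sample is set to `factor` times the minimum
#' observed intensity of that sample (the published rule uses 1.5x, which
#' places imputed values *above* the observed floor; see the methods
#' vignette for discussion). Imputation is per sample, never global.
#'
#' @param data Wide abundance tibble, typically after [normalize_sum()].
#' @param factor Positive multiplier of the per-sample minimum.
#' @return The completed tibble (no missing cells), with attribute
#'   `imputed_cells` (long tibble `protein_id`, `sample_id`, `value`)
#'   retrievable via [imputed_cells()]. Normalization factors, if
#'   present, are carried through.
#' @export
impute_missing <- function(data, factor = 1.5) {
  if (factor <= 0) stop_pq("imputation factor must be positive")
  samples <- sample_cols(data)
  mat <- as.matrix(data[samples])
  if (any(colSums(!is.na(mat)) == 0))
    stop_pq("sample(s) with all-missing column cannot be imputed")
  mins <- apply(mat, 2, min, na.rm = TRUE)
  miss <- which(is.na(mat), arr.ind = TRUE)
  fill <- factor * mins[miss[, "col"]]
  mat[miss] <- fill
  out <- data
  out[samples] <- tibble::as_tibble(mat)
  attr(out, "norm_factors") <- attr(data, "norm_factors")
  attr(out, "imputed_cells") <- tibble::tibble(
    protein_id = data$protein_id[miss[, "row"]],
    sample_id = samples[miss[, "col"]],
    value = unname(fill))
  out
}

#' Cells filled by imputation
#'
#' @param data A tibble returned by [impute_missing()].
#' @return Long tibble `protein_id`, `sample_id`, `value`.
#' @export
imputed_cells <- function(data) {
  m <- attr(data, "imputed_cells")
  if (is.null(m)) stop_pq("data carries no imputation record; run impute_missing() first")
  m
}

#' Log2 view of a completed abundance table
#'
#' @param data Wide abundance tibble with no missing and no non-positive
#'   intensities (run [impute_missing()] first).
#' @return The tibble with every sample column log2-transformed.
#' @export
log2_view <- function(data) {
  samples <- sample_cols(data)
  mat <- as.matrix(data[samples])
  bad <- which(is.na(mat) | mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_pq("non-positive or missing intensity at protein %s, sample %s",
            data$protein_id[bad[1, "row"]], samples[bad[1, "col"]])
  data[samples] <- tibble::as_tibble(log2(mat))
  data
}

#' Run the full LFQ preprocessing chain
#'
#' Convenience wrapper applying, in order: detection filter, summed-
#' intensity normalization, per-sample minimum imputation, log2
#' transform. The order is fixed: normalization factors are computed from
#' observed cells only, so imputed values never influence loading
#' correction.
#'
#' @inheritParams filter_by_detection
#' @param impute_factor Multiplier for [impute_missing()].
#' @return Log2-scale tibble carrying the `norm_factors` and
#'   `imputed_cells` attributes.
#' @export
preprocess_lfq <- function(data, metadata, groups = NULL, min_frac = 0.6,
                           min_unique_peptides = 1L, impute_factor = 1.5) {
  out <- data |>
    filter_by_detection(metadata, groups, min_frac, min_unique_peptides) |>
    normalize_sum() |>
    impute_missing(factor = impute_factor)
  res <- log2_view(out)
  attr(res, "norm_factors") <- attr(out, "norm_factors")
  attr(res, "imputed_cells") <- attr(out, "imputed_cells")
  res
}

#' Normalized spectral abundance factors (NSAF)
#'
#' For protein i in sample s, `NSAF = (count/length) / sum_j(count_j/length_j)`,
#' so each sample column sums to 1. NSAF is invariant to rescaling all
#' counts of a sample by a constant.
#'
#' @param counts Wide tibble: `protein_id` then one non-negative integer
#'   column per sample.
#' @param lengths Named vector protein_id -> amino-acid length (all
#'   positive), or `NULL` to use a `length_aa` column of `counts`.
#' @return Tibble `protein_id` plus one NSAF column per sample.
#' @examples
#' counts <- tibble::tibble(protein_id = c("a", "b"),
#'                          s1 = c(10L, 10L), s2 = c(4L, 2L))
#' compute_nsaf(counts, c(a = 100, b = 200))
#' @export
compute_nsaf <- function(counts, lengths = NULL) {
  if (is.null(lengths)) {
    if (!"length_aa" %in% names(counts))
      stop_pq("lengths not given and counts has no length_aa column")
    lengths <- setNames(counts$length_aa, counts$protein_id)
  }
  missing_len <- setdiff(counts$protein_id, names(lengths))
  if (length(missing_len) > 0)
    stop_pq("missing length for protein(s): %s",
            paste(head(missing_len, 5), collapse = ", "))
  len <- lengths[counts$protein_id]
  if (any(len <= 0)) stop_pq("all protein lengths must be positive")
  samples <- sample_cols(counts)
  mat <- as.matrix(counts[samples])
  saf <- mat / len
  tot <- colSums(saf)
  if (any(tot <= 0))
    stop_pq("all-zero counts in sample(s): %s",
            paste(samples[tot <= 0], collapse = ", "))
  out <- tibble::tibble(protein_id = counts$protein_id)
  dplyr::bind_cols(out, tibble::as_tibble(sweep(saf, 2, tot, "/")))
}

check_metadata <- function(data, metadata) {
  samples <- sample_cols(data)
  if (anyDuplicated(metadata$sample_id))
    stop_pq("duplicate sample_id in metadata")
  missing_meta <- setdiff(samples, metadata$sample_id)
  if (length(missing_meta) > 0)
    stop_pq("sample(s) without metadata: %s",
            paste(missing_meta, collapse = ", "))
  invisible(TRUE)
}
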