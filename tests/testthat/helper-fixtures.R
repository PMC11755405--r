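# Small in-code fixtures shared across test files.

sample_cols_of <- function(data) {
  setdiff(names(data), c("protein_id", "unique_peptides", "length_aa",
                         "description"))
}

# Wide abundance tibble from a plain matrix (rows named by protein).
abundance_from_matrix <- function(mat, unique_peptides = NULL) {
  tb <- tibble::tibble(protein_id = rownames(mat))
  if (!is.null(unique_peptides)) tb$unique_peptides <- unique_peptides
  dplyr::bind_cols(tb, tibble::as_tibble(mat))
}

two_group_metadata <- function(n_a, n_b, labels = c("A", "B")) {
  tibble::tibble(
    sample_id = c(sprintf("a%d", seq_len(n_a)), sprintf("b%d", seq_len(n_b))),
    patient_id = sprintf("p%d", seq_len(n_a + n_b)),
    group = rep(labels, c(n_a, n_b)))
}

# Calibrant tibble for one peptide lying exactly on slope * x.
noiseless_series <- function(slope = 0.02, levels = default_calibration_levels(),
                             reps = 3, peptide_id = "PEP1") {
  tidyr::expand_grid(nominal_fmol = levels, replicate = seq_len(reps)) |>
    dplyr::mutate(peptide_id = peptide_id, sample_type = "calibrant",
                  ratio = slope * nominal_fmol)
}

# Independent brute-force two-stage (Benjamini-Krieger) step-up, written
# directly from the procedure's definition; used as the oracle for
# bky_adjust(). Deliberately shares no code with the implementation.
bf_step_up <- function(p_sorted, level) {
  m <- length(p_sorted)
  ok <- which(p_sorted <= seq_len(m) * level / m)
  if (length(ok) == 0) 0L else max(ok)
}

bf_bky_n_reject <- function(p_sorted, alpha) {
  m <- length(p_sorted)
  q1 <- alpha / (1 + alpha)
  r1 <- bf_step_up(p_sorted, q1)
  if (r1 == 0) return(0L)
  if (r1 == m) return(m)
  bf_step_up(p_sorted, q1 * m / (m - r1))
}

bf_bky_q <- function(p, tol = 1e-6) {
  ord <- order(p)
  ps <- p[ord]
  m <- length(p)
  q_sorted <- vapply(seq_len(m), function(k) {
    if (bf_bky_n_reject(ps, 1 - 1e-9) < k) return(1)
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (bf_bky_n_reject(ps, mid) >= k) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- cummax(q_sorted)
  q
}

# DE-stage calibration run: simulate a cohort with no loading variation
# and no dropout, feed the complete log2 intensities to the comparison.
de_stage_run <- function(seed, n_true_deps = 0, n_proteins = 2000,
                         n_per_group = 15, within_group_sd = 0.5,
                         true_log2fc = 2) {
  cfg <- lfq_sim_config(
    seed = seed, group_sizes = c(DCIS = n_per_group, IDC = n_per_group),
    n_proteins = n_proteins, n_true_deps = n_true_deps,
    true_log2fc = true_log2fc, within_group_sd = within_group_sd,
    loading_sd = 0, dropout_midpoint = -Inf)
  sim <- simulate_lfq_dataset(cfg)
  proc <- sim$abundance |> impute_missing() |> log2_view()
  list(records = run_comparison(proc, sim$metadata, "DCIS", "IDC"),
       truth = sim$truth)
}
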