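#' Read a wide abundance CSV
#'
#' First column is the protein id; the reserved metadata columns
#' `unique_peptides`, `length_aa` and `description` are recognized by
#' header; every remaining column is a sample. Empty cells, `NA` and
#' `NaN` are read as missing.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param col_map Optional named character vector renaming foreign
#'   headers to the expected ones before parsing, e.g.
#'   `c(protein_id = "Accession", unique_peptides = "# Unique Peptides")`,
#'   so spreadsheet-style exports can be adapted without code changes.
#' @return Wide abundance tibble (see [filter_by_detection()]). Rows
#'   with no observed intensity are kept, with a warning.
#' @export
read_abundance_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop_pq("file not found: %s", path)
  raw <- readr::read_csv(path, na = c("", "NA", "NaN"),
                         show_col_types = FALSE)
  if (!is.null(col_map)) {
    for (target in names(col_map)) {
      if (!col_map[[target]] %in% names(raw))
        stop_pq("col_map column '%s' not present in %s", col_map[[target]], path)
      names(raw)[names(raw) == col_map[[target]]] <- target
    }
  }
  if (!"protein_id" %in% names(raw)) names(raw)[1] <- "protein_id"
  if (anyDuplicated(names(raw)))
    stop_pq("duplicate sample column(s): %s",
            paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  dup <- raw$protein_id[duplicated(raw$protein_id)]
  if (length(dup) > 0)
    stop_pq("duplicate protein id(s): %s", paste(unique(dup), collapse = ", "))
  samples <- sample_cols(raw)
  for (s in samples) {
    if (!is.numeric(raw[[s]]))
      stop_pq("non-numeric cell(s) in sample column '%s'", s)
    neg <- which(raw[[s]] < 0)
    if (length(neg) > 0)
      stop_pq("negative intensity at row %d, column '%s'", neg[1], s)
  }
  mat <- as.matrix(raw[samples])
  blank_rows <- rowSums(!is.na(mat)) == 0
  if (any(blank_rows))
    warn(sprintf("%d protein(s) with no observed intensity kept: %s",
                 sum(blank_rows),
                 paste(head(raw$protein_id[blank_rows], 5), collapse = ", ")))
  raw
}

#' Write a wide abundance CSV
#'
#' Missing cells are written as empty strings; [read_abundance_csv()]
#' round-trips the table losslessly.
#'
#' @param data Wide abundance tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Read a long-format PRM report CSV
#'
#' Expected columns: `peptide_id`, `sample_id`, `sample_type`
#' (`blank` / `calibrant` / `unknown`), `nominal_fmol` (calibrants
#' only), `light_area`, `heavy_area`. The light/heavy response ratio is
#' computed per row; rows with `heavy_area = 0` (internal standard not
#' seen) get a missing ratio and are treated as not detected downstream,
#' not as an error.
#'
#' @param path Path to the CSV.
#' @param col_map Optional header renaming as in [read_abundance_csv()].
#' @return A list: `calibration` (tibble of blank + calibrant rows with
#'   `ratio`), `unknowns` (tibble of unknown rows with `ratio`).
#' @export
read_prm_report_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop_pq("file not found: %s", path)
  raw <- readr::read_csv(path, na = c("", "NA", "NaN"),
                         show_col_types = FALSE)
  if (!is.null(col_map)) {
    for (target in names(col_map)) {
      names(raw)[names(raw) == col_map[[target]]] <- target
    }
  }
  needed <- c("peptide_id", "sample_id", "sample_type", "light_area",
              "heavy_area")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0)
    stop_pq("PRM report lacks column(s): %s",
            paste(missing_cols, collapse = ", "))
  if (!"nominal_fmol" %in% names(raw)) raw$nominal_fmol <- NA_real_
  bad_type <- setdiff(unique(raw$sample_type),
                      c("blank", "calibrant", "unknown"))
  if (length(bad_type) > 0)
    stop_pq("unknown sample_type value(s): %s",
            paste(bad_type, collapse = ", "))
  no_nominal <- raw$sample_type == "calibrant" & is.na(raw$nominal_fmol)
  if (any(no_nominal))
    stop_pq("calibrant row(s) without nominal_fmol (first: peptide %s, sample %s)",
            raw$peptide_id[which(no_nominal)[1]],
            raw$sample_id[which(no_nominal)[1]])
  raw$ratio <- ifelse(raw$heavy_area > 0,
                      raw$light_area / raw$heavy_area, NA_real_)
  list(calibration = raw[raw$sample_type != "unknown", ],
       unknowns = raw[raw$sample_type == "unknown", ])
}

#' Write differential records as a volcano TSV
#'
#' @param records Tibble from [run_comparison()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volcano_tsv <- function(records, path) {
  readr::write_tsv(records, path, na = "")
  invisible(path)
}

#' Write a ranked list in the two-column RNK convention
#'
#' Tab-separated id/score pairs without a header, as enrichment tools
#' expect.
#'
#' @param ranked Tibble from [build_ranked_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  readr::write_tsv(ranked, path, col_names = FALSE)
  invisible(path)
}

#' Write the preprocessing report
#'
#' Per-sample normalization factors and imputed-cell counts as TSV.
#'
#' @param data Tibble from [preprocess_lfq()] (or [impute_missing()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_processing_report <- function(data, path) {
  report <- norm_factors(data) |>
    dplyr::left_join(
      imputed_cells(data) |> dplyr::count(.data$sample_id, name = "n_imputed"),
      by = "sample_id") |>
    dplyr::mutate(n_imputed = dplyr::coalesce(.data$n_imputed, 0L))
  readr::write_tsv(report, path)
  invisible(path)
}

#' Write a run manifest beside pipeline outputs
#'
#' Records the configuration snapshot, package version, input file
#' digests and a timestamp as JSON, so a run can be reproduced and
#' verified byte-for-byte.
#'
#' @param config Named list of the parameters the run used.
#' @param inputs Character vector of input paths to digest.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, inputs = character(0), path) {
  digests <- vapply(inputs, function(f) {
    if (!file.exists(f)) return(NA_character_)
    as.character(tools::md5sum(f))
  }, character(1))
  manifest <- list(
    package = "protquant",
    version = as.character(utils::packageVersion("protquant")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config,
    input_md5 = as.list(digests))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
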