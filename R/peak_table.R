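#' Read a peak intensity table
#'
#' Reads a delimited samples-by-peaks intensity table. The first column must
#' hold sample identifiers; every remaining column is a peak labelled by its
#' chemical shift in ppm (a 3-decimal string such as `"2.356"`). Cells equal
#' to `na` are non-detects, i.e. signals below the detection limit; they are
#' kept as `NA` and are distinct from a measured intensity of `0`.
#'
#' @param path Path to a CSV/TSV file with a header row of peak labels.
#' @param na Token encoding a non-detect (default: the empty string).
#' @param delim Field delimiter; guessed from the file extension when `NULL`.
#'
#' @return A tibble with a `sample_id` character column followed by one
#'   numeric column per peak; `NA` marks a non-detect.
#' @export
read_peak_table <- function(path, na = "", delim = NULL) {
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, na = na, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  validate_peak_table(tbl)
}

#' Write a peak intensity table
#'
#' Inverse of [read_peak_table()]: non-detects (`NA`) are written as the
#' `na` token so a write/read round trip is lossless.
#'
#' @param peaks A validated peak table (see [read_peak_table()]).
#' @param path Output file path.
#' @param na Token to write for non-detect cells.
#' @return `peaks`, invisibly.
#' @export
write_peak_table <- function(peaks, path, na = "") {
  readr::write_csv(peaks, path, na = na, progress = FALSE)
  invisible(peaks)
}

#' Validate a peak table
#'
#' Checks the structural invariants of a samples-by-peaks table: unique
#' sample and peak identifiers, peak labels that parse as chemical shifts in
#' (-1, 11) ppm, and finite nonnegative intensities wherever a value is
#' present.
#'
#' @param peaks A data frame with a `sample_id` column and numeric peak
#'   columns.
#' @return The table as a tibble, unchanged, if valid. Errors otherwise.
#' @export
validate_peak_table <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  if (!"sample_id" %in% names(peaks)) {
    abort("peak table must have a 'sample_id' column")
  }
  dup_s <- peaks$sample_id[duplicated(peaks$sample_id)]
  if (length(dup_s) > 0) {
    abort(paste0("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", ")))
  }
  peak_ids <- setdiff(names(peaks), "sample_id")
  if (anyDuplicated(peak_ids)) {
    abort(paste0("duplicated peak id(s): ",
                 paste(unique(peak_ids[duplicated(peak_ids)]), collapse = ", ")))
  }
  ppm <- suppressWarnings(as.numeric(peak_ids))
  bad <- peak_ids[is.na(ppm) | ppm <= -1 | ppm >= 11]
  if (length(bad) > 0) {
    abort(paste0("peak label(s) not a chemical shift in (-1, 11) ppm: ",
                 paste(bad, collapse = ", ")))
  }
  for (j in peak_ids) {
    x <- peaks[[j]]
    if (!is.numeric(x)) abort(paste0("peak column '", j, "' is not numeric"))
    ok <- is.na(x) | (is.finite(x) & x >= 0)
    if (!all(ok)) {
      i <- which(!ok)[1]
      abort(paste0("invalid intensity at sample '", peaks$sample_id[i],
                   "', peak '", j, "': ", x[i]))
    }
  }
  peaks
}

#' Convert a peak table to a numeric matrix
#'
#' @param peaks A peak table.
#' @return A numeric matrix (samples x peaks) with sample ids as row names;
#'   non-detects become `NA`.
#' @export
peaks_to_matrix <- function(peaks) {
  m <- as.matrix(peaks[setdiff(names(peaks), "sample_id")])
  rownames(m) <- peaks$sample_id
  storage.mode(m) <- "double"
  m
}

#' Convert a samples-by-peaks matrix back to a peak table
#'
#' @param m A numeric matrix with sample ids as row names.
#' @return A peak-table tibble.
#' @export
matrix_to_peaks <- function(m) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(sample_id = rownames(m), .before = 1)
}

#' Validate a sample metadata table
#'
#' The metadata table carries one row per sample with the design and
#' covariate record: `sample_id`, `role` (STUDY/QC/HV), `disease`
#' (PHT/PA/PPGL/CS or `NA`), `center`, `cluster` (1, 2 or `NA`),
#' `sample_age_days`, `batch`, `run_order`, `sex`, `patient_age`.
#' STUDY samples must carry a disease label; QC and HV samples must not.
#' `(batch, run_order)` pairs are unique; a run order above 18 triggers a
#' warning (spectra recorded that late in a batch are technically suspect)
#' but is not an error.
#'
#' @param meta A data frame of per-sample metadata.
#' @return The metadata as a tibble, unchanged, if valid.
#' @export
validate_sample_meta <- function(meta) {
  meta <- tibble::as_tibble(meta)
  need <- c("sample_id", "role", "disease", "center", "cluster",
            "sample_age_days", "batch", "run_order", "sex", "patient_age")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort(paste0("metadata missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicated sample id(s) in metadata")
  }
  if (!all(meta$role %in% c("STUDY", "QC", "HV"))) {
    abort("role must be one of STUDY, QC, HV")
  }
  ok_dis <- is.na(meta$disease) | meta$disease %in% c("PHT", "PA", "PPGL", "CS")
  if (!all(ok_dis)) abort("disease must be PHT, PA, PPGL, CS or NA")
  study_na <- meta$role == "STUDY" & is.na(meta$disease)
  if (any(study_na)) {
    abort(paste0("STUDY sample(s) without disease label: ",
                 paste(head(meta$sample_id[study_na], 5), collapse = ", ")))
  }
  ctrl_dis <- meta$role != "STUDY" & !is.na(meta$disease)
  if (any(ctrl_dis)) {
    abort(paste0("QC/HV sample(s) carry a disease label: ",
                 paste(head(meta$sample_id[ctrl_dis], 5), collapse = ", ")))
  }
  if (!all(is.na(meta$cluster) | meta$cluster %in% c(1, 2))) {
    abort("cluster must be 1, 2 or NA")
  }
  if (any(!is.na(meta$sample_age_days) & meta$sample_age_days < 0)) {
    abort("sample_age_days must be nonnegative")
  }
  key <- paste(meta$batch, meta$run_order)
  if (anyDuplicated(key)) {
    abort("(batch, run_order) pairs must be unique")
  }
  if (any(meta$run_order > 18, na.rm = TRUE)) {
    warn("run_order above 18 detected: spectra recorded that late in a batch are technically suspect")
  }
  meta
}
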