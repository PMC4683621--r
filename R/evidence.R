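#' Assemble and validate an evidence table
#'
#' An evidence table holds one row per (sample, replicate, protein)
#' observation, carrying the search-engine protein score, the number of
#' unique peptides, and the spectral count (peptide-spectrum matches).
#' Absence of a protein from a replicate is encoded by a missing row; rows
#' with zero counts are accepted on input and normalised away, so both
#' encodings mean "not detected".
#'
#' Validation enforces the evidence invariants:
#' * `unique_peptides >= 1` exactly when `spectral_count >= 1`;
#' * `spectral_count >= unique_peptides` (each peptide contributes at least
#'   one spectrum);
#' * scores and counts are non-negative;
#' * (sample, replicate, protein) keys are unique, samples exist in the
#'   design, and replicate indices are within the design's replicate count
#'   (1-based).
#'
#' @param records A data frame with columns `sample_id`, `replicate_id`,
#'   `protein_id`, `score`, `unique_peptides`, `spectral_count`.
#' @param design A [study_design()].
#' @return An `evidence_table` tibble (zero-count rows dropped), with the
#'   design attached as attribute `design`.
#' @export
evidence_table <- function(records, design) {
  stopifnot(inherits(design, "study_design"))
  needed <- c("sample_id", "replicate_id", "protein_id",
              "score", "unique_peptides", "spectral_count")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    trap_abort(sprintf("evidence is missing columns: %s",
                       paste(missing_cols, collapse = ", ")), "evidence")
  }
  rec <- as_tibble(records)[needed]
  rec$sample_id <- as.character(rec$sample_id)
  rec$protein_id <- as.character(rec$protein_id)
  rec$replicate_id <- as.integer(rec$replicate_id)
  rec$score <- as.numeric(rec$score)
  rec$unique_peptides <- as.integer(rec$unique_peptides)
  rec$spectral_count <- as.integer(rec$spectral_count)

  if (anyNA(rec)) {
    trap_abort("evidence contains missing or non-numeric values", "evidence")
  }
  if (any(rec$score < 0) || any(rec$unique_peptides < 0L) || any(rec$spectral_count < 0L)) {
    trap_abort("negative value in score or counts", "evidence")
  }
  bad_sample <- setdiff(unique(rec$sample_id), design$sample_id)
  if (length(bad_sample) > 0L) {
    trap_abort(sprintf("unknown sample label: %s", paste(bad_sample, collapse = ", ")),
               "evidence")
  }
  nrep <- setNames(design$n_replicates, design$sample_id)
  out_of_range <- rec$replicate_id < 1L | rec$replicate_id > nrep[rec$sample_id]
  if (any(out_of_range)) {
    trap_abort("replicate index out of range for its sample", "evidence")
  }
  if ((any(rec$spectral_count >= 1L & rec$unique_peptides < 1L)) ||
      (any(rec$spectral_count < 1L & rec$unique_peptides >= 1L))) {
    trap_abort("a detected protein must have >=1 unique peptide and >=1 spectrum",
               "evidence")
  }
  if (any(rec$spectral_count < rec$unique_peptides)) {
    trap_abort("spectral_count must be >= unique_peptides", "evidence")
  }
  key <- paste(rec$sample_id, rec$replicate_id, rec$protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    trap_abort("duplicate (sample, replicate, protein) key", "evidence")
  }
  # all-zero rows encode absence; normalise to missing rows
  rec <- rec[rec$spectral_count >= 1L, , drop = FALSE]
  rec <- arrange(rec, .data$sample_id, .data$replicate_id, .data$protein_id)
  structure(rec, design = design, class = c("evidence_table", class(rec)))
}

#' Read a per-replicate evidence TSV
#'
#' The canonical exchange format is a tab-separated file with a header and
#' columns `sample_id`, `replicate`, `protein_id`, `score`,
#' `unique_peptides`, `spectral_count`. (`replicate_id` is also accepted for
#' the replicate column.)
#'
#' @param path Path to the TSV file.
#' @param design A [study_design()] the rows are validated against.
#' @return An [evidence_table()].
#' @export
read_evidence <- function(path, design) {
  if (!file.exists(path)) {
    trap_abort(sprintf("evidence file not found: %s", path), "io")
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("replicate" %in% names(tbl) && !"replicate_id" %in% names(tbl)) {
    tbl <- rename(tbl, replicate_id = "replicate")
  }
  evidence_table(tbl, design)
}

#' Write an evidence table to TSV
#'
#' Inverse of [read_evidence()]: `write_evidence()` then [read_evidence()]
#' reproduces the table field-for-field.
#'
#' @param x An [evidence_table()].
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_evidence <- function(x, path) {
  stopifnot(inherits(x, "evidence_table"))
  out <- as_tibble(x)
  names(out)[names(out) == "replicate_id"] <- "replicate"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

#' Write the simulator's planted-truth table to TSV
#'
#' @param truth A tibble with columns `protein_id`, `role`.
#' @param path Output path.
#' @return `truth`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(all(c("protein_id", "role") %in% names(truth)))
  readr::write_tsv(as_tibble(truth)[c("protein_id", "role")], path, progress = FALSE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) trap_abort(sprintf("truth file not found: %s", path), "io")
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  bad <- setdiff(unique(tbl$role), planted_roles)
  if (length(bad) > 0L) {
    trap_abort(sprintf("unknown planted role: %s", paste(bad, collapse = ", ")), "truth")
  }
  as_tibble(tbl)[c("protein_id", "role")]
}
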