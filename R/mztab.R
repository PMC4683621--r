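#' Read protein-level evidence from an mzTab file
#'
#' Convenience reader for the mzTab identification-export format. Only the
#' protein section (`PRH` header line and `PRT` rows) is consulted. Because
#' mzTab exporters disagree on where per-assay spectral counts live, the
#' `assay_map` makes the dialect explicit: it maps each `ms_run`/assay index
#' to a sample and replicate of the study design, and optionally names the
#' columns the counts are read from.
#'
#' By default, for assay index `i`, spectral counts are read from
#' `num_psms_ms_run[i]`, unique peptides from
#' `num_peptides_unique_ms_run[i]`, and the score from
#' `best_search_engine_score[1]` (shared across assays). Any of these can
#' be overridden per assay via `spectral_col`, `peptides_col`, `score_col`
#' entries (typically pointing at `opt_` columns).
#'
#' @param path Path to the mzTab file.
#' @param design A [study_design()].
#' @param assay_map A list of entries, each a list with `assay` (integer
#'   index), `sample_id`, `replicate_id`, and optional `spectral_col`,
#'   `peptides_col`, `score_col` column-name overrides.
#' @return An [evidence_table()] with one record per (protein, assay) that
#'   has a nonzero spectral count.
#' @export
read_mztab_proteins <- function(path, design, assay_map) {
  if (!file.exists(path)) {
    trap_abort(sprintf("mzTab file not found: %s", path), "io")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  prh <- grep("^PRH\\t", lines, value = TRUE)
  prt <- grep("^PRT\\t", lines, value = TRUE)
  if (length(prh) != 1L || length(prt) == 0L) {
    trap_abort("mzTab file has no protein section (PRH/PRT lines)", "mztab")
  }
  header <- strsplit(prh, "\t", fixed = TRUE)[[1]][-1]
  cells <- lapply(strsplit(prt, "\t", fixed = TRUE), `[`, -1)
  if (any(lengths(cells) != length(header))) {
    trap_abort("PRT row with wrong number of fields", "mztab")
  }
  prot <- as_tibble(setNames(as.data.frame(do.call(rbind, cells),
                                           stringsAsFactors = FALSE), header))
  if (!"accession" %in% names(prot)) {
    trap_abort("mzTab protein section lacks an 'accession' column", "mztab")
  }

  map <- purrr::map_dfr(assay_map, function(m) {
    tibble(
      assay = as.integer(m$assay),
      sample_id = as.character(m$sample_id),
      replicate_id = as.integer(m$replicate_id),
      spectral_col = as.character(m$spectral_col %||% sprintf("num_psms_ms_run[%d]", as.integer(m$assay))),
      peptides_col = as.character(m$peptides_col %||% sprintf("num_peptides_unique_ms_run[%d]", as.integer(m$assay))),
      score_col = as.character(m$score_col %||% "best_search_engine_score[1]")
    )
  })
  if (anyNA(map$assay) || anyDuplicated(map$assay)) {
    trap_abort("assay_map entries need unique integer 'assay' indices", "mztab")
  }

  # every per-assay count column present in the file must be mapped
  seen <- unique(as.integer(sub("^num_psms_ms_run\\[(\\d+)\\]$", "\\1",
                                grep("^num_psms_ms_run\\[\\d+\\]$", names(prot), value = TRUE))))
  unmapped <- setdiff(seen, map$assay)
  if (length(unmapped) > 0L) {
    trap_abort(sprintf("assay %s present in mzTab but absent from assay_map",
                       paste(unmapped, collapse = ", ")), "mztab")
  }

  mz_num <- function(x, what) {
    x[x %in% c("null", "NA", "")] <- NA
    out <- suppressWarnings(as.numeric(x))
    if (any(is.na(out) & !is.na(x))) {
      trap_abort(sprintf("malformed numeric field in mzTab column '%s'", what), "mztab")
    }
    out
  }

  recs <- purrr::pmap_dfr(map, function(assay, sample_id, replicate_id,
                                        spectral_col, peptides_col, score_col) {
    for (col in c(spectral_col, peptides_col, score_col)) {
      if (!col %in% names(prot)) {
        trap_abort(sprintf("mzTab column '%s' (assay %d) not found", col, assay), "mztab")
      }
    }
    sc <- mz_num(prot[[spectral_col]], spectral_col)
    up <- mz_num(prot[[peptides_col]], peptides_col)
    score <- mz_num(prot[[score_col]], score_col)
    keep <- !is.na(sc) & sc >= 1
    tibble(
      sample_id = sample_id,
      replicate_id = replicate_id,
      protein_id = prot$accession[keep],
      score = score[keep],
      unique_peptides = up[keep],
      spectral_count = sc[keep]
    )
  })
  evidence_table(recs, design)
}
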