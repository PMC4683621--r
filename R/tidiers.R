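#' Tidy a classification
#'
#' Returns one row per protein with the audit trail collapsed to a single
#' string, suitable for further dplyr work or export.
#'
#' @param x A [classify_proteins()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trap_classification <- function(x, ...) {
  as_tibble(x) %>%
    mutate(audit = purrr::map_chr(.data$audit, paste, collapse = " | "))
}

#' Summarise a classification in one row
#'
#' @param x A [classify_proteins()] result.
#' @param ... Unused.
#' @return A one-row tibble: protein total, one count column per category,
#'   the number of substrate calls, and the thresholds used.
#' @export
glance.trap_classification <- function(x, ...) {
  counts <- table(x$category)
  p <- attr(x, "params")
  tibble(
    n_proteins = nrow(x),
    n_shared = counts[["SHARED_INTERACTOR"]],
    n_trap_specific = counts[["TRAP_SPECIFIC"]],
    n_trap_exclusive = sum(x$trap_exclusive %in% TRUE),
    n_substrates = sum(x$substrate),
    n_trap_enriched = sum(x$trap_enriched %in% TRUE),
    n_wt_preferential = counts[["WT_PREFERENTIAL"]],
    n_background = counts[["BACKGROUND"]],
    n_low_evidence = counts[["LOW_EVIDENCE"]],
    n_not_reproducible = counts[["NOT_REPRODUCIBLE"]],
    score_min = p$score_min,
    min_replicates = p$min_replicates,
    rescue_factor = p$rescue_factor,
    specific_factor = p$specific_factor,
    enriched_factor = p$enriched_factor,
    min_avg_unique_peptides = p$min_avg_unique_peptides
  )
}

#' Tidy an evaluation
#'
#' @param x An [evaluate_classification()] result.
#' @param ... Unused.
#' @return The per-role metrics tibble (`role`, `expected_category`,
#'   `n_planted`, `n_assigned`, `n_correct`, `precision`, `recall`).
#' @export
tidy.trap_evaluation <- function(x, ...) {
  x$metrics
}

#' Summarise an evaluation in one row
#'
#' @param x An [evaluate_classification()] result.
#' @param ... Unused.
#' @return A one-row tibble with the protein total, overall accuracy
#'   (fraction of planted proteins assigned their expected category), and
#'   the minimum per-role precision and recall (ignoring undefined ones).
#' @export
glance.trap_evaluation <- function(x, ...) {
  m <- x$metrics
  tibble(
    n_proteins = x$n_proteins,
    accuracy = sum(m$n_correct) / sum(m$n_planted),
    min_precision = if (all(is.na(m$precision))) NA_real_ else min(m$precision, na.rm = TRUE),
    min_recall = if (all(is.na(m$recall))) NA_real_ else min(m$recall, na.rm = TRUE)
  )
}
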