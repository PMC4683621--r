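#' Score a classification against planted truth
#'
#' Compares the categories assigned by [classify_proteins()] with the roles
#' planted by [simulate_evidence()] or [clpp_fixture()]. Each role maps to
#' one expected category (contaminant to background, interactor to shared
#' interactor, substrate to trap-specific, wild-type partner to
#' wild-type-preferential, sporadic to not-reproducible). For each role:
#'
#' * recall = planted proteins assigned the expected category / planted;
#' * precision = planted proteins assigned the expected category / all
#'   proteins assigned that category.
#'
#' Metrics with a zero denominator are reported as `NA`, never as `0/0`.
#'
#' @param x A [classify_proteins()] result covering every truth protein
#'   (`NOT_REPRODUCIBLE` is a legal assignment; a truth protein entirely
#'   absent from `x` is an error).
#' @param truth A tibble `protein_id`, `role` (non-empty).
#' @return A `trap_evaluation` object: a list with `confusion` (tibble
#'   `role` x `category` counts), `metrics` (per-role precision/recall),
#'   and `n_proteins`. [tidy()], [glance()] and [autoplot()] methods are
#'   provided.
#' @examples
#' sim <- simulate_evidence(sim_params(seed = 7))
#' cls <- sim$evidence |>
#'   apply_score_filter() |>
#'   aggregate_evidence() |>
#'   classify_proteins()
#' evaluate_classification(cls, sim$truth)
#' @export
evaluate_classification <- function(x, truth) {
  stopifnot(inherits(x, "trap_classification"))
  truth <- as_tibble(truth)
  if (nrow(truth) == 0L) trap_abort("truth table is empty", "evaluate")
  bad_role <- setdiff(unique(truth$role), planted_roles)
  if (length(bad_role) > 0L) {
    trap_abort(sprintf("unknown planted role: %s", paste(bad_role, collapse = ", ")),
               "evaluate")
  }
  missing <- setdiff(truth$protein_id, x$protein_id)
  if (length(missing) > 0L) {
    trap_abort(sprintf("truth proteins missing from classification: %s",
                       paste(utils::head(missing, 5), collapse = ", ")), "evaluate")
  }

  joined <- truth %>%
    left_join(as_tibble(x)[c("protein_id", "category")], by = "protein_id") %>%
    mutate(role = factor(.data$role, levels = planted_roles))
  confusion <- joined %>%
    count(.data$role, .data$category, .drop = FALSE, name = "n")

  metrics <- purrr::map_dfr(planted_roles, function(r) {
    expected <- role_expected_category[[r]]
    planted <- sum(joined$role == r)
    assigned <- sum(x$category == expected)
    correct <- sum(joined$role == r & joined$category == expected)
    tibble(
      role = r, expected_category = expected,
      n_planted = planted, n_assigned = assigned, n_correct = correct,
      precision = if (assigned > 0) correct / assigned else NA_real_,
      recall = if (planted > 0) correct / planted else NA_real_
    )
  })

  structure(
    list(confusion = confusion, metrics = metrics, n_proteins = nrow(truth)),
    class = "trap_evaluation"
  )
}

#' @export
print.trap_evaluation <- function(x, ...) {
  cat("<trap_evaluation> ", x$n_proteins, " proteins\n", sep = "")
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' Join external annotations onto a classification
#'
#' Left-joins an annotation table (for instance homologue accessions and
#' gene symbols from an orthology analysis, see [clpp_annotations()]) onto
#' classification rows. Proteins without annotation keep empty fields; the
#' row count and every classification column are unchanged.
#'
#' @param x A [classify_proteins()] result (or any tibble with a
#'   `protein_id` column).
#' @param annotations A tibble with `protein_id` plus annotation columns;
#'   accessions must be unique.
#' @return `x` with the annotation columns appended.
#' @export
annotate_classification <- function(x, annotations) {
  annotations <- as_tibble(annotations)
  if (!"protein_id" %in% names(annotations)) {
    trap_abort("annotations need a protein_id column", "annotate")
  }
  dup <- unique(annotations$protein_id[duplicated(annotations$protein_id)])
  if (length(dup) > 0L) {
    trap_abort(sprintf("duplicate protein_id in annotations: %s",
                       paste(utils::head(dup, 5), collapse = ", ")), "annotate")
  }
  attrs <- attributes(x)
  out <- left_join(as_tibble(x), annotations, by = "protein_id")
  for (a in setdiff(names(attrs), c("names", "row.names", "class"))) {
    attr(out, a) <- attrs[[a]]
  }
  class(out) <- attrs$class
  out
}

#' Read an annotation TSV
#'
#' @param path TSV with a `protein_id` column plus free annotation columns.
#' @return A tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) trap_abort(sprintf("file not found: %s", path), "io")
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"protein_id" %in% names(tbl)) {
    trap_abort("annotations need a protein_id column", "annotate")
  }
  tbl
}
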