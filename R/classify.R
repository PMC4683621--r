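#' Classify proteins from a substrate-trapping experiment
#'
#' Implements the full decision cascade that turns per-sample aggregates
#' into one category per protein. Every protein detected anywhere receives
#' exactly one of:
#'
#' * `NOT_REPRODUCIBLE` — reproducibly present (>= `min_replicates`
#'   detections) in no sample;
#' * `BACKGROUND` — reproducibly present in the control purification and
#'   rescued into neither bait candidate set;
#' * `SHARED_INTERACTOR` — candidate with both baits, trap-vs-reference
#'   enrichment factor <= `specific_factor`; flagged `trap_enriched` when
#'   the factor exceeds `enriched_factor`;
#' * `TRAP_SPECIFIC` — candidate with the trap bait only
#'   (`trap_exclusive = TRUE`), or with both baits but enriched more than
#'   `specific_factor`-fold in the trap sample (`trap_exclusive = FALSE`);
#' * `WT_PREFERENTIAL` — candidate with the reference bait only; reported,
#'   but excluded from the final interactor lists;
#' * `LOW_EVIDENCE` — a shared or trap-specific candidate failing the
#'   unique-peptide floor (> `min_avg_unique_peptides` on average in both
#'   bait samples for shared proteins, in the trap sample for trap-specific
#'   ones).
#'
#' The cascade, step by step:
#' 1. *Reproducibility*: a protein is present in a sample when detected in
#'    at least `min_replicates` replicates.
#' 2. *Background subtraction with rescue*: a protein present in the
#'    control is background-tainted; it re-enters a bait's candidate set
#'    only if its bait-vs-control enrichment factor is defined and exceeds
#'    `rescue_factor` (evaluated per bait independently).
#' 3. *Candidate sets* per bait: present and not un-rescued background.
#' 4. *Both baits*: trap-vs-reference enrichment factor decides
#'    trap-specific versus shared (with the trap-enriched flag).
#' 5. *Trap only*: trap-specific by exclusivity.
#' 6. *Reference only*: wild-type-preferential.
#' 7. *Unique-peptide floor* demotes under-supported shared and
#'    trap-specific candidates to `LOW_EVIDENCE`. Wild-type-preferential
#'    proteins keep their category — they are already excluded from the
#'    final lists — with the floor outcome recorded in the audit trail.
#' 8. *Substrate call*: trap-specific proteins not on the bait-machinery
#'    exclusion list are flagged as potential substrates.
#'
#' Every step appends a line to the per-protein `audit` trail.
#'
#' @param agg A [aggregate_evidence()] result.
#' @param exclusions Character vector of bait-machinery accessions that can
#'   never be called substrates (e.g. the CLPX chaperone partner,
#'   [clpp_exclusions()]).
#' @param design,params Normally taken from the attributes `agg` carries.
#' @return A `trap_classification` tibble with one row per observed
#'   protein: `protein_id`, `category`, `trap_enriched`, `trap_exclusive`,
#'   `substrate`, the three enrichment factors (`NA` when undefined),
#'   per-sample mean unique peptides, and the `audit` list-column.
#'   [tidy()] and [glance()] methods and an [autoplot()] method are
#'   provided.
#' @examples
#' fx <- clpp_fixture()
#' cls <- fx$evidence |>
#'   apply_score_filter() |>
#'   aggregate_evidence() |>
#'   classify_proteins(exclusions = clpp_exclusions())
#' glance(cls)
#' @export
classify_proteins <- function(agg,
                              exclusions = character(),
                              design = attr(agg, "design"),
                              params = attr(agg, "params")) {
  stopifnot(inherits(agg, "sample_aggregate"))
  if (is.null(design)) trap_abort("no study design attached or supplied", "classify")
  if (is.null(params)) params <- filter_params()
  if (!inherits(params, "filter_params")) {
    params <- do.call(filter_params, as.list(params))
  }
  exclusions <- as.character(unlist(exclusions, use.names = FALSE))
  bad <- setdiff(unique(agg$sample_id), design$sample_id)
  if (length(bad) > 0L) {
    trap_abort(sprintf("aggregates reference samples absent from design: %s",
                       paste(bad, collapse = ", ")), "classify")
  }

  s_ctrl <- sample_for_role(design, "control")
  s_ref  <- sample_for_role(design, "bait_reference")
  s_trap <- sample_for_role(design, "bait_trap")

  proteins <- sort(unique(agg$protein_id))
  pick <- function(sample, col, default) {
    i <- match(paste(proteins, sample), paste(agg$protein_id, agg$sample_id))
    out <- agg[[col]][i]
    out[is.na(i)] <- default
    out
  }
  w <- tibble(
    protein_id = proteins,
    present_ctrl = pick(s_ctrl, "present", FALSE),
    present_ref  = pick(s_ref, "present", FALSE),
    present_trap = pick(s_trap, "present", FALSE),
    total_ctrl = pick(s_ctrl, "total_spectral", 0),
    total_ref  = pick(s_ref, "total_spectral", 0),
    total_trap = pick(s_trap, "total_spectral", 0),
    mean_unique_control   = pick(s_ctrl, "mean_unique_peptides", 0),
    mean_unique_reference = pick(s_ref, "mean_unique_peptides", 0),
    mean_unique_trap      = pick(s_trap, "mean_unique_peptides", 0)
  )

  w <- w %>% mutate(
    ef_ref_vs_control  = ifelse(.data$total_ctrl > 0, .data$total_ref / .data$total_ctrl, NA_real_),
    ef_trap_vs_control = ifelse(.data$total_ctrl > 0, .data$total_trap / .data$total_ctrl, NA_real_),
    ef_trap_vs_ref_raw = ifelse(.data$total_ref > 0, .data$total_trap / .data$total_ref, NA_real_),
    tainted = .data$present_ctrl,
    rescued_ref  = .data$tainted & !is.na(.data$ef_ref_vs_control) &
      .data$ef_ref_vs_control > params$rescue_factor,
    rescued_trap = .data$tainted & !is.na(.data$ef_trap_vs_control) &
      .data$ef_trap_vs_control > params$rescue_factor,
    cand_ref  = .data$present_ref & (!.data$tainted | .data$rescued_ref),
    cand_trap = .data$present_trap & (!.data$tainted | .data$rescued_trap)
  )

  w <- w %>% mutate(
    category = case_when(
      !.data$present_ctrl & !.data$present_ref & !.data$present_trap ~ "NOT_REPRODUCIBLE",
      .data$tainted & !.data$cand_ref & !.data$cand_trap ~ "BACKGROUND",
      .data$cand_ref & .data$cand_trap &
        .data$ef_trap_vs_ref_raw > params$specific_factor ~ "TRAP_SPECIFIC",
      .data$cand_ref & .data$cand_trap ~ "SHARED_INTERACTOR",
      .data$cand_trap ~ "TRAP_SPECIFIC",
      TRUE ~ "WT_PREFERENTIAL"
    ),
    trap_exclusive = ifelse(.data$category == "TRAP_SPECIFIC",
                            !.data$cand_ref, NA),
    trap_enriched = ifelse(.data$category == "SHARED_INTERACTOR",
                           .data$ef_trap_vs_ref_raw > params$enriched_factor, NA),
    floor_ok = case_when(
      .data$category == "SHARED_INTERACTOR" ~
        .data$mean_unique_reference > params$min_avg_unique_peptides &
        .data$mean_unique_trap > params$min_avg_unique_peptides,
      .data$category == "TRAP_SPECIFIC" ~
        .data$mean_unique_trap > params$min_avg_unique_peptides,
      .data$category == "WT_PREFERENTIAL" ~
        .data$mean_unique_reference > params$min_avg_unique_peptides,
      TRUE ~ NA
    )
  )

  demote <- w$category %in% c("SHARED_INTERACTOR", "TRAP_SPECIFIC") & !w$floor_ok
  w$final_category <- ifelse(demote, "LOW_EVIDENCE", w$category)
  w <- w %>% mutate(
    substrate = .data$final_category == "TRAP_SPECIFIC" &
      !.data$protein_id %in% exclusions,
    trap_enriched = ifelse(.data$final_category == "SHARED_INTERACTOR",
                           .data$trap_enriched, NA),
    trap_exclusive = ifelse(.data$final_category == "TRAP_SPECIFIC",
                            .data$trap_exclusive, NA),
    # undefined by convention whenever the reference side is not a candidate
    ef_trap_vs_ref = ifelse(.data$cand_ref & .data$cand_trap,
                            .data$ef_trap_vs_ref_raw, NA_real_)
  )

  audit <- purrr::pmap(
    list(w$present_ctrl, w$present_ref, w$present_trap, w$tainted,
         w$rescued_ref, w$rescued_trap, w$cand_ref, w$cand_trap,
         w$ef_trap_vs_ref_raw, w$category, w$floor_ok, w$final_category,
         w$substrate, w$protein_id),
    function(pc, pr, pt, taint, rr, rt, cr, ct, ef_tr, cat0, fok, cat, sub, id) {
      fmt <- function(x) ifelse(is.na(x), "undefined", sprintf("%.3g", x))
      lines <- sprintf(
        "reproducibility: present control=%s reference=%s trap=%s (min_replicates=%d)",
        pc, pr, pt, params$min_replicates)
      lines <- c(lines, if (taint) {
        sprintf("background: control-tainted; rescue(>%g) reference=%s trap=%s",
                params$rescue_factor, rr, rt)
      } else "background: not present in control")
      lines <- c(lines, sprintf("candidates: reference=%s trap=%s", cr, ct))
      if (cr && ct) {
        lines <- c(lines, sprintf(
          "trap-vs-reference: EF=%s on spectral counts (trap-specific if >%g, enriched if >%g)",
          fmt(ef_tr), params$specific_factor, params$enriched_factor))
      }
      lines <- c(lines, sprintf("category before floor: %s", cat0))
      if (!is.na(fok)) {
        lines <- c(lines, sprintf(
          "unique-peptide floor (> %g on average): %s%s",
          params$min_avg_unique_peptides,
          ifelse(fok, "pass", "fail"),
          ifelse(!fok && cat == "WT_PREFERENTIAL",
                 " (recorded; wt-preferential proteins keep their category)", "")))
      }
      c(lines, sprintf("final: %s%s", cat,
                       ifelse(cat == "TRAP_SPECIFIC",
                              ifelse(sub, ", potential substrate",
                                     ", excluded bait machinery"), "")))
    }
  )

  out <- tibble(
    protein_id = w$protein_id,
    category = factor(w$final_category, levels = trap_categories),
    trap_enriched = w$trap_enriched,
    trap_exclusive = w$trap_exclusive,
    substrate = w$substrate,
    ef_trap_vs_ref = w$ef_trap_vs_ref,
    ef_ref_vs_control = w$ef_ref_vs_control,
    ef_trap_vs_control = w$ef_trap_vs_control,
    mean_unique_control = w$mean_unique_control,
    mean_unique_reference = w$mean_unique_reference,
    mean_unique_trap = w$mean_unique_trap,
    audit = audit
  ) %>%
    arrange(.data$category, .data$protein_id)
  structure(out, design = design, params = params, exclusions = exclusions,
            class = c("trap_classification", class(out)))
}

#' Extract the final reported protein lists
#'
#' Splits a classification into the three lists the assay reports:
#' potential interaction partners (shared interactors), potential substrates
#' (trap-specific proteins not on the exclusion list), and the
#' trap-enriched subset of the shared interactors. Wild-type-preferential,
#' background, low-evidence, and non-reproducible proteins never enter
#' these lists. Each list is sorted by descending mean unique peptides in
#' the trap sample, ties broken by accession.
#'
#' @param x A [classify_proteins()] result.
#' @return A named list of tibbles: `interactors`, `substrates`, `enriched`.
#' @export
final_lists <- function(x) {
  stopifnot(inherits(x, "trap_classification"))
  tbl <- as_tibble(x)
  ord <- function(d) arrange(d, dplyr::desc(.data$mean_unique_trap), .data$protein_id)
  list(
    interactors = ord(filter(tbl, .data$category == "SHARED_INTERACTOR")),
    substrates  = ord(filter(tbl, .data$substrate)),
    enriched    = ord(filter(tbl, .data$category == "SHARED_INTERACTOR" &
                               .data$trap_enriched %in% TRUE))
  )
}

#' Write / read a classification table
#'
#' `write_classification()` writes one row per protein, ordered by category
#' then accession, with empty fields for undefined enrichment factors and
#' the audit trail collapsed into a single `" | "`-separated field.
#' `read_classification()` reads such a file back into a tibble.
#'
#' @param x A [classify_proteins()] result.
#' @param path Output (input) path.
#' @return `write_classification()` returns `x` invisibly;
#'   `read_classification()` returns a tibble.
#' @export
write_classification <- function(x, path) {
  stopifnot(inherits(x, "trap_classification"))
  out <- as_tibble(x) %>%
    mutate(audit = purrr::map_chr(.data$audit, paste, collapse = " | ")) %>%
    arrange(.data$category, .data$protein_id)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(x)
}

#' @rdname write_classification
#' @export
read_classification <- function(path) {
  if (!file.exists(path)) trap_abort(sprintf("file not found: %s", path), "io")
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           protein_id = readr::col_character(),
                           category = readr::col_character(),
                           trap_enriched = readr::col_logical(),
                           trap_exclusive = readr::col_logical(),
                           substrate = readr::col_logical(),
                           audit = readr::col_character()
                         ))
  tbl$category <- factor(tbl$category, levels = trap_categories)
  tbl$audit <- strsplit(tbl$audit, " | ", fixed = TRUE)
  as_tibble(tbl)
}

#' @export
print.trap_classification <- function(x, ...) {
  counts <- table(x$category)
  cat("<trap_classification> ", nrow(x), " proteins\n", sep = "")
  for (cat_name in trap_categories) {
    cat(sprintf("  %-18s %d\n", cat_name, counts[[cat_name]]))
  }
  cat(sprintf("  substrates: %d\n", sum(x$substrate)))
  NextMethod()
}
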