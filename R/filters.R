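#' Filtering and classification thresholds
#'
#' Bundles the thresholds of the selection cascade. Defaults reproduce the
#' original substrate-trapping analysis:
#'
#' * `score_min = 40` — minimum search-engine (Mascot) protein score; a
#'   record is retained when `score >= score_min`.
#' * `min_replicates = 2` — a protein counts as reproducibly present in a
#'   sample when detected in at least this many biological replicates
#'   (2 of 3 in the original design).
#' * `rescue_factor = 3` — a background-tainted protein is rescued into a
#'   bait's candidate set when its bait-vs-control spectral-count enrichment
#'   factor is strictly greater than this.
#' * `specific_factor = 3` — a protein found with both baits is called
#'   trap-specific when its trap-vs-reference enrichment factor is strictly
#'   greater than this.
#' * `enriched_factor = 1.5` — a shared interactor is flagged trap-enriched
#'   when its trap-vs-reference enrichment factor is strictly greater than
#'   this.
#' * `min_avg_unique_peptides = 1` — candidate proteins must have strictly
#'   more than this many unique peptides on average across all replicates of
#'   the supporting sample(s).
#'
#' @param score_min,min_replicates,rescue_factor,specific_factor,enriched_factor,min_avg_unique_peptides
#'   See above.
#' @return A `filter_params` list.
#' @examples
#' filter_params()
#' filter_params(score_min = 60, enriched_factor = 2)
#' @export
filter_params <- function(score_min = 40,
                          min_replicates = 2,
                          rescue_factor = 3,
                          specific_factor = 3,
                          enriched_factor = 1.5,
                          min_avg_unique_peptides = 1) {
  p <- list(
    score_min = as.numeric(score_min),
    min_replicates = as.integer(min_replicates),
    rescue_factor = as.numeric(rescue_factor),
    specific_factor = as.numeric(specific_factor),
    enriched_factor = as.numeric(enriched_factor),
    min_avg_unique_peptides = as.numeric(min_avg_unique_peptides)
  )
  if (anyNA(unlist(p))) trap_abort("filter parameters must be numeric", "params")
  if (p$min_replicates < 1L) trap_abort("min_replicates must be >= 1", "params")
  with(p, {
    if (any(c(rescue_factor, specific_factor, enriched_factor,
              min_avg_unique_peptides) <= 0) || score_min < 0) {
      trap_abort("thresholds must be positive (score_min non-negative)", "params")
    }
  })
  if (p$enriched_factor > p$specific_factor) {
    trap_abort("enriched_factor must not exceed specific_factor", "params")
  }
  structure(p, class = "filter_params")
}

#' Apply the search-engine score threshold
#'
#' Removes evidence records whose protein score falls below the threshold.
#' The comparison is inclusive: a record scoring exactly `score_min` is
#' retained.
#'
#' @param x An [evidence_table()].
#' @param score_min Score threshold (default 40).
#' @return The filtered [evidence_table()]; the design is unchanged.
#' @export
apply_score_filter <- function(x, score_min = 40) {
  stopifnot(inherits(x, "evidence_table"))
  design <- attr(x, "design")
  keep <- x$score >= score_min
  out <- as_tibble(x)[keep, , drop = FALSE]
  structure(out, design = design, class = c("evidence_table", class(out)))
}

#' Aggregate evidence per protein and sample
#'
#' Summarises the (score-filtered) evidence into one row per (protein,
#' sample) pair with at least one detection:
#'
#' * `n_detected` — replicates with a detection (spectral count >= 1);
#' * `mean_unique_peptides` — arithmetic mean of unique peptides over *all*
#'   replicates of the sample, zeros included (so counts (2,1,1) over three
#'   replicates give 4/3, displayed as 1.3 at one decimal);
#' * `total_spectral` — summed spectral counts across replicates, the basis
#'   of every enrichment factor;
#' * `present` — the reproducibility call, `n_detected >= min_replicates`.
#'
#' @param x An [evidence_table()], normally after [apply_score_filter()].
#' @param params A [filter_params()].
#' @return A `sample_aggregate` tibble with the design and params attached
#'   as attributes.
#' @export
aggregate_evidence <- function(x, params = filter_params()) {
  stopifnot(inherits(x, "evidence_table"), inherits(params, "filter_params"))
  design <- attr(x, "design")
  nrep <- setNames(design$n_replicates, design$sample_id)
  agg <- as_tibble(x) %>%
    group_by(.data$protein_id, .data$sample_id) %>%
    summarise(
      n_detected = sum(.data$spectral_count >= 1L),
      sum_unique_peptides = sum(.data$unique_peptides),
      total_spectral = sum(.data$spectral_count),
      .groups = "drop"
    ) %>%
    mutate(
      n_replicates = unname(nrep[.data$sample_id]),
      mean_unique_peptides = .data$sum_unique_peptides / .data$n_replicates,
      present = .data$n_detected >= params$min_replicates
    ) %>%
    select("protein_id", "sample_id", "n_detected", "n_replicates",
           "mean_unique_peptides", "total_spectral", "present") %>%
    arrange(.data$protein_id, .data$sample_id)
  structure(agg, design = design, params = params,
            class = c("sample_aggregate", class(agg)))
}

#' Spectral-count enrichment factor between two samples
#'
#' The enrichment factor of a protein between two samples is the ratio of
#' its summed spectral counts, numerator over denominator. When the
#' denominator total is zero the factor is undefined and `NA` is returned —
#' exclusivity is handled by the classification cascade, never as infinite
#' enrichment. No pseudocount is used.
#'
#' @param agg A [aggregate_evidence()] result.
#' @param protein_id Protein accession (must occur in `agg`).
#' @param numerator_sample,denominator_sample Sample labels.
#' @return A positive number, or `NA_real_` when undefined.
#' @export
enrichment_factor <- function(agg, protein_id, numerator_sample, denominator_sample) {
  stopifnot(inherits(agg, "sample_aggregate"))
  design <- attr(agg, "design")
  if (!protein_id %in% agg$protein_id) {
    trap_abort(sprintf("unknown protein: %s", protein_id), "lookup")
  }
  for (s in c(numerator_sample, denominator_sample)) {
    if (!s %in% design$sample_id) trap_abort(sprintf("unknown sample: %s", s), "lookup")
  }
  total_of <- function(s) {
    i <- agg$protein_id == protein_id & agg$sample_id == s
    if (any(i)) sum(agg$total_spectral[i]) else 0L
  }
  den <- total_of(denominator_sample)
  if (den == 0L) return(NA_real_)
  total_of(numerator_sample) / den
}
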