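#' Describe a three-arm substrate-trapping study design
#'
#' A substrate-trapping AP-MS experiment has exactly three purifications:
#' a background `control` (untagged strain; nonspecific resin binders), a
#' `bait_reference` purification of the catalytically active tagged bait, and
#' a `bait_trap` purification of the catalytically dead variant in which
#' substrates accumulate. Each sample is purified in independent biological
#' replicates (three in the original assay).
#'
#' @param control,bait_reference,bait_trap Sample labels, one per role.
#' @param n_replicates Number of biological replicates per sample; either a
#'   single value recycled to all samples or a vector of three (control,
#'   reference, trap).
#'
#' @return A `study_design` tibble with columns `sample_id`, `role`,
#'   `n_replicates`.
#' @examples
#' study_design("ctrl", "wt", "trap")
#' @export
study_design <- function(control, bait_reference, bait_trap, n_replicates = 3) {
  ids <- c(control, bait_reference, bait_trap)
  if (!is.character(ids) || length(ids) != 3L || anyNA(ids) || any(ids == "")) {
    trap_abort("each role needs exactly one non-empty sample label", "design")
  }
  if (anyDuplicated(ids)) {
    trap_abort("sample labels must be unique across roles", "design")
  }
  n_replicates <- as.integer(rep_len(n_replicates, 3L))
  if (anyNA(n_replicates) || any(n_replicates < 1L)) {
    trap_abort("n_replicates must be a positive integer for every sample", "design")
  }
  out <- tibble(sample_id = ids, role = trap_roles, n_replicates = n_replicates)
  class(out) <- c("study_design", class(out))
  out
}

#' Read a study design from a YAML configuration file
#'
#' The file lists one entry per sample under the key `samples`, each with
#' `id`, `role` (one of `control`, `bait_reference`, `bait_trap`) and an
#' optional `replicates` (default 3):
#'
#' ```yaml
#' samples:
#'   - {id: ctrl, role: control, replicates: 3}
#'   - {id: wt,   role: bait_reference, replicates: 3}
#'   - {id: trap, role: bait_trap, replicates: 3}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A [study_design()] tibble.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    trap_abort(sprintf("design file not found: %s", path), "io")
  }
  cfg <- yaml::read_yaml(path)
  design_from_config(cfg)
}

# Build a validated design from a parsed config list (shared by read_design
# and the pipeline runner).
design_from_config <- function(cfg) {
  samples <- cfg$samples
  if (is.null(samples) || length(samples) == 0L) {
    trap_abort("design config has no 'samples' entries", "design")
  }
  entries <- purrr::map_dfr(samples, function(s) {
    tibble(
      sample_id = as.character(s$id %||% NA_character_),
      role = as.character(s$role %||% NA_character_),
      n_replicates = as.integer(s$replicates %||% 3L)
    )
  })
  if (anyNA(entries$sample_id) || anyNA(entries$role)) {
    trap_abort("every sample entry needs 'id' and 'role'", "design")
  }
  bad_role <- setdiff(entries$role, trap_roles)
  if (length(bad_role) > 0L) {
    trap_abort(sprintf("unknown role: %s", paste(bad_role, collapse = ", ")), "design")
  }
  dup <- entries$role[duplicated(entries$role)]
  if (length(dup) > 0L) {
    trap_abort(sprintf("duplicate role: %s", paste(unique(dup), collapse = ", ")), "design")
  }
  missing <- setdiff(trap_roles, entries$role)
  if (length(missing) > 0L) {
    trap_abort(sprintf("missing role: %s", paste(missing, collapse = ", ")), "design")
  }
  e <- entries[match(trap_roles, entries$role), ]
  study_design(e$sample_id[1], e$sample_id[2], e$sample_id[3], e$n_replicates)
}

sample_for_role <- function(design, role) {
  design$sample_id[design$role == role]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
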