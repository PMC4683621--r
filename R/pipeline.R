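#' Run the full classification pipeline in memory
#'
#' Convenience wrapper chaining score filter, aggregation and
#' classification with one set of parameters.
#'
#' @param evidence An [evidence_table()].
#' @param params A [filter_params()].
#' @param exclusions Bait-machinery accessions (see [clpp_exclusions()]).
#' @return A [classify_proteins()] result.
#' @examples
#' fx <- clpp_fixture()
#' cls <- trap_pipeline(fx$evidence, exclusions = clpp_exclusions())
#' final_lists(cls)$substrates$protein_id
#' @export
trap_pipeline <- function(evidence, params = filter_params(),
                          exclusions = character()) {
  evidence |>
    apply_score_filter(score_min = params$score_min) |>
    aggregate_evidence(params = params) |>
    classify_proteins(exclusions = exclusions)
}

#' Run the pipeline end-to-end from a configuration
#'
#' Drives the whole workflow from a run configuration and writes its
#' artifacts to disk: the classification TSV, a JSON summary (category
#' counts, final-list sizes, parameter echo, input provenance), a planted
#' truth/evaluation section when ground truth is available, and a plain
#' text log.
#'
#' The configuration is a named list (or a YAML file path) with:
#'
#' * exactly one input source:
#'   * `evidence:` path to an evidence TSV plus `design:` path to a design
#'     YAML, or
#'   * `simulate:` a block of [sim_params()] fields (plus optional `seed`),
#'     or
#'   * `fixture:` a block with optional `contaminants` / `sporadic`;
#' * optional `params:` block of [filter_params()] fields;
#' * optional `exclude:` character vector of accessions or path to a file
#'   of accessions, one per line (defaults to [clpp_exclusions()] for
#'   fixture input, empty otherwise);
#' * optional `annotations:` path to an annotation TSV.
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the classification, the summary list,
#'   the evaluation (or `NULL`), and the paths written.
#' @export
run_trap_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) trap_abort(sprintf("config not found: %s", config), "io")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) trap_abort("config must be a list or a YAML path", "config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      trap_abort(sprintf("stage '%s': %s", name, conditionMessage(e)), "pipeline")
    })
  }

  truth <- NULL
  if (!is.null(config$evidence)) {
    if (is.null(config$design)) trap_abort("evidence input needs a design", "config")
    design <- stage("read design", read_design(config$design))
    evidence <- stage("read evidence", read_evidence(config$evidence, design))
    source_desc <- list(type = "evidence", path = config$evidence)
    say("read %d evidence records from %s", nrow(evidence), config$evidence)
  } else if (!is.null(config$simulate)) {
    sim_cfg <- if (isTRUE(config$simulate)) list() else config$simulate
    sp <- stage("simulation parameters", do.call(sim_params, sim_cfg))
    sim <- stage("simulate", simulate_evidence(sp))
    evidence <- sim$evidence
    truth <- sim$truth
    source_desc <- list(type = "simulate", seed = sp$seed)
    say("simulated %d proteins (seed %d)", nrow(truth), sp$seed)
  } else if (!is.null(config$fixture)) {
    fb <- config$fixture
    if (isTRUE(fb)) fb <- list()
    fx <- stage("fixture", clpp_fixture(
      n_contaminants = fb$contaminants %||% 10,
      n_sporadic = fb$sporadic %||% 5
    ))
    evidence <- fx$evidence
    truth <- fx$truth
    source_desc <- list(type = "fixture")
    say("built reference fixture with %d proteins", nrow(truth))
  } else {
    trap_abort("no input source: config needs 'evidence', 'simulate' or 'fixture'",
               "config")
  }

  params <- stage("filter parameters",
                  do.call(filter_params, config$params %||% list()))
  exclusions <- config$exclude %||%
    (if (!is.null(config$fixture)) clpp_exclusions() else character())
  if (is.character(exclusions) && length(exclusions) == 1L && file.exists(exclusions)) {
    exclusions <- readr::read_lines(exclusions, progress = FALSE)
    exclusions <- exclusions[nzchar(trimws(exclusions))]
  }

  cls <- stage("classify", trap_pipeline(evidence, params, exclusions))
  lists <- stage("final lists", final_lists(cls))
  say("classified %d proteins", nrow(cls))

  if (!is.null(config$annotations)) {
    ann <- stage("annotate", read_annotations(config$annotations))
    cls_out <- stage("annotate", annotate_classification(cls, ann))
  } else {
    cls_out <- cls
  }

  eval_out <- if (!is.null(truth)) {
    stage("evaluate", evaluate_classification(cls, truth))
  }

  cls_path <- file.path(out_dir, "classification.tsv")
  stage("write classification", write_classification(cls_out, cls_path))
  if (!is.null(truth)) {
    stage("write truth", write_truth(truth, file.path(out_dir, "truth.tsv")))
  }

  counts <- as.list(table(cls$category))
  summary <- list(
    input = source_desc,
    n_proteins = nrow(cls),
    categories = counts,
    n_interactors = nrow(lists$interactors),
    n_substrates = nrow(lists$substrates),
    n_trap_enriched = nrow(lists$enriched),
    params = unclass(params),
    exclusions = as.list(exclusions)
  )
  if (!is.null(eval_out)) {
    summary$evaluation <- list(
      precision = setNames(as.list(eval_out$metrics$precision), eval_out$metrics$role),
      recall = setNames(as.list(eval_out$metrics$recall), eval_out$metrics$role)
    )
  }
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  say("wrote %s and %s", cls_path, summary_path)
  writeLines(log_lines, log_path)

  invisible(list(
    classification = cls_out, summary = summary, evaluation = eval_out,
    paths = list(classification = cls_path, summary = summary_path, log = log_path)
  ))
}
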