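fixture_classification <- function(...) {
  fx <- clpp_fixture(...)
  trap_pipeline(fx$evidence, exclusions = clpp_exclusions())
}

test_that("known proteins from the trapping assay classify as published", {
  cls <- fixture_classification()
  row <- function(id) cls[cls$protein_id == id, ]

  # citrate synthase homologue: shared, trap-enriched (EF 420/220)
  cs <- row("Pa_3_6780")
  expect_equal(as.character(cs$category), "SHARED_INTERACTOR")
  expect_true(cs$trap_enriched)
  expect_equal(cs$ef_trap_vs_ref, 420 / 220)
  expect_equal(cs$mean_unique_reference, 22 / 3)  # prints as 7.3
  expect_equal(cs$mean_unique_trap, 14)

  # NDUFS1 homologue: trap-exclusive substrate
  ndufs1 <- row("Pa_3_4870")
  expect_equal(as.character(ndufs1$category), "TRAP_SPECIFIC")
  expect_true(ndufs1$trap_exclusive)
  expect_true(ndufs1$substrate)
  expect_true(is.na(ndufs1$ef_trap_vs_ref))
  expect_equal(ndufs1$mean_unique_trap, 21)

  # CLPX chaperone partner: trap-specific but excluded bait machinery
  clpx <- row("Pa_6_5590")
  expect_equal(as.character(clpx$category), "TRAP_SPECIFIC")
  expect_false(clpx$substrate)

  # DLST homologue: present with both baits, EF 3.8 > 3 -> trap-specific
  dlst <- row("Pa_5_5370")
  expect_equal(as.character(dlst$category), "TRAP_SPECIFIC")
  expect_false(dlst$trap_exclusive)
  expect_true(dlst$substrate)
  expect_equal(dlst$ef_trap_vs_ref, 3.8)  # printed enrichment factor

  # audit trail covers every cascade step
  expect_true(all(purrr::map_int(cls$audit, length) >= 4L))
})

test_that("background rescue requires an enrichment factor above the threshold", {
  make_cls <- function(trap_counts) {
    ev <- make_evidence(
      ev_rows("Pa_X", "ctrl", c(5, 5, 5)),
      ev_rows("Pa_X", "wt", c(10, 10, 10)),
      ev_rows("Pa_X", "trap", trap_counts)
    )
    trap_pipeline(ev)
  }
  # EF(bait vs control) = 2 for both baits: not rescued, background
  expect_equal(as.character(make_cls(c(10, 10, 10))$category), "BACKGROUND")
  # trap EF = 4 > 3: rescued into the trap candidate set only
  rescued <- make_cls(c(20, 20, 20))
  expect_equal(as.character(rescued$category), "TRAP_SPECIFIC")
  expect_true(rescued$trap_exclusive)
})

test_that("single-candidate branches and the floor behave per cascade", {
  # reference-only candidate with ample evidence: wt-preferential
  wtp <- trap_pipeline(make_evidence(ev_rows("Pa_W", "wt", c(8, 8, 8))))
  expect_equal(as.character(wtp$category), "WT_PREFERENTIAL")

  # shared candidate failing the >1 average-unique-peptide floor in one bait
  low <- trap_pipeline(make_evidence(
    ev_rows("Pa_L", "wt", c(2, 2, 0), unique = c(1L, 1L, 0L)),
    ev_rows("Pa_L", "trap", c(4, 4, 4), unique = c(2L, 2L, 2L))
  ))
  expect_equal(as.character(low$category), "LOW_EVIDENCE")
  expect_false(low$substrate)

  # detected once anywhere: not reproducible
  sporadic <- trap_pipeline(make_evidence(ev_rows("Pa_S", "trap", c(9, 0, 0))))
  expect_equal(as.character(sporadic$category), "NOT_REPRODUCIBLE")
})

test_that("classification partitions proteins and is order-invariant", {
  for (seed in c(7, 19)) {
    set.seed(seed)
    ev <- random_evidence(40)
    cls <- trap_pipeline(ev)

    observed <- unique(apply_score_filter(ev, 40)$protein_id)
    expect_setequal(cls$protein_id, observed)
    expect_equal(anyDuplicated(cls$protein_id), 0L)
    expect_false(anyNA(cls$category))

    # flags stay inside their categories
    expect_true(all(cls$category[cls$substrate] == "TRAP_SPECIFIC"))
    expect_true(all(cls$category[cls$trap_enriched %in% TRUE] == "SHARED_INTERACTOR"))
    expect_true(all(is.na(cls$ef_trap_vs_ref[cls$trap_exclusive %in% TRUE])))

    shuffled <- as.data.frame(ev)[sample(nrow(ev)), ]
    cls2 <- trap_pipeline(evidence_table(shuffled, attr(ev, "design")))
    expect_equal(as.data.frame(cls), as.data.frame(cls2))
  }
})

test_that("removing the control empties BACKGROUND without touching TRAP_SPECIFIC", {
  set.seed(23)
  ev <- random_evidence(40)
  cls_full <- trap_pipeline(ev)

  design <- attr(ev, "design")
  ctrl <- design$sample_id[design$role == "control"]
  no_ctrl <- evidence_table(as.data.frame(ev)[ev$sample_id != ctrl, ], design)
  cls_nc <- trap_pipeline(no_ctrl)

  expect_equal(sum(cls_nc$category == "BACKGROUND"), 0L)
  # trap-specific calls that did not depend on the control stay put (a
  # control-tainted protein rescued into the trap set only may legitimately
  # become shared once the control no longer suppresses its reference presence)
  agg <- aggregate_evidence(apply_score_filter(ev, 40))
  ctrl_present <- agg$protein_id[agg$sample_id == ctrl & agg$present]
  ts <- function(x) x$protein_id[x$category == "TRAP_SPECIFIC"]
  expect_true(all(setdiff(ts(cls_full), ctrl_present) %in% ts(cls_nc)))
})

test_that("threshold monotonicity holds for specific and rescue factors", {
  for (seed in c(5, 77)) {
    set.seed(seed)
    ev <- random_evidence(40)
    n_cat <- function(params, cat) {
      cls <- trap_pipeline(ev, params = params)
      sum(cls$category == cat)
    }
    expect_lte(n_cat(filter_params(specific_factor = 5), "TRAP_SPECIFIC"),
               n_cat(filter_params(specific_factor = 3), "TRAP_SPECIFIC"))
    expect_gte(n_cat(filter_params(rescue_factor = 6), "BACKGROUND"),
               n_cat(filter_params(rescue_factor = 3), "BACKGROUND"))
  }
})

test_that("final lists honour categories, flags and ordering", {
  cls <- fixture_classification()
  lists <- final_lists(cls)
  expect_equal(nrow(lists$interactors), 47L)
  expect_equal(nrow(lists$substrates), 19L)
  expect_equal(nrow(lists$enriched), 12L)
  expect_false("Pa_6_5590" %in% lists$substrates$protein_id)
  expect_false(any(c("Pa_synthetic_MCCC2", "Pa_synthetic_ccp1") %in%
                     unlist(purrr::map(lists, "protein_id"))))
  # descending trap evidence, ties by accession
  s <- lists$substrates
  expect_true(all(diff(s$mean_unique_trap) <= 1e-12))
  expect_equal(s$protein_id[1], "Pa_3_4870")

  empty <- final_lists(trap_pipeline(make_evidence(ev_rows("Pa_X", "ctrl", c(5, 5, 5)))))
  expect_equal(purrr::map_int(empty, nrow), c(interactors = 0L, substrates = 0L, enriched = 0L))
})

test_that("classification tables round-trip through TSV with counts intact", {
  cls <- fixture_classification()
  path <- tempfile(fileext = ".tsv")
  write_classification(cls, path)
  back <- read_classification(path)
  expect_equal(nrow(back), nrow(cls))
  expect_equal(table(back$category), table(cls$category))
  expect_equal(sum(back$substrate), sum(cls$substrate))

  # header-only file for an empty classification
  empty <- trap_pipeline(make_evidence(ev_rows("Pa_X", "wt", c(1, 0, 0), score = 10)))
  expect_equal(nrow(empty), 0L)
  p2 <- tempfile(fileext = ".tsv")
  write_classification(empty, p2)
  expect_equal(length(readr::read_lines(p2)), 1L)
})
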