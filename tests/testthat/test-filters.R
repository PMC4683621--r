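test_that("the score threshold is inclusive and score_min = 0 is the identity", {
  ev <- make_evidence(
    ev_rows("Pa_low", "wt", c(3, 0, 0), score = 39),
    ev_rows("Pa_edge", "wt", c(3, 0, 0), score = 40),
    ev_rows("Pa_high", "wt", c(3, 0, 0), score = 41)
  )
  kept <- apply_score_filter(ev, 40)
  expect_setequal(kept$protein_id, c("Pa_edge", "Pa_high"))
  expect_equal(as.data.frame(apply_score_filter(ev, 0)), as.data.frame(ev))
})

test_that("aggregation divides by the design replicate count, zeros included", {
  ev <- make_evidence(ev_rows("Pa_A", "wt", c(2, 1, 1) * 2, unique = c(2L, 1L, 1L)))
  agg <- aggregate_evidence(ev)
  expect_equal(agg$mean_unique_peptides, 4 / 3)
  expect_equal(round(agg$mean_unique_peptides, 1), 1.3)  # display convention
  expect_equal(agg$total_spectral, 8L)
  expect_equal(agg$n_detected, 3L)
})

test_that("the reproducibility call needs min_replicates detections in any replicates", {
  two_of_three <- make_evidence(ev_rows("Pa_A", "wt", c(3, 0, 2)))
  one_of_three <- make_evidence(ev_rows("Pa_B", "wt", c(0, 5, 0)))
  expect_true(aggregate_evidence(two_of_three)$present)
  expect_false(aggregate_evidence(one_of_three)$present)
})

test_that("enrichment factors are spectral-count ratios, undefined on zero denominators", {
  ev <- make_evidence(
    ev_rows("Pa_A", "trap", c(12, 12, 12)),
    ev_rows("Pa_A", "wt", c(3, 3, 3)),
    ev_rows("Pa_B", "trap", c(5, 5, 5))
  )
  agg <- aggregate_evidence(ev)
  expect_equal(enrichment_factor(agg, "Pa_A", "trap", "wt"), 4.0)
  expect_equal(enrichment_factor(agg, "Pa_A", "wt", "trap") *
                 enrichment_factor(agg, "Pa_A", "trap", "wt"), 1.0)
  expect_true(is.na(enrichment_factor(agg, "Pa_B", "trap", "wt")))
  expect_error(enrichment_factor(agg, "Pa_missing", "trap", "wt"), "unknown protein")
  expect_error(enrichment_factor(agg, "Pa_A", "trap", "elsewhere"), "unknown sample")
})

test_that("raising thresholds is monotone and aggregation is order-invariant", {
  for (seed in c(11, 42, 303)) {
    set.seed(seed)
    ev <- random_evidence(30)

    detected <- function(x) paste(x$sample_id, x$replicate_id, x$protein_id)
    loose <- apply_score_filter(ev, 40)
    strict <- apply_score_filter(ev, 80)
    expect_true(all(detected(strict) %in% detected(loose)))

    present_pairs <- function(min_replicates) {
      agg <- aggregate_evidence(loose, filter_params(min_replicates = min_replicates))
      with(agg[agg$present, ], paste(protein_id, sample_id))
    }
    expect_true(all(present_pairs(3) %in% present_pairs(2)))

    # permutation of record order never changes aggregates
    agg <- aggregate_evidence(loose)
    shuffled <- as.data.frame(loose)[sample(nrow(loose)), ]
    agg2 <- aggregate_evidence(evidence_table(shuffled, attr(ev, "design")))
    expect_equal(as.data.frame(agg), as.data.frame(agg2))

    # mean times replicate count recovers an integer peptide sum
    expect_true(all(abs(agg$mean_unique_peptides * agg$n_replicates -
                          round(agg$mean_unique_peptides * agg$n_replicates)) < 1e-9))
  }
})

test_that("filter parameters validate their invariants", {
  expect_error(filter_params(min_replicates = 0), "min_replicates")
  expect_error(filter_params(rescue_factor = -1), "positive")
  expect_error(filter_params(enriched_factor = 4, specific_factor = 3), "exceed")
})
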