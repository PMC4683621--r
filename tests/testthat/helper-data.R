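# Small builders shared across tests. Counts are chosen per test; nothing
# here depends on the classifier under test.

test_design <- function(n_replicates = 3) {
  study_design("ctrl", "wt", "trap", n_replicates = n_replicates)
}

# One protein's evidence rows in one sample from a vector of per-replicate
# spectral counts (unique peptides default to ceiling(spectral / 2)).
ev_rows <- function(protein, sample, spectral, unique = NULL, score = 100) {
  spectral <- as.integer(spectral)
  if (is.null(unique)) unique <- as.integer(ceiling(spectral / 2))
  det <- spectral >= 1L
  tibble::tibble(
    sample_id = sample,
    replicate_id = seq_along(spectral)[det],
    protein_id = protein,
    score = score,
    unique_peptides = unique[det],
    spectral_count = spectral[det]
  )
}

make_evidence <- function(..., design = test_design()) {
  evidence_table(dplyr::bind_rows(...), design)
}

# A randomized evidence table for property tests: n proteins, arbitrary
# detection patterns, valid unique/spectral pairs.
random_evidence <- function(n = 40, design = test_design()) {
  rows <- list()
  for (i in seq_len(n)) {
    id <- sprintf("P%03d", i)
    for (s in design$sample_id) {
      spectral <- rpois(3, lambda = sample(c(0, 1, 4, 15), 1))
      if (all(spectral == 0)) next
      unique <- pmin(spectral, pmax(1L, rpois(3, spectral / 2)))
      unique[spectral == 0] <- 0L
      score <- round(runif(3, 20, 120), 1)
      rows <- c(rows, list(ev_rows(id, s, spectral, unique, score = score[spectral >= 1])))
    }
  }
  evidence_table(dplyr::bind_rows(rows), design)
}
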