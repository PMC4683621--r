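# Independent brute-force classifier used as an oracle. Written directly as
# literal set operations over base-R vectors (membership, union, setdiff on
# protein-id sets), sharing no code with the package implementation.

oracle_classify <- function(evidence, design, params, exclusions = character()) {
  rec <- as.data.frame(evidence)
  rec <- rec[rec$score >= params$score_min & rec$spectral_count >= 1, ]

  ctrl <- design$sample_id[design$role == "control"]
  ref  <- design$sample_id[design$role == "bait_reference"]
  trap <- design$sample_id[design$role == "bait_trap"]
  nrep <- setNames(design$n_replicates, design$sample_id)

  # universe: proteins with at least one detection surviving the score filter
  observed <- sort(unique(rec$protein_id))

  key <- paste(rec$protein_id, rec$sample_id, sep = "\r")
  det_tab <- table(key)
  tot_tab <- tapply(rec$spectral_count, key, sum)
  upt_tab <- tapply(rec$unique_peptides, key, sum)
  look <- function(tab, p, s) {
    v <- tab[paste(p, s, sep = "\r")]
    v[is.na(v)] <- 0
    as.numeric(v)
  }
  detections <- function(p, s) look(det_tab, p, s)
  total <- function(p, s) look(tot_tab, p, s)
  mean_u <- function(p, s) look(upt_tab, p, s) / nrep[[s]]
  present_set <- function(s) observed[detections(observed, s) >= params$min_replicates]

  P_ctrl <- present_set(ctrl)
  P_ref  <- present_set(ref)
  P_trap <- present_set(trap)

  # (1) reproducibility
  NOT_REPRODUCIBLE <- setdiff(observed, union(P_ctrl, union(P_ref, P_trap)))

  # (2) background subtraction with per-bait rescue
  tainted <- P_ctrl
  rescued_ref <- tainted[total(tainted, ctrl) > 0 &
                           total(tainted, ref) / total(tainted, ctrl) > params$rescue_factor]
  rescued_trap <- tainted[total(tainted, ctrl) > 0 &
                            total(tainted, trap) / total(tainted, ctrl) > params$rescue_factor]

  # (3) candidate sets
  cand_ref  <- union(setdiff(P_ref, tainted), intersect(P_ref, rescued_ref))
  cand_trap <- union(setdiff(P_trap, tainted), intersect(P_trap, rescued_trap))
  BACKGROUND <- setdiff(tainted, union(cand_ref, cand_trap))

  # (4)-(6) comparison of the candidate sets
  both <- intersect(cand_ref, cand_trap)
  ts_by_ef <- both[total(both, ref) > 0 &
                     total(both, trap) / total(both, ref) > params$specific_factor]
  TRAP_SPECIFIC <- union(setdiff(cand_trap, cand_ref), ts_by_ef)
  SHARED <- setdiff(both, ts_by_ef)
  WT_PREFERENTIAL <- setdiff(cand_ref, cand_trap)

  # (7) unique-peptide floor (shared: both baits; trap-specific: trap sample;
  # wt-preferential proteins keep their category)
  f <- params$min_avg_unique_peptides
  low_shared <- SHARED[!(mean_u(SHARED, ref) > f & mean_u(SHARED, trap) > f)]
  low_ts <- TRAP_SPECIFIC[!(mean_u(TRAP_SPECIFIC, trap) > f)]
  LOW_EVIDENCE <- union(low_shared, low_ts)
  SHARED <- setdiff(SHARED, LOW_EVIDENCE)
  TRAP_SPECIFIC <- setdiff(TRAP_SPECIFIC, LOW_EVIDENCE)

  # (8) substrate call
  substrates <- setdiff(TRAP_SPECIFIC, exclusions)

  category <- setNames(rep(NA_character_, length(observed)), observed)
  category[NOT_REPRODUCIBLE] <- "NOT_REPRODUCIBLE"
  category[BACKGROUND] <- "BACKGROUND"
  category[SHARED] <- "SHARED_INTERACTOR"
  category[TRAP_SPECIFIC] <- "TRAP_SPECIFIC"
  category[WT_PREFERENTIAL] <- "WT_PREFERENTIAL"
  category[LOW_EVIDENCE] <- "LOW_EVIDENCE"

  data.frame(
    protein_id = observed,
    category = unname(category[observed]),
    substrate = observed %in% substrates,
    trap_exclusive = ifelse(unname(category[observed]) == "TRAP_SPECIFIC",
                            !(observed %in% cand_ref), NA),
    row.names = NULL
  )
}
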