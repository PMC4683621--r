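#' Parameters of the evidence-count simulator
#'
#' The simulator plants proteins with known roles and draws per-replicate
#' spectral counts from a Poisson model around a log-normal per-protein
#' baseline abundance:
#'
#' * each protein gets a baseline expected spectral count
#'   `lambda ~ logNormal(abundance_meanlog, abundance_sdlog)`
#'   (defaults `log(20)` and `0.8`, giving per-replicate counts roughly in
#'   the 1–30 range seen in real trapping experiments);
#' * the expectation in a given sample is `lambda` times a role-and-sample
#'   multiplier: contaminants appear in all samples, interactors with both
#'   baits, substrates with the trap bait (and at `substrate_ref_fraction`
#'   of that with the reference bait), wild-type partners with the
#'   reference bait only, and sporadic proteins in exactly one random
#'   replicate of one random sample;
#' * spectral counts are Poisson draws, zeroed with probability `dropout`;
#' * unique peptides are `max(1, Binomial(spectral_count, peptide_yield))`
#'   for detected records;
#' * scores follow `score_a + score_b * log2(1 + spectral_count)` plus
#'   Gaussian noise (`score_sd`), truncated at 0.
#'
#' @param n_contaminants,n_interactors,n_substrates,n_wt_partners,n_sporadic
#'   Number of proteins planted per role (defaults 50/20/10/2/5).
#' @param abundance_meanlog,abundance_sdlog Log-normal location and scale of
#'   the per-protein baseline `lambda`.
#' @param substrate_ref_fraction Expected reference-bait counts for
#'   substrate proteins, as a fraction of their trap counts (0 =
#'   trap-exclusive; 0.25 plants an enrichment factor of 4).
#' @param interactor_control_fraction Expected control-sample counts for
#'   interactor and substrate proteins, as a fraction of their bait counts.
#' @param dropout Per-replicate probability that a detected protein yields
#'   no evidence.
#' @param peptide_yield Expected unique peptides per spectrum, in (0, 1].
#' @param score_a,score_b,score_sd Score-model intercept, slope and noise.
#' @param seed Default random seed used by [simulate_evidence()].
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_contaminants = 50,
                       n_interactors = 20,
                       n_substrates = 10,
                       n_wt_partners = 2,
                       n_sporadic = 5,
                       abundance_meanlog = log(20),
                       abundance_sdlog = 0.8,
                       substrate_ref_fraction = 0,
                       interactor_control_fraction = 0,
                       dropout = 0,
                       peptide_yield = 0.5,
                       score_a = 30,
                       score_b = 15,
                       score_sd = 5,
                       seed = 1L) {
  p <- list(
    n_contaminants = as.integer(n_contaminants),
    n_interactors = as.integer(n_interactors),
    n_substrates = as.integer(n_substrates),
    n_wt_partners = as.integer(n_wt_partners),
    n_sporadic = as.integer(n_sporadic),
    abundance_meanlog = as.numeric(abundance_meanlog),
    abundance_sdlog = as.numeric(abundance_sdlog),
    substrate_ref_fraction = as.numeric(substrate_ref_fraction),
    interactor_control_fraction = as.numeric(interactor_control_fraction),
    dropout = as.numeric(dropout),
    peptide_yield = as.numeric(peptide_yield),
    score_a = as.numeric(score_a),
    score_b = as.numeric(score_b),
    score_sd = as.numeric(score_sd),
    seed = as.integer(seed)
  )
  counts <- unlist(p[1:5])
  if (anyNA(unlist(p))) trap_abort("simulation parameters must be numeric", "params")
  if (any(counts < 0L)) trap_abort("role counts must be >= 0", "params")
  if (p$abundance_sdlog <= 0) trap_abort("abundance_sdlog must be > 0", "params")
  if (p$substrate_ref_fraction < 0 || p$substrate_ref_fraction > 1 ||
      p$interactor_control_fraction < 0 || p$interactor_control_fraction > 1) {
    trap_abort("fractions must lie in [0, 1]", "params")
  }
  if (p$dropout < 0 || p$dropout >= 1) trap_abort("dropout must lie in [0, 1)", "params")
  if (p$peptide_yield <= 0 || p$peptide_yield > 1) {
    trap_abort("peptide_yield must lie in (0, 1]", "params")
  }
  structure(p, class = "sim_params")
}

#' Simulate an evidence table with planted ground truth
#'
#' Draws a full three-arm experiment under the count model described in
#' [sim_params()]. The same seed always yields an identical table.
#'
#' @param params A [sim_params()].
#' @param design A [study_design()] (default: samples `ctrl`/`wt`/`trap`,
#'   three replicates each).
#' @param seed Random seed; defaults to `params$seed`.
#' @return A list with `evidence` (an [evidence_table()]) and `truth` (a
#'   tibble `protein_id`, `role` covering every generated protein).
#' @examples
#' sim <- simulate_evidence(sim_params(seed = 7))
#' dplyr::count(sim$truth, role)
#' @export
simulate_evidence <- function(params = sim_params(),
                              design = study_design("ctrl", "wt", "trap"),
                              seed = params$seed) {
  stopifnot(inherits(params, "sim_params"), inherits(design, "study_design"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  roles <- rep(planted_roles,
               c(params$n_contaminants, params$n_interactors, params$n_substrates,
                 params$n_wt_partners, params$n_sporadic))
  n <- length(roles)
  truth <- tibble(
    protein_id = sprintf("SIM_%s_%03d", roles,
                         as.integer(stats::ave(seq_len(n), roles, FUN = seq_along))),
    role = roles
  )
  if (n == 0L) {
    return(list(evidence = evidence_table(tibble(
      sample_id = character(), replicate_id = integer(), protein_id = character(),
      score = numeric(), unique_peptides = integer(), spectral_count = integer()
    ), design), truth = truth))
  }
  lambda <- rlnorm(n, params$abundance_meanlog, params$abundance_sdlog)

  s_ctrl <- sample_for_role(design, "control")
  s_ref  <- sample_for_role(design, "bait_reference")
  s_trap <- sample_for_role(design, "bait_trap")
  mult <- function(role, sample) {
    switch(role,
      CONTAMINANT = 1,
      INTERACTOR = if (sample == s_ctrl) params$interactor_control_fraction else 1,
      SUBSTRATE = if (sample == s_ctrl) params$interactor_control_fraction
        else if (sample == s_ref) params$substrate_ref_fraction else 1,
      WT_PARTNER = as.numeric(sample == s_ref),
      SPORADIC = 0
    )
  }

  rows <- vector("list", n * nrow(design))
  k <- 0L
  for (i in seq_len(n)) {
    role <- roles[i]
    sporadic_slot <- if (role == "SPORADIC") {
      smp <- design$sample_id[sample.int(nrow(design), 1L)]
      rpl <- sample.int(design$n_replicates[design$sample_id == smp], 1L)
      c(smp, rpl)
    }
    for (s in design$sample_id) {
      nrep <- design$n_replicates[design$sample_id == s]
      if (role == "SPORADIC") {
        mu <- rep(0, nrep)
        if (!is.null(sporadic_slot) && sporadic_slot[1] == s) {
          mu[as.integer(sporadic_slot[2])] <- lambda[i]
        }
      } else {
        mu <- rep(lambda[i] * mult(role, s), nrep)
      }
      sc <- rpois(nrep, mu)
      if (params$dropout > 0) {
        sc[stats::runif(nrep) < params$dropout] <- 0L
      }
      det <- sc >= 1L
      if (!any(det)) next
      up <- pmax(1L, rbinom(sum(det), sc[det], params$peptide_yield))
      score <- pmax(0, params$score_a + params$score_b * log2(1 + sc[det]) +
                      rnorm(sum(det), 0, params$score_sd))
      k <- k + 1L
      rows[[k]] <- tibble(
        sample_id = s, replicate_id = which(det),
        protein_id = truth$protein_id[i],
        score = score, unique_peptides = up, spectral_count = sc[det]
      )
    }
  }
  ev <- evidence_table(bind_rows(rows[seq_len(k)]), design)
  list(evidence = ev, truth = truth)
}
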