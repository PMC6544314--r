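# Small fixtures built in code, shared across test files.

# Minimal valid metadata row block for hand-built matrices.
toy_metadata <- function(sample_ids, tissue = "larva", stage = NULL,
                         colony = NULL) {
  n <- length(sample_ids)
  data.frame(
    sample_id = sample_ids,
    tissue = tissue,
    nurse_type = if (tissue == "larva") "not_applicable" else
      "stage_specific",
    stage = stage %||% STAGES[seq_len(n)],
    colony = colony %||% paste0("r", seq_len(n)),
    caste = if (tissue == "larva") "worker" else "not_applicable",
    queen_present = TRUE,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One larval sample per stage with prescribed per-gene stage values.
toy_expr_by_stage <- function(stage_values) {
  v <- as.matrix(stage_values)
  colnames(v) <- paste0("s_", STAGES)
  if (is.null(rownames(v))) rownames(v) <- paste0("g", seq_len(nrow(v)))
  expression_matrix(v, toy_metadata(colnames(v), stage = STAGES,
                                    colony = "r1"))
}

# Desk-scale default simulation shared by several tests.
small_sim <- function(seed = 1, ...) {
  simulate_experiment(sim_config(n_genes_per_tissue = 200,
                                 n_colonies_per_stage = 4,
                                 n_social_regulators = 8,
                                 n_within_regulators = 8,
                                 targets_per_regulator = 5,
                                 seed = seed, ...))
}
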