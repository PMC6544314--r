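# Synthetic nurse/larva experiment generator with planted ground truth.
#
# Emulates the study design: five larval stages, a replicate block of
# colonies per stage, each colony sampled once and contributing one pooled
# larval sample (whole body, worker-destined), one stage-specific nurse head
# and abdomen, and one random-nurse head and abdomen. Planted structure is
# recoverable by every pipeline stage: co-expression module profiles shared
# (parallel or anti-parallel) between larvae and stage-specific nurses but
# stage-shuffled in random nurses, cross-tissue regulator->target edges
# injected as colony-level covariation, and annotation tables whose
# constraint/age/secretion columns correlate with planted sociality.

#' Simulation configuration
#'
#' Defaults mirror the study conditions: 5 stages x 6 colonies per stage,
#' pooled samples modelled as a single noisy draw per colony, FPKM-scale
#' baselines log-normal around ~55 FPKM, and planted effect sizes strong
#' enough to be recoverable at the study's sample sizes.
#'
#' @param n_genes_per_tissue Number of genes (shared across tissues).
#' @param n_colonies_per_stage Colonies (replicate blocks) per stage.
#' @param baseline_log_mean,baseline_log_sd Natural-log FPKM baseline
#'   distribution.
#' @param profile_noise_sd Per-sample log2 noise around the planted profile
#'   (absorbs pooling variance).
#' @param planted_module_fraction Fraction of genes following a planted
#'   (non-flat) module profile.
#' @param n_planted_modules Number of distinct module profiles the planted
#'   genes are spread over. Real developmental series concentrate
#'   co-expressed genes in a handful of dominant trajectories, so planted
#'   genes form coherent blocks rather than a uniform scatter.
#' @param antiparallel_fraction Probability that a planted gene's nurse
#'   profile is the negation of its larval profile, per nurse tissue.
#' @param n_social_regulators Nurse-head genes with planted cross-tissue
#'   (social) edges onto larval targets.
#' @param n_within_regulators Larval genes with planted within-tissue edges.
#' @param targets_per_regulator Planted targets per regulator.
#' @param regulator_effect_size Log2 coefficient propagating a regulator's
#'   colony-level deviation into its targets.
#' @param pool_size Nurses pooled per random-nurse sample; each pooled
#'   nurse expresses the profile at her own uniformly drawn fed stage, so
#'   averaging flattens the stage trend as in the pooled study design.
#' @param meta_noise_sd Additional independent measurement noise (log2).
#' @param rho_sociality_constraint Target Spearman correlation between the
#'   latent sociality score and the constraint annotation.
#' @param seed Integer master seed; a fixed seed reproduces every output
#'   bitwise.
#' @return Validated list of class `SimConfig`.
#' @export
sim_config <- function(n_genes_per_tissue = 1000,
                       n_colonies_per_stage = 6,
                       baseline_log_mean = 4,
                       baseline_log_sd = 1,
                       profile_noise_sd = 0.25,
                       planted_module_fraction = 0.5,
                       n_planted_modules = 8,
                       antiparallel_fraction = 0.3,
                       n_social_regulators = 20,
                       n_within_regulators = 20,
                       targets_per_regulator = 8,
                       regulator_effect_size = 1,
                       pool_size = 10,
                       meta_noise_sd = 0.1,
                       rho_sociality_constraint = -0.2,
                       seed = 1) {
  cfg <- list(n_genes_per_tissue = n_genes_per_tissue,
              n_colonies_per_stage = n_colonies_per_stage,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              profile_noise_sd = profile_noise_sd,
              planted_module_fraction = planted_module_fraction,
              n_planted_modules = n_planted_modules,
              antiparallel_fraction = antiparallel_fraction,
              n_social_regulators = n_social_regulators,
              n_within_regulators = n_within_regulators,
              targets_per_regulator = targets_per_regulator,
              regulator_effect_size = regulator_effect_size,
              pool_size = pool_size,
              meta_noise_sd = meta_noise_sd,
              rho_sociality_constraint = rho_sociality_constraint,
              seed = seed)
  stopifnot(cfg$n_genes_per_tissue >= 1)
  if (cfg$n_colonies_per_stage < 1)
    stop("degenerate config: need >= 1 colony per stage")
  stopifnot(cfg$n_planted_modules >= 1, cfg$pool_size >= 1)
  for (f in c("planted_module_fraction", "antiparallel_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must be in [0, 1]")
  for (s in c("profile_noise_sd", "baseline_log_sd", "meta_noise_sd"))
    if (cfg[[s]] < 0) stop(s, " must be >= 0")
  if (abs(cfg$rho_sociality_constraint) > 1)
    stop("rho_sociality_constraint must be in [-1, 1]")
  n_free <- cfg$n_genes_per_tissue -
    round(cfg$planted_module_fraction * cfg$n_genes_per_tissue)
  if (cfg$n_social_regulators + cfg$n_within_regulators > n_free)
    stop("not enough non-planted genes to host the requested regulators")
  class(cfg) <- c("SimConfig", "list")
  cfg
}

#' Simulate a nurse/larva expression experiment with planted structure
#'
#' Emits one abundance table over all strata (larva; stage-specific nurse
#' head/abdomen; random-nurse head/abdomen), one sample of each per colony.
#' A planted fraction of genes follows a randomly chosen non-flat module
#' profile; abundance is `baseline * 2^(profile[s] + noise)`. For planted
#' genes, the stage-specific nurse profile equals the larval profile
#' (parallel) or its negation (anti-parallel). Random-nurse samples are
#' modelled as pools of `pool_size` nurses, each expressing the profile at
#' her own uniformly drawn fed stage (averaged in abundance space), so no
#' stage trend survives. Social regulator->target effects are injected at the colony
#' level: each target's larval log2 abundance gains `coefficient *` (the
#' regulator's realised colony deviation), which is exactly the covariation
#' visible to meta-sample network inference.
#'
#' @param config `SimConfig` from [sim_config()].
#' @return List with `expr` (an [expression_matrix()]) and `truth` (class
#'   `GroundTruth`: per-gene planted module/relations/regulator flags, the
#'   planted edge list, and the config).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_genes_per_tissue
  k <- config$n_colonies_per_stage
  genes <- sprintf("g%04d", seq_len(n))
  modules <- enumerate_module_profiles()
  nonflat <- modules[rownames(modules) != FLAT_MODULE, , drop = FALSE]

  n_planted <- round(config$planted_module_fraction * n)
  planted_idx <- sort(sample.int(n, n_planted))
  prof <- matrix(0, n, 5, dimnames = list(genes, STAGES))
  planted_module <- rep(NA_character_, n)
  if (n_planted > 0) {
    # planted trajectories emulate the dominant developmental programmes:
    # multi-fold changes across larval growth (dynamic range >= 2 log2
    # units); shallow oscillatory shapes are left to the noise background
    strong <- which(apply(nonflat, 1, function(v) diff(range(v))) >= 2)
    block <- sample(strong, min(config$n_planted_modules, length(strong)))
    pick <- sample(block, n_planted, replace = TRUE)
    prof[planted_idx, ] <- nonflat[pick, , drop = FALSE]
    planted_module[planted_idx] <- rownames(nonflat)[pick]
  }
  rel_head <- rel_abd <- rep(NA_real_, n)
  rel_head[planted_idx] <-
    ifelse(stats::runif(n_planted) < config$antiparallel_fraction, -1, 1)
  rel_abd[planted_idx] <-
    ifelse(stats::runif(n_planted) < config$antiparallel_fraction, -1, 1)

  free_idx <- setdiff(seq_len(n), planted_idx)
  reg_idx <- sample(free_idx,
                    config$n_social_regulators + config$n_within_regulators)
  social_idx <- reg_idx[seq_len(config$n_social_regulators)]
  within_idx <- setdiff(reg_idx, social_idx)
  # planted edges target non-planted genes so the module and edge
  # structures stay disjoint and each is individually recoverable
  target_pool <- setdiff(free_idx, reg_idx)
  if (length(target_pool) < config$targets_per_regulator &&
      length(reg_idx) > 0)
    stop("not enough non-planted genes to host regulator targets")
  edges <- list()
  for (r in social_idx) {
    tg <- sample(target_pool, config$targets_per_regulator)
    edges[[length(edges) + 1L]] <- data.frame(
      source_gene = genes[r], target_gene = genes[tg],
      source_tissue = "nurse_head", target_tissue = "larva",
      coefficient = config$regulator_effect_size, stringsAsFactors = FALSE)
  }
  for (w in within_idx) {
    tg <- sample(target_pool, config$targets_per_regulator)
    edges[[length(edges) + 1L]] <- data.frame(
      source_gene = genes[w], target_gene = genes[tg],
      source_tissue = "larva", target_tissue = "larva",
      coefficient = config$regulator_effect_size, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source_gene = character(), target_gene = character(),
               source_tissue = character(), target_tissue = character(),
               coefficient = numeric(), stringsAsFactors = FALSE)

  baseline <- exp(stats::rnorm(n, config$baseline_log_mean,
                               config$baseline_log_sd))

  n_col <- 5L * k
  colony_stage <- rep(STAGES, each = k)
  colony_rep <- rep(sprintf("r%d", seq_len(k)), times = 5L)
  queen <- rep(FALSE, n_col)
  queen[sample.int(n_col, n_col %/% 2L)] <- TRUE
  stage_of <- match(colony_stage, STAGES)

  noise <- function() matrix(stats::rnorm(n * n_col, 0,
                                          config$profile_noise_sd), n, n_col)
  meta <- function() matrix(stats::rnorm(n * n_col, 0,
                                         config$meta_noise_sd), n, n_col)
  E_larva <- noise(); E_head <- noise(); E_abd <- noise()

  rel0 <- function(r) ifelse(is.na(r), 1, r)
  L_larva <- prof[, stage_of, drop = FALSE] + E_larva
  L_head <- rel0(rel_head) * prof[, stage_of, drop = FALSE] + E_head
  L_abd <- rel0(rel_abd) * prof[, stage_of, drop = FALSE] + E_abd
  # random-nurse samples: abundance-space mean over the pooled nurses,
  # each expressing the profile at a uniformly drawn fed stage. Stage
  # draws are independent per gene, matching the gene-independence the
  # stage-permutation null assumes; no stage trend survives the average.
  pooled <- function(rel) {
    acc <- matrix(0, n, n_col)
    for (i in seq_len(config$pool_size)) {
      s_i <- matrix(sample.int(5L, n * n_col, replace = TRUE), n, n_col)
      p_i <- matrix(prof[cbind(rep(seq_len(n), times = n_col),
                               as.vector(s_i))], n, n_col)
      acc <- acc + 2^(rel * p_i + noise())
    }
    log2(acc / config$pool_size)
  }
  L_head_rd <- pooled(rel0(rel_head))
  L_abd_rd <- pooled(rel0(rel_abd))

  # propagate regulator colony-level deviations into larval targets
  if (nrow(edges)) {
    src <- match(edges$source_gene, genes)
    tgt <- match(edges$target_gene, genes)
    for (e in seq_len(nrow(edges))) {
      dev <- if (edges$source_tissue[e] == "nurse_head")
        E_head[src[e], ] else E_larva[src[e], ]
      L_larva[tgt[e], ] <- L_larva[tgt[e], ] + edges$coefficient[e] * dev
    }
  }
  L_larva <- L_larva + meta(); L_head <- L_head + meta()
  L_abd <- L_abd + meta(); L_head_rd <- L_head_rd + meta()
  L_abd_rd <- L_abd_rd + meta()

  col_tag <- paste0(colony_stage, "_", colony_rep)
  blocks <- list(
    larva = list(L_larva, "larva", "not_applicable", "worker"),
    nh_ss = list(L_head, "nurse_head", "stage_specific", "not_applicable"),
    na_ss = list(L_abd, "nurse_abdomen", "stage_specific", "not_applicable"),
    nh_rd = list(L_head_rd, "nurse_head", "random", "not_applicable"),
    na_rd = list(L_abd_rd, "nurse_abdomen", "random", "not_applicable"))
  values <- NULL
  md <- NULL
  for (b in names(blocks)) {
    blk <- blocks[[b]]
    v <- baseline * 2^blk[[1]]
    colnames(v) <- paste0(b, "_", col_tag)
    values <- cbind(values, v)
    md <- rbind(md, data.frame(
      sample_id = colnames(v), tissue = blk[[2]], nurse_type = blk[[3]],
      stage = colony_stage, colony = colony_rep, caste = blk[[4]],
      queen_present = queen, stringsAsFactors = FALSE))
  }
  rownames(values) <- genes
  expr <- expression_matrix(values, md)

  truth <- structure(list(
    genes = data.frame(
      gene_id = genes, planted_module = planted_module,
      relation_head = ifelse(is.na(rel_head), NA_character_,
                             ifelse(rel_head > 0, "parallel",
                                    "antiparallel")),
      relation_abdomen = ifelse(is.na(rel_abd), NA_character_,
                                ifelse(rel_abd > 0, "parallel",
                                       "antiparallel")),
      is_social_regulator = seq_len(n) %in% social_idx,
      is_within_regulator = seq_len(n) %in% within_idx,
      stringsAsFactors = FALSE),
    edges = edges,
    config = config), class = "GroundTruth")
  list(expr = expr, truth = truth)
}

#' Simulate per-gene evolutionary and protein annotations
#'
#' Builds annotations whose structure matches the planted regulatory roles.
#' A latent sociality score (social-regulator status minus within-regulator
#' status plus Gaussian jitter, sd 0.5) drives all three columns: selective
#' constraint is drawn through a Gaussian copula so its Spearman correlation
#' with the score targets `rho_sociality_constraint`; evolutionary age
#' classes are cut from a noisy copy of the score so ancient genes are the
#' least social (enriched among within-regulators); and the secreted flag is
#' Bernoulli with log-odds increasing in the score (base rate 10%). Twelve
#' gene sets are attached: ten drawn uniformly (null sets) and two sampled
#' preferentially from high-score genes (enriched sets).
#'
#' @param truth `GroundTruth` from [simulate_experiment()].
#' @param config `SimConfig`; `rho_sociality_constraint` and `seed` are used.
#' @return Annotation `data.frame` (columns `gene_id`, `constraint`,
#'   `age_class`, `secreted`, `gene_sets`) with the latent score attached as
#'   attribute `"sociality_score"`. 5% of constraint and age values are
#'   masked as missing to exercise pairwise deletion downstream.
#' @export
simulate_annotations <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "GroundTruth"))
  set.seed(config$seed + 1L)
  g <- truth$genes
  n <- nrow(g)
  score <- as.numeric(g$is_social_regulator) -
    as.numeric(g$is_within_regulator) + stats::rnorm(n, 0, 0.5)
  rho_p <- 2 * sin(pi * config$rho_sociality_constraint / 6)
  z_s <- stats::qnorm((rank(score) - 0.5) / n)
  z_c <- rho_p * z_s + sqrt(1 - rho_p^2) * stats::rnorm(n)
  constraint <- stats::pnorm(z_c)

  age_latent <- score + stats::rnorm(n, 0, 0.75)
  cuts <- stats::quantile(age_latent, c(0.40, 0.65, 0.85))
  age <- cut(age_latent, c(-Inf, cuts, Inf),
             labels = c("ancient", "insect", "hymenoptera", "ant"))
  age <- as.character(age)

  secreted <- stats::runif(n) < stats::plogis(stats::qlogis(0.1) +
                                                1.5 * score)

  set_size <- max(5L, min(50L, n %/% 10L))
  sets <- character(n)
  add_set <- function(sets, id, members) {
    sets[members] <- ifelse(sets[members] == "", id,
                            paste(sets[members], id, sep = ";"))
    sets
  }
  for (i in 1:10)
    sets <- add_set(sets, sprintf("set%02d", i), sample.int(n, set_size))
  w <- rank(score)^2
  for (i in 1:2)
    sets <- add_set(sets, sprintf("set_hi_social%d", i),
                    sample.int(n, set_size, prob = w))

  constraint[sample.int(n, round(0.05 * n))] <- NA
  age[sample.int(n, round(0.05 * n))] <- NA
  ann <- data.frame(gene_id = g$gene_id, constraint = constraint,
                    age_class = age, secreted = secreted, gene_sets = sets,
                    stringsAsFactors = FALSE)
  attr(ann, "sociality_score") <- stats::setNames(score, g$gene_id)
  ann
}

#' Write a simulated experiment to disk
#'
#' Writes `expression.tsv`, `metadata.tsv`, `annotations.tsv` and
#' `ground_truth.json` under `dir`. Deterministic given the config seed, so
#' fixtures regenerate bitwise-identically.
#'
#' @param sim List from [simulate_experiment()].
#' @param ann Annotation table from [simulate_annotations()] (optional).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, ann = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"))
  write_expression(sim$expr, paths[["expression"]], paths[["metadata"]])
  if (!is.null(ann)) {
    paths[["annotations"]] <- file.path(dir, "annotations.tsv")
    utils::write.table(ann, paths[["annotations"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  paths[["ground_truth"]] <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(genes = sim$truth$genes, edges = sim$truth$edges,
         config = unclass(sim$truth$config)),
    paths[["ground_truth"]], dataframe = "columns", auto_unbox = TRUE,
    digits = NA)
  invisible(paths)
}
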