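# End-to-end orchestration: simulate (or load) -> filter -> module mining ->
# differential expression + random-nurse filter -> meta-samples -> network
# inference -> connectivity -> evolutionary statistics, with every
# intermediate written to disk and a manifest recording parameters, seeds,
# per-stage row counts and file checksums. Reruns with the same config give
# identical checksums.

#' Pipeline configuration
#'
#' Either `sim` (a [sim_config()]) for a synthetic run, or
#' `expression_path`/`metadata_path` (and optionally `annotation_path`) for
#' real input. Numeric defaults follow the analysis at full scale where a
#' stated value exists (1000 permutations, top 1000 candidates, alpha 0.05,
#' Bonferroni family-wise 0.05); forest size and run count default to
#' desk-scale values and can be raised to 1000 trees x 1000 runs.
#'
#' @param sim `SimConfig` or `NULL`.
#' @param expression_path,metadata_path,annotation_path Input TSVs
#'   (ignored when `sim` is given).
#' @param min_mean,min_stages Expression filter thresholds (FPKM scale).
#' @param pseudocount Log2 fold-change pseudocount.
#' @param flat_epsilon Flat-profile variance threshold.
#' @param n_perm Stage permutations for the module null.
#' @param alpha Nominal significance level (module enrichment family-wise
#'   rate before Bonferroni; DE screen threshold).
#' @param k Candidate genes per tissue for network inference.
#' @param n_trees,n_runs Random-forest size and averaging runs.
#' @param n_boot Bootstrap resamples for age-class means.
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(sim = sim_config(), expression_path = NULL,
                            metadata_path = NULL, annotation_path = NULL,
                            min_mean = 1, min_stages = 1, pseudocount = 1,
                            flat_epsilon = 1e-8, n_perm = 1000,
                            alpha = 0.05, k = 1000, n_trees = 100,
                            n_runs = 10, n_boot = 1000, seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$sim)) {
    if (is.null(cfg$expression_path) || is.null(cfg$metadata_path))
      stop("config needs either a simulation config or expression and ",
           "metadata paths")
    for (p in c(cfg$expression_path, cfg$metadata_path, cfg$annotation_path))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `sim` mapping
#' is passed to [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return `PipelineConfig`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(pipeline_config, raw)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order and writes every intermediate artifact
#' under `out_dir`, plus `manifest.json` (package version, seed, parameter
#' values, per-stage row counts, warnings, timings and md5 checksums of all
#' outputs).
#'
#' @param config `PipelineConfig`.
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress per-stage progress messages. Default `TRUE`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, quiet = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("socialinteractome")),
                   seed = config$seed,
                   parameters = config[!vapply(config, is.list,
                                               logical(1))],
                   stages = list(), warnings = character())
  t_all <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message(...)
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(manifest$stages[[stage]], list(...))
  }
  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    note(stage, seconds = round(proc.time()[["elapsed"]] - t0, 2))
    say(sprintf("[%s] done", stage))
    res
  }

  # -- input --
  ann <- NULL
  input <- run_stage("input", function() {
    if (!is.null(config$sim)) {
      sim <- simulate_experiment(config$sim)
      ann <<- simulate_annotations(sim$truth, config$sim)
      write_simulation(sim, ann, file.path(out_dir, "input"))
      sim
    } else {
      expr <- load_expression(config$expression_path, config$metadata_path)
      if (!is.null(config$annotation_path))
        ann <<- load_annotations(config$annotation_path)
      list(expr = expr, truth = NULL)
    }
  })
  expr <- input$expr
  note("input", n_genes = nrow(expr$values), n_samples = ncol(expr$values))

  # -- expression filter --
  genes <- run_stage("filter", function()
    expression_filter(expr, min_mean = config$min_mean,
                      min_stages = config$min_stages))
  note("filter", n_retained = length(genes))

  # -- module mining, per stratum, and shared modules --
  strata <- list(
    larva = list(tissue = "larva", nurse_type = NULL, caste = "worker"),
    nurse_head_ss = list(tissue = "nurse_head",
                         nurse_type = "stage_specific", caste = NULL),
    nurse_abdomen_ss = list(tissue = "nurse_abdomen",
                            nurse_type = "stage_specific", caste = NULL),
    nurse_head_random = list(tissue = "nurse_head", nurse_type = "random",
                             caste = NULL),
    nurse_abdomen_random = list(tissue = "nurse_abdomen",
                                nurse_type = "random", caste = NULL))
  reports <- run_stage("modules", function() {
    lapply(strata, function(s)
      tissue_module_report(expr, tissue = s$tissue,
                           nurse_type = s$nurse_type, caste = s$caste,
                           genes = genes, n_perm = config$n_perm,
                           seed = config$seed + 11L,
                           pseudocount = config$pseudocount,
                           alpha = config$alpha,
                           flat_epsilon = config$flat_epsilon))
  })
  mod_dir <- file.path(out_dir, "modules")
  dir.create(mod_dir, showWarnings = FALSE)
  for (nm in names(reports)) {
    .write_tsv(reports[[nm]]$enrichment,
               file.path(mod_dir, paste0("enrichment_", nm, ".tsv")))
    .write_tsv(reports[[nm]]$assignment,
               file.path(mod_dir, paste0("assignment_", nm, ".tsv")))
  }
  shared <- run_stage("shared_modules", function() {
    out <- list()
    for (nm in setdiff(names(reports), "larva")) {
      sh <- shared_modules(reports$larva$enriched, reports[[nm]]$enriched)
      counts <- shared_gene_counts(reports$larva$assignment,
                                   reports[[nm]]$assignment, sh)
      counts$side <- c("larva", nm)
      out[[nm]] <- list(shared = sh, counts = counts)
      .write_tsv(sh, file.path(mod_dir, paste0("shared_larva_", nm,
                                               ".tsv")))
      .write_tsv(counts, file.path(mod_dir,
                                   paste0("shared_counts_", nm, ".tsv")))
    }
    out
  })
  note("shared_modules",
       n_shared_head = nrow(shared$nurse_head_ss$shared),
       n_shared_abdomen = nrow(shared$nurse_abdomen_ss$shared))

  # -- differential expression + candidate selection --
  de_dir <- file.path(out_dir, "diffexp")
  dir.create(de_dir, showWarnings = FALSE)
  k_eff <- min(config$k, length(genes))
  candidates <- run_stage("diffexp", function() {
    sub <- subset_samples(expr, colnames(expr$values))
    sub$values <- sub$values[genes, , drop = FALSE]
    de <- list(
      larva = stage_association_test(sub, "larva", caste = "worker"),
      head_ss = stage_association_test(sub, "nurse_head",
                                       nurse_type = "stage_specific"),
      abd_ss = stage_association_test(sub, "nurse_abdomen",
                                      nurse_type = "stage_specific"),
      head_rd = stage_association_test(sub, "nurse_head",
                                       nurse_type = "random"),
      abd_rd = stage_association_test(sub, "nurse_abdomen",
                                      nurse_type = "random"))
    for (nm in names(de))
      .write_tsv(de[[nm]], file.path(de_dir, paste0("de_", nm, ".tsv")))
    larv_sig <- de$larva[de$larva$p_value < config$alpha, , drop = FALSE]
    larv_sig <- larv_sig[order(larv_sig$p_value, larv_sig$gene_id), ]
    list(larva = utils::head(larv_sig$gene_id, k_eff),
         head = candidate_selection(de$head_ss, de$head_rd,
                                    alpha = config$alpha, k = k_eff),
         abdomen = candidate_selection(de$abd_ss, de$abd_rd,
                                       alpha = config$alpha, k = k_eff))
  })
  note("diffexp", n_candidates_larva = length(candidates$larva),
       n_candidates_head = length(candidates$head),
       n_candidates_abdomen = length(candidates$abdomen))

  # -- network inference + connectivity --
  net_dir <- file.path(out_dir, "network")
  dir.create(net_dir, showWarnings = FALSE)
  conn <- run_stage("grn", function() {
    out <- NULL
    for (side in c("head", "abdomen")) {
      nurse_tissue <- paste0("nurse_", side)
      meta <- build_meta_samples(expr, candidates$larva,
                                 candidates[[side]],
                                 nurse_tissue = nurse_tissue)
      reg <- infer_regulatory_matrix(meta, n_trees = config$n_trees,
                                     n_runs = config$n_runs,
                                     seed = config$seed + 101L)
      utils::write.table(
        data.frame(source = rownames(reg$importance),
                   round(reg$importance, 8), check.names = FALSE),
        file.path(net_dir, paste0("importance_", side, "_net.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      ct <- connectivity_summary(reg, network = paste0(side, "_net"))
      out <- rbind(out, ct)
    }
    .write_tsv(out, file.path(net_dir, "connectivity.tsv"))
    out
  })
  note("grn", n_connectivity_rows = nrow(conn))

  # -- evolutionary statistics --
  stats_out <- NULL
  if (!is.null(ann)) {
    stats_dir <- file.path(out_dir, "evostats")
    dir.create(stats_dir, showWarnings = FALSE)
    stats_out <- run_stage("evostats", function() {
      res <- list()
      res$constraint <- connectivity_constraint_correlations(conn, ann)
      .write_tsv(res$constraint,
                 file.path(stats_dir, "constraint_correlations.tsv"))
      d <- merge(as.data.frame(conn), ann, by = "gene_id")
      sec <- d[d$tissue != "larva" & !is.na(d$secreted), , drop = FALSE]
      res$secreted <- as.data.frame(
        group_contrast(sec$social_connectivity, sec$secreted))
      .write_tsv(res$secreted,
                 file.path(stats_dir, "secreted_contrast.tsv"))
      res$within_vs_social <- as.data.frame(
        group_contrast(d$within_connectivity, d$social_connectivity,
                       paired = TRUE))
      .write_tsv(res$within_vs_social,
                 file.path(stats_dir, "within_vs_social.tsv"))
      glm_res <- sociality_age_glm(conn, ann)
      res$age_glm_lrt <- glm_res$lrt
      res$age_posthoc <- glm_res$posthoc
      .write_tsv(glm_res$lrt, file.path(stats_dir, "age_glm_lrt.tsv"))
      .write_tsv(glm_res$posthoc, file.path(stats_dir,
                                            "age_posthoc.tsv"))
      dd <- d[!is.na(d$age_class), , drop = FALSE]
      res$age_boot <- bootstrap_class_means(dd$sociality_index,
                                            dd$age_class,
                                            n_boot = config$n_boot,
                                            seed = config$seed + 201L)
      .write_tsv(res$age_boot, file.path(stats_dir, "age_bootstrap.tsv"))
      sc <- d[d$tissue != "larva", , drop = FALSE]
      vals <- stats::setNames(sc$social_connectivity,
                              paste(sc$gene_id, sc$network, sep = "@"))
      sets <- gene_sets_from_annotations(ann)
      sets_feat <- lapply(sets, function(g)
        names(vals)[sub("@.*", "", names(vals)) %in% g])
      res$ks <- ks_set_enrichment(vals, sets_feat)
      .write_tsv(res$ks, file.path(stats_dir, "ks_enrichment.tsv"))
      res
    })
  }

  manifest$elapsed_seconds <- round(proc.time()[["elapsed"]] - t_all, 2)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  sums <- tools::md5sum(files)
  manifest$checksums <- stats::setNames(unname(sums),
                                        sub(paste0("^", out_dir, "/?"), "",
                                            files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
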