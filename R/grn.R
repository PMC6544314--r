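# Social gene regulatory network inference.
#
# Meta-samples join the larval and nurse expression vectors collected from
# the same colony and time point, with features labelled by tissue of
# expression. A directed importance matrix is inferred per-target with
# random-forest regressions (one forest per target gene, all other features
# as predictors), averaged over repeated independently-seeded runs because
# the procedure is stochastic. Connectivity statistics then split each
# gene's mean outgoing importance into within-tissue and social (cross-
# tissue) components; their difference is the per-gene sociality index.

#' Build meta-samples pairing larval and nurse expression
#'
#' One observation per (colony, stage) pairing that has both a larval
#' sample (worker-destined) and a stage-specific nurse sample of the chosen
#' tissue; incomplete pairings are dropped. Values are asinh-transformed.
#' Features are the union of the two gene lists, labelled
#' `"larva:<gene>"` / `"<nurse_tissue>:<gene>"`.
#'
#' @param expr `ExpressionMatrix`.
#' @param larval_genes,nurse_genes Character vectors of gene ids used on
#'   each side (typically the top differential-expression candidates).
#' @param nurse_tissue `"nurse_head"` or `"nurse_abdomen"`.
#' @return Object of class `MetaSampleMatrix`: list with `values`
#'   (features x observations, asinh scale), `feature_tissue` (named
#'   vector), `feature_gene` (named vector), and `observations`
#'   (`data.frame` of colony/stage pairings).
#' @export
build_meta_samples <- function(expr, larval_genes, nurse_genes,
                               nurse_tissue = c("nurse_head",
                                                "nurse_abdomen")) {
  nurse_tissue <- match.arg(nurse_tissue)
  md <- expr$samples
  larva <- md[md$tissue == "larva" & md$caste == "worker", , drop = FALSE]
  nurse <- md[md$tissue == nurse_tissue &
                md$nurse_type == "stage_specific", , drop = FALSE]
  key_l <- paste(larva$colony, larva$stage, sep = "|")
  key_n <- paste(nurse$colony, nurse$stage, sep = "|")
  shared <- intersect(key_l, key_n)
  if (length(shared) < 3)
    stop("need >= 3 complete (colony, stage) pairings, found ",
         length(shared))
  shared <- sort(shared)
  l_ids <- larva$sample_id[match(shared, key_l)]
  n_ids <- nurse$sample_id[match(shared, key_n)]
  missing_l <- setdiff(larval_genes, rownames(expr$values))
  missing_n <- setdiff(nurse_genes, rownames(expr$values))
  if (length(missing_l) || length(missing_n))
    stop("unknown gene id(s): ",
         paste(c(missing_l, missing_n), collapse = ", "))
  vals <- rbind(asinh(expr$values[larval_genes, l_ids, drop = FALSE]),
                asinh(expr$values[nurse_genes, n_ids, drop = FALSE]))
  feat <- c(paste0("larva:", larval_genes),
            paste0(nurse_tissue, ":", nurse_genes))
  rownames(vals) <- feat
  colnames(vals) <- shared
  obs <- do.call(rbind, strsplit(shared, "|", fixed = TRUE))
  structure(list(
    values = vals,
    feature_tissue = stats::setNames(rep(c("larva", nurse_tissue),
                                         c(length(larval_genes),
                                           length(nurse_genes))), feat),
    feature_gene = stats::setNames(c(larval_genes, nurse_genes), feat),
    observations = data.frame(colony = obs[, 1], stage = obs[, 2],
                              stringsAsFactors = FALSE)),
    class = "MetaSampleMatrix")
}

#' @export
print.MetaSampleMatrix <- function(x, ...) {
  cat(sprintf("MetaSampleMatrix: %d features (%s) x %d observations\n",
              nrow(x$values),
              paste(sprintf("%s: %d", names(table(x$feature_tissue)),
                            table(x$feature_tissue)), collapse = ", "),
              ncol(x$values)))
  invisible(x)
}

#' Infer a directed regulatory importance matrix by random forests
#'
#' For each target feature, a random-forest regression of its values on all
#' other features (each standardised to unit variance) is fitted; the
#' impurity-reduction (variance) importance of each predictor, on the
#' per-tree-average scale, fills the target's column. The whole matrix is
#' averaged over `n_runs` runs with distinct derived seeds, since single
#' runs are stochastic. Entries are non-negative; the diagonal is exactly
#' 0. Importances are not renormalised per target, so they remain
#' comparable across targets.
#'
#' @param meta `MetaSampleMatrix` from [build_meta_samples()].
#' @param n_trees Trees per forest (>= 10). 1000 at full scale; 100 is
#'   adequate for desk-scale work.
#' @param n_runs Independent repetitions to average (>= 1).
#' @param seed Master seed; run `r` uses `seed + r`.
#' @param mtry Candidate features per split; default
#'   `floor(sqrt(p - 1))`.
#' @return Object of class `RegulatoryMatrix`: list with `importance`
#'   (features x features; entry (i, j) = importance of feature i for
#'   predicting feature j), `feature_tissue`, `feature_gene`,
#'   `n_runs_averaged`.
#' @export
infer_regulatory_matrix <- function(meta, n_trees = 1000, n_runs = 1,
                                    seed = 1, mtry = NULL) {
  stopifnot(inherits(meta, "MetaSampleMatrix"), n_trees >= 10, n_runs >= 1)
  X <- t(meta$values)                       # observations x features
  p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  const <- sds < 1e-12
  if (any(const))
    warning("zero-variance feature(s), importance column set to 0: ",
            paste(colnames(X)[const], collapse = ", "))
  Xs <- X
  Xs[, !const] <- scale(X[, !const, drop = FALSE])
  Xs[, const] <- 0
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p - 1)))
  acc <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    target_seeds <- sample.int(.Machine$integer.max - 1L, p)
    for (j in seq_len(p)) {
      if (const[j]) next
      dat <- data.frame(Xs[, -j, drop = FALSE], check.names = FALSE)
      y <- Xs[, j]
      rf <- ranger::ranger(x = dat, y = y, num.trees = n_trees,
                           mtry = min(mtry, p - 1L),
                           importance = "impurity", num.threads = 1L,
                           seed = target_seeds[j])
      acc[-j, j] <- acc[-j, j] + rf$variable.importance[colnames(dat)]
    }
  }
  structure(list(importance = acc / n_runs,
                 feature_tissue = meta$feature_tissue,
                 feature_gene = meta$feature_gene,
                 n_runs_averaged = n_runs),
            class = "RegulatoryMatrix")
}

#' Within-tissue and social connectivity per gene
#'
#' For each feature i, within-tissue connectivity is the mean outgoing
#' importance over same-tissue targets (excluding itself), social
#' connectivity the mean over other-tissue targets, and the sociality index
#' their difference (social minus within).
#'
#' @param reg `RegulatoryMatrix`, or a plain square matrix if
#'   `feature_tissue` is supplied.
#' @param feature_tissue Named tissue labels (only needed for a plain
#'   matrix).
#' @param network Optional network label stored in the output (e.g.
#'   `"head_net"`).
#' @return `data.frame` (class `ConnectivityTable`) with columns `feature`,
#'   `gene_id`, `tissue`, `within_connectivity`, `social_connectivity`,
#'   `sociality_index`, `network`.
#' @export
connectivity_summary <- function(reg, feature_tissue = NULL,
                                 network = NA_character_) {
  if (inherits(reg, "RegulatoryMatrix")) {
    m <- reg$importance
    tis <- reg$feature_tissue
    gene <- reg$feature_gene
  } else {
    m <- reg
    tis <- feature_tissue
    if (is.null(tis)) stop("feature_tissue required for a plain matrix")
    gene <- stats::setNames(rownames(m), rownames(m))
  }
  tis <- tis[rownames(m)]
  n <- nrow(m)
  same <- outer(tis, tis, "==")
  within_n <- rowSums(same) - 1
  social_n <- rowSums(!same)
  within_sum <- rowSums(m * same)           # diagonal is 0 by convention
  social_sum <- rowSums(m * !same)
  within <- ifelse(within_n > 0, within_sum / within_n, 0)
  social <- ifelse(social_n > 0, social_sum / social_n, 0)
  out <- data.frame(feature = rownames(m), gene_id = gene[rownames(m)],
                    tissue = tis, within_connectivity = within,
                    social_connectivity = social,
                    sociality_index = social - within,
                    network = network, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("ConnectivityTable", "data.frame")
  out
}

#' Cross-tissue Spearman correlation of two genes over colony pairings
#'
#' Correlates one gene's expression in tissue A with another gene's
#' expression in tissue B across complete (colony, stage) pairings, the
#' statistic behind single-pair social-regulation candidates such as a
#' nurse-expressed inhibitor tracking a larval pathway member.
#'
#' @param expr `ExpressionMatrix`.
#' @param gene_a,gene_b Gene identifiers.
#' @param tissue_a,tissue_b Tissues of expression for the two genes.
#' @param nurse_type Nurse stratum for nurse tissues. Default
#'   `"stage_specific"`.
#' @return List with `rho`, `p_value`, `n` (pairings used). A constant
#'   expression vector yields `rho = NA` with `flag = "constant"`.
#' @export
cross_tissue_gene_correlation <- function(expr, gene_a, gene_b,
                                          tissue_a = "nurse_head",
                                          tissue_b = "larva",
                                          nurse_type = "stage_specific") {
  md <- expr$samples
  pick <- function(tissue) {
    if (tissue == "larva")
      md[md$tissue == "larva" & md$caste == "worker", , drop = FALSE]
    else
      md[md$tissue == tissue & md$nurse_type == nurse_type, , drop = FALSE]
  }
  a <- pick(tissue_a); b <- pick(tissue_b)
  key_a <- paste(a$colony, a$stage); key_b <- paste(b$colony, b$stage)
  shared <- intersect(key_a, key_b)
  if (length(shared) < 3)
    stop("need >= 3 complete (colony, stage) pairings")
  va <- expr$values[gene_a, a$sample_id[match(shared, key_a)]]
  vb <- expr$values[gene_b, b$sample_id[match(shared, key_b)]]
  if (stats::sd(va) < 1e-12 || stats::sd(vb) < 1e-12)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(shared),
                flag = "constant"))
  ct <- suppressWarnings(stats::cor.test(va, vb, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}
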