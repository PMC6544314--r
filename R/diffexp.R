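# Stage-association differential expression and the random-nurse filter.
#
# The working model is a Gaussian linear model per gene on asinh-transformed
# abundance with stage and colony-replicate terms, compared by a
# likelihood-ratio test. The default reference distribution is the exact
# finite-sample F (the monotone transform of the Gaussian LRT); the
# chi-square deviance form is available via `test = "chisq"` for users who
# want the asymptotic GLM convention. A negative-binomial path is not
# provided because the pipeline consumes FPKM-like (non-count) input.

# Shared engine: nested linear models fitted to many genes at once.
# Y: genes x samples. X0 nested in X1. Returns statistic + p per gene.
.lrt_engine <- function(Y, X0, X1, test = c("F", "chisq")) {
  test <- match.arg(test)
  q0 <- qr(X0); q1 <- qr(X1)
  df_diff <- q1$rank - q0$rank
  if (df_diff < 1)
    stop("degenerate design: the tested term adds no estimable contrast ",
         "(aliased with the nuisance terms)")
  n_obs <- nrow(X1)
  df_res <- n_obs - q1$rank
  if (df_res < 1)
    stop("degenerate design: no residual degrees of freedom")
  rss0 <- colSums(qr.resid(q0, t(Y))^2)
  rss1 <- colSums(qr.resid(q1, t(Y))^2)
  tot <- rowSums((Y - rowMeans(Y))^2)
  flat <- tot < 1e-12
  if (test == "F") {
    stat <- ((rss0 - rss1) / df_diff) / (rss1 / df_res)
    p <- stats::pf(stat, df_diff, df_res, lower.tail = FALSE)
  } else {
    stat <- n_obs * log(rss0 / rss1)
    p <- stats::pchisq(stat, df_diff, lower.tail = FALSE)
  }
  stat[flat] <- NA_real_
  p[flat] <- 1
  list(statistic = stat, p_value = p, df = df_diff, df_res = df_res,
       test = test)
}

#' Per-gene stage-association test
#'
#' For one sample stratum, tests a developmental-stage factor in a linear
#' model of asinh-transformed abundance with colony-replicate nuisance
#' terms: `value ~ colony + stage` against `value ~ colony`. Genes with no
#' variance are flagged with `statistic = NA` and `p_value = 1`. P-values
#' are deliberately left nominal (no multiplicity correction): this stage
#' is a candidate screen, not an inference endpoint.
#'
#' @param expr `ExpressionMatrix`.
#' @param tissue,nurse_type,caste Stratum selectors.
#' @param transform `"asinh"` (default) or `"none"`.
#' @param test `"F"` (exact under the Gaussian working model; default) or
#'   `"chisq"` (asymptotic deviance LRT).
#' @return `data.frame` with columns `gene_id`, `statistic`, `p_value`,
#'   `tissue`.
#' @export
stage_association_test <- function(expr, tissue, nurse_type = NULL,
                                   caste = NULL,
                                   transform = c("asinh", "none"),
                                   test = c("F", "chisq")) {
  transform <- match.arg(transform)
  ids <- .stratum_ids(expr$samples, tissue = tissue, nurse_type = nurse_type,
                      caste = caste)
  sub <- subset_samples(expr, ids)
  md <- sub$samples
  if (length(unique(md$stage)) < 2)
    stop("need >= 2 stages with samples in the stratum")
  Y <- sub$values
  if (transform == "asinh") Y <- asinh(Y)
  has_colony <- length(unique(md$colony)) > 1
  X0 <- if (has_colony) stats::model.matrix(~colony, md) else
    stats::model.matrix(~1, md)
  X1 <- if (has_colony) stats::model.matrix(~colony + stage, md) else
    stats::model.matrix(~stage, md)
  fit <- .lrt_engine(Y, X0, X1, test = test)
  data.frame(gene_id = rownames(Y), statistic = fit$statistic,
             p_value = fit$p_value,
             tissue = paste(tissue, collapse = "+"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select network candidates with the random-nurse control filter
#'
#' Genes differentially expressed in both stage-specific and random nurses
#' reflect colony-specific environmental effects rather than social
#' regulation and are removed; of the remaining genes significant in the
#' stage-specific stratum, the `k` with the smallest p-values are retained
#' (ties broken lexicographically by gene id for determinism).
#'
#' @param de_ss [stage_association_test()] result for the stage-specific
#'   stratum.
#' @param de_random Result for the matching random-nurse stratum.
#' @param alpha Nominal significance threshold. Default 0.05.
#' @param k Number of candidates to keep. Default 1000.
#' @return Ordered character vector of gene ids. If fewer than `k` qualify,
#'   all are returned with attribute `short = TRUE` and a warning.
#' @export
candidate_selection <- function(de_ss, de_random, alpha = 0.05, k = 1000) {
  stopifnot(alpha > 0, alpha < 1, k >= 1)
  m <- merge(de_ss[c("gene_id", "p_value")],
             de_random[c("gene_id", "p_value")],
             by = "gene_id", suffixes = c("_ss", "_random"))
  drop_both <- m$p_value_ss < alpha & m$p_value_random < alpha
  cand <- m[!drop_both & m$p_value_ss < alpha, , drop = FALSE]
  cand <- cand[order(cand$p_value_ss, cand$gene_id), , drop = FALSE]
  out <- utils::head(cand$gene_id, k)
  if (length(out) < k) {
    warning("only ", length(out), " genes qualify (requested ", k, ")")
    attr(out, "short") <- TRUE
  }
  out
}

#' Per-gene association with a binary sample-level factor
#'
#' Same model family as [stage_association_test()] with the binary factor
#' replacing stage (colony-replicate terms retained when estimable), plus a
#' Benjamini-Hochberg adjusted p-value column. Used e.g. to verify that
#' queen presence leaves no expression signal.
#'
#' @param expr `ExpressionMatrix`.
#' @param group Name of a logical metadata column (default
#'   `"queen_present"`) or a logical vector aligned with the selected
#'   samples.
#' @param tissue,nurse_type,caste Stratum selectors.
#' @param transform,test See [stage_association_test()].
#' @return `data.frame` with `gene_id`, `statistic`, `p_value`, `padj`.
#' @export
group_association_test <- function(expr, group = "queen_present",
                                   tissue = NULL, nurse_type = NULL,
                                   caste = NULL,
                                   transform = c("asinh", "none"),
                                   test = c("F", "chisq")) {
  transform <- match.arg(transform)
  ids <- .stratum_ids(expr$samples, tissue = tissue, nurse_type = nurse_type,
                      caste = caste)
  sub <- subset_samples(expr, ids)
  md <- sub$samples
  g <- if (is.character(group) && length(group) == 1) md[[group]] else group
  if (length(g) != nrow(md))
    stop("grouping vector length (", length(g),
         ") does not match the selected samples (", nrow(md), ")")
  if (length(unique(g)) < 2)
    stop("the grouping factor has a single level in the stratum")
  md$.group <- factor(g)
  Y <- sub$values
  if (transform == "asinh") Y <- asinh(Y)
  has_colony <- length(unique(md$colony)) > 1
  X0 <- if (has_colony) stats::model.matrix(~colony, md) else
    stats::model.matrix(~1, md)
  X1 <- cbind(X0, stats::model.matrix(~.group, md)[, -1, drop = FALSE])
  fit <- .lrt_engine(Y, X0, X1, test = test)
  data.frame(gene_id = rownames(Y), statistic = fit$statistic,
             p_value = fit$p_value,
             padj = stats::p.adjust(fit$p_value, "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stage-by-group interaction test for one gene
#'
#' Tests whether an expression trajectory over development differs between
#' two groups (e.g. worker- vs reproductive-destined larvae): a linear
#' model of expression on ordinal stage, group, and their interaction,
#' compared against the no-interaction model by LRT.
#'
#' @param a,b `data.frame`s with columns `stage` (`L1`..`L5` or numeric
#'   1..5) and `value`, one row per sample, for the two groups.
#' @param test `"F"` (finite-sample; default) or `"chisq"` (deviance LRT,
#'   the conventional GLM chi-square form).
#' @return List with `statistic`, `df`, `p_value`, `test`.
#' @export
interaction_test <- function(a, b, test = c("F", "chisq")) {
  test <- match.arg(test)
  norm_stage <- function(s)
    if (is.numeric(s)) s else match(as.character(s), STAGES)
  df <- rbind(data.frame(stage = norm_stage(a$stage), value = a$value,
                         group = "a"),
              data.frame(stage = norm_stage(b$stage), value = b$value,
                         group = "b"))
  if (length(unique(df$stage[df$group == "a"])) < 3 ||
      length(unique(df$stage[df$group == "b"])) < 3)
    stop("both groups must span >= 3 stages")
  X0 <- stats::model.matrix(~stage + group, df)
  X1 <- stats::model.matrix(~stage * group, df)
  fit <- .lrt_engine(matrix(df$value, nrow = 1), X0, X1, test = test)
  list(statistic = unname(fit$statistic), df = fit$df,
       p_value = unname(fit$p_value), test = test)
}
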