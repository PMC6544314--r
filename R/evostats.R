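# Downstream statistics relating network position to molecular evolution:
# Spearman correlations of connectivity with selective constraint, Wilcoxon
# contrasts (secreted vs non-secreted, within vs social), a Gaussian GLM of
# sociality index on age class + constraint + tissue with per-term LRTs and
# Tukey post-hoc age contrasts, percentile bootstrap CIs per age class, and
# flat two-sample KS gene-set enrichment on connectivity. Missing
# annotations are dropped pairwise; reported n is always the rows used.

.direction <- function(delta, tol = 0) {
  if (is.na(delta) || abs(delta) <= tol) "none"
  else if (delta > 0) "positive" else "negative"
}

#' Spearman correlations of constraint with connectivity measures
#'
#' Per tissue, correlates selective constraint with within-tissue
#' connectivity, social connectivity and the sociality index.
#'
#' @param conn `ConnectivityTable` from [connectivity_summary()].
#' @param ann Annotation table with `gene_id` and `constraint`.
#' @return `data.frame` with one row per (tissue, measure): `test`,
#'   `tissue`, `measure`, `statistic` (rho), `p_value`, `n`, `direction`.
#'   Constant inputs are flagged (`direction = "none"`, no p-value).
#' @export
connectivity_constraint_correlations <- function(conn, ann) {
  d <- merge(as.data.frame(conn), ann[c("gene_id", "constraint")],
             by = "gene_id")
  measures <- c("within_connectivity", "social_connectivity",
                "sociality_index")
  rows <- list()
  for (tis in unique(d$tissue)) {
    dt <- d[d$tissue == tis & !is.na(d$constraint), , drop = FALSE]
    if (nrow(dt) < 10)
      stop("need >= 10 genes with constraint for tissue ", tis)
    for (m in measures) {
      x <- dt[[m]]; y <- dt$constraint
      if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
        rows[[length(rows) + 1L]] <- data.frame(
          test = "spearman", tissue = tis, measure = m,
          statistic = NA_real_, p_value = NA_real_, n = nrow(dt),
          direction = "none", stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        test = "spearman", tissue = tis, measure = m,
        statistic = unname(ct$estimate), p_value = ct$p.value,
        n = nrow(dt), direction = .direction(unname(ct$estimate)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rank-based two-group contrast
#'
#' Wilcoxon rank-sum test (unpaired) or signed-rank test (paired), with the
#' effect direction taken from the median difference (group TRUE minus
#' group FALSE for unpaired; first minus second series for paired).
#'
#' @param values Numeric vector. For `paired = TRUE`, the first series;
#'   `groups` then holds the second series of equal length.
#' @param groups Logical/two-level group labels (unpaired), or the paired
#'   second series.
#' @param paired Logical. Default `FALSE`.
#' @return List: `test`, `statistic`, `p_value`, `n`, `direction`.
#'   All-tied values give `p_value = 1` with a warning.
#' @export
group_contrast <- function(values, groups, paired = FALSE) {
  if (paired) {
    x <- values; y <- groups
    if (length(x) != length(y)) stop("paired series must be equal length")
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (all(x == y)) {
      warning("all paired values tied; p set to 1")
      return(list(test = "wilcoxon_signed_rank", statistic = 0,
                  p_value = 1, n = length(x), direction = "none"))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    delta <- stats::median(x - y)
    return(list(test = "wilcoxon_signed_rank",
                statistic = unname(wt$statistic), p_value = wt$p.value,
                n = length(x), direction = .direction(delta)))
  }
  g <- as.factor(groups)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  if (nlevels(g) != 2) stop("need exactly two non-empty groups")
  x <- values[g == levels(g)[2]]   # e.g. TRUE group
  y <- values[g == levels(g)[1]]
  if (length(unique(values)) == 1) {
    warning("all values tied; p set to 1")
    return(list(test = "wilcoxon_rank_sum", statistic = NA_real_,
                p_value = 1, n = length(values), direction = "none"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(test = "wilcoxon_rank_sum", statistic = unname(wt$statistic),
       p_value = wt$p.value, n = length(values),
       direction = .direction(stats::median(x) - stats::median(y)))
}

#' GLM of sociality index on evolutionary age, constraint and tissue
#'
#' Gaussian GLM (identity link) of the per-gene sociality index on
#' categorical age class, selective constraint and tissue, with drop-one
#' likelihood-ratio tests per term and Tukey(-Kramer) post-hoc contrasts
#' between all age-class pairs. Rows with missing age or constraint are
#' dropped (reported in `n`).
#'
#' @param conn `ConnectivityTable`.
#' @param ann Annotation table with `gene_id`, `age_class`, `constraint`.
#' @return List: `lrt` (`data.frame` term/statistic/df/p_value), `posthoc`
#'   (`data.frame` of pairwise age contrasts with Tukey-adjusted p),
#'   `model` (the `glm` fit), `n`.
#' @export
sociality_age_glm <- function(conn, ann) {
  d <- merge(as.data.frame(conn),
             ann[c("gene_id", "age_class", "constraint")], by = "gene_id")
  d <- d[!is.na(d$age_class) & !is.na(d$constraint), , drop = FALSE]
  d$age_class <- factor(d$age_class,
                        levels = intersect(c("ancient", "insect",
                                             "hymenoptera", "ant"),
                                           unique(d$age_class)))
  if (nlevels(d$age_class) < 2)
    stop("need >= 2 evolutionary age classes, found ",
         nlevels(d$age_class))
  multi_tissue <- length(unique(d$tissue)) > 1
  form <- if (multi_tissue)
    sociality_index ~ age_class + constraint + tissue
  else sociality_index ~ age_class + constraint
  X <- stats::model.matrix(form, d)
  if (qr(X)$rank < ncol(X)) {
    ali <- colnames(X)[-seq_len(qr(X)$rank)]
    stop("rank-deficient design; aliased term(s): ",
         paste(ali, collapse = ", "))
  }
  fit <- stats::glm(form, data = d, family = stats::gaussian())
  dr <- stats::drop1(fit, test = "LRT")
  dr <- dr[-1, , drop = FALSE]
  lrt <- data.frame(term = rownames(dr), statistic = dr[["scaled dev."]],
                    df = dr$Df, p_value = dr[["Pr(>Chi)"]],
                    stringsAsFactors = FALSE, row.names = NULL)
  aov_fit <- stats::aov(form, data = d)
  # TukeyHSD warns that covariate terms are ignored; the age-class factor
  # contrasts are exactly what we ask it for
  tk <- suppressWarnings(
    stats::TukeyHSD(aov_fit, which = "age_class"))$age_class
  posthoc <- data.frame(contrast = rownames(tk), difference = tk[, "diff"],
                        lower = tk[, "lwr"], upper = tk[, "upr"],
                        p_adjusted = tk[, "p adj"],
                        stringsAsFactors = FALSE, row.names = NULL)
  list(lrt = lrt, posthoc = posthoc, model = fit, n = nrow(d))
}

#' Percentile bootstrap of per-class means
#'
#' @param values Numeric vector (e.g. sociality index per gene).
#' @param classes Class labels aligned with `values`.
#' @param n_boot Bootstrap resamples (>= 100). Default 1000.
#' @param seed Integer seed.
#' @param conf Confidence level. Default 0.95.
#' @return `data.frame` with `class`, `n`, `mean`, `lower`, `upper`,
#'   `flag` (`"degenerate"` for classes of size 1).
#' @export
bootstrap_class_means <- function(values, classes, n_boot = 1000, seed = 1,
                                  conf = 0.95) {
  stopifnot(n_boot >= 100)
  keep <- !is.na(values) & !is.na(classes)
  values <- values[keep]; classes <- as.character(classes[keep])
  set.seed(seed)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  out <- lapply(unique(classes), function(cl) {
    v <- values[classes == cl]
    if (length(v) == 1)
      return(data.frame(class = cl, n = 1L, mean = v, lower = v, upper = v,
                        flag = "degenerate", stringsAsFactors = FALSE))
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(v[sample.int(length(v), replace = TRUE)]),
                 numeric(1))
    q <- stats::quantile(bm, probs, names = FALSE)
    data.frame(class = cl, n = length(v), mean = mean(v), lower = q[1],
               upper = q[2], flag = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Kolmogorov-Smirnov gene-set enrichment on a per-gene score
#'
#' Two-sample KS test of member genes' scores against non-members', per
#' set, with unadjusted p-values and the direction taken from the median
#' difference (members minus non-members). This is a flat set test: no
#' ontology-graph decorrelation is attempted.
#'
#' @param values Named numeric vector of per-gene scores (e.g. social
#'   connectivity), names are gene ids.
#' @param sets Named list of character vectors (gene ids per set), or an
#'   annotation table with `gene_id` and semicolon-delimited `gene_sets`.
#' @param min_size Minimum members and non-members required. Default 5.
#' @return `data.frame` with `set`, `n_set`, `n_background`, `statistic`,
#'   `p_value`, `direction`, `flag` (`"skipped_small"` for undersized
#'   sets).
#' @export
ks_set_enrichment <- function(values, sets, min_size = 5) {
  if (is.data.frame(sets)) sets <- gene_sets_from_annotations(sets)
  genes <- names(values)
  if (is.null(genes)) stop("'values' must be named by gene id")
  out <- lapply(names(sets), function(s) {
    members <- intersect(sets[[s]], genes)
    others <- setdiff(genes, members)
    if (length(others) == 0)
      stop("set '", s, "' covers all genes; no background remains")
    if (length(members) < min_size || length(others) < min_size)
      return(data.frame(set = s, n_set = length(members),
                        n_background = length(others),
                        statistic = NA_real_, p_value = NA_real_,
                        direction = "none", flag = "skipped_small",
                        stringsAsFactors = FALSE))
    kt <- suppressWarnings(stats::ks.test(values[members], values[others]))
    data.frame(set = s, n_set = length(members),
               n_background = length(others),
               statistic = unname(kt$statistic), p_value = kt$p.value,
               direction = .direction(stats::median(values[members]) -
                                        stats::median(values[others])),
               flag = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expand an annotation table's gene_sets column into a named list
#' @param ann Annotation table with `gene_id` and semicolon-delimited
#'   `gene_sets`.
#' @return Named list of gene-id vectors, one per set.
#' @export
gene_sets_from_annotations <- function(ann) {
  pieces <- strsplit(ann$gene_sets, ";", fixed = TRUE)
  long <- data.frame(gene_id = rep(ann$gene_id, lengths(pieces)),
                     set = unlist(pieces), stringsAsFactors = FALSE)
  long <- long[long$set != "", , drop = FALSE]
  split(long$gene_id, long$set)
}
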