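# Short time-series co-expression module mining.
#
# Modules are the 81 predefined five-point log2 fold-change trajectories
# obtained by doubling, halving or holding expression at each of the four
# steps after the first larval stage (3^4 = 81). Genes are assigned to the
# closest module by Pearson correlation, enrichment is judged against a
# stage-permutation null with a one-sided binomial test (Bonferroni over the
# 81 modules), and enriched modules shared between two tissues are split
# into parallel (identical) and anti-parallel (sign-flipped) pairs.

FLAT_MODULE <- "0,0,0,0,0"

#' Enumerate the 81 predefined module profiles
#'
#' Every profile starts at 0 and at each subsequent stage doubles (+1 in
#' log2), halves (-1) or keeps (0) the expression level, giving 3^4 = 81
#' distinct trajectories. The set is closed under negation and contains
#' exactly one self-inverse (the flat module).
#'
#' @return 81 x 5 numeric matrix, one profile per row, rows named by the
#'   canonical module id (comma-separated values, e.g. `"0,0,-1,-2,-3"`),
#'   in lexicographic order on the profile values.
#' @export
enumerate_module_profiles <- function() {
  steps <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), 4L)))
  prof <- cbind(0L, t(apply(steps, 1L, cumsum)))
  prof <- prof[do.call(order, as.data.frame(prof)), , drop = FALSE]
  dimnames(prof) <- list(apply(prof, 1L, paste, collapse = ","),
                         STAGES)
  prof
}

#' Canonical module id of a profile
#' @param profile Length-5 numeric vector.
#' @return Character id, e.g. `"0,1,2,3,4"`.
#' @export
module_id <- function(profile) paste(profile, collapse = ",")

#' Negate a module id
#'
#' The inverse trajectory: halving wherever the original doubles and vice
#' versa (anti-parallel partner).
#'
#' @param id Canonical module id.
#' @return Module id of the negated profile.
#' @export
negate_module <- function(id) {
  vapply(id, function(one) {
    module_id(-as.numeric(strsplit(one, ",", fixed = TRUE)[[1]]))
  }, character(1), USE.NAMES = FALSE)
}

# Row-standardise to zero mean / unit norm for fast Pearson via crossprod.
.row_standardise <- function(m) {
  c_m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(c_m^2))
  c_m / nrm
}

#' Assign stage profiles to their closest modules
#'
#' Each gene's observed log2 fold-change profile is assigned to the module
#' with which it has the highest Pearson correlation. Profiles whose
#' variance is below `flat_epsilon` go to the flat module (Pearson is
#' undefined against a constant trajectory) with the correlation recorded
#' as `NA`. Ties are broken by smaller Euclidean distance to the module,
#' then by canonical module order.
#'
#' @param profiles Genes x 5 matrix of log2 fold-change profiles.
#' @param modules Module matrix from [enumerate_module_profiles()].
#' @param flat_epsilon Variance threshold below which a profile is treated
#'   as flat. Default `1e-8`.
#' @return `data.frame` with columns `gene_id`, `module`, `correlation`.
#' @export
assign_profiles <- function(profiles, modules = enumerate_module_profiles(),
                            flat_epsilon = 1e-8) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  stopifnot(ncol(profiles) == 5L)
  n <- nrow(profiles)
  nonflat_mod <- modules[rownames(modules) != FLAT_MODULE, , drop = FALSE]
  mod_std <- .row_standardise(nonflat_mod)
  vars <- rowSums((profiles - rowMeans(profiles))^2) / (ncol(profiles) - 1)
  flat <- vars < flat_epsilon
  module <- rep(FLAT_MODULE, n)
  corr <- rep(NA_real_, n)
  if (any(!flat)) {
    p <- profiles[!flat, , drop = FALSE]
    cc <- .row_standardise(p) %*% t(mod_std)
    best <- max.col(cc, ties.method = "first")
    mx <- cc[cbind(seq_len(nrow(cc)), best)]
    ties <- which(rowSums(cc >= mx - 1e-12) > 1L)
    for (i in ties) {
      cand <- which(cc[i, ] >= mx[i] - 1e-12)
      d2 <- rowSums((nonflat_mod[cand, , drop = FALSE] -
                       rep(p[i, ], each = length(cand)))^2)
      best[i] <- cand[which.min(d2)]  # which.min keeps canonical order
    }
    module[!flat] <- rownames(nonflat_mod)[best]
    corr[!flat] <- mx
  }
  data.frame(gene_id = rownames(profiles) %||% paste0("g", seq_len(n)),
             module = module, correlation = corr,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign a single stage profile to a module
#'
#' Scalar convenience wrapper around [assign_profiles()].
#'
#' @param profile Length-5 log2 fold-change profile (first entry 0).
#' @param modules,flat_epsilon See [assign_profiles()].
#' @return List with elements `module` (id) and `correlation` (`NA` for the
#'   flat rule).
#' @export
assign_to_module <- function(profile, modules = enumerate_module_profiles(),
                             flat_epsilon = 1e-8) {
  res <- assign_profiles(matrix(profile, nrow = 1), modules = modules,
                         flat_epsilon = flat_epsilon)
  list(module = res$module[1], correlation = res$correlation[1])
}

# Permute each row of a matrix independently (vectorised).
.permute_rows <- function(m) {
  n <- nrow(m); k <- ncol(m)
  key <- matrix(stats::runif(n * k), n, k)
  o <- order(row(key), key)              # sorts within rows
  perm_col <- (o - 1L) %/% n + 1L        # column index of each sorted entry
  idx <- cbind(rep(seq_len(n), each = k), as.vector(t(matrix(perm_col, n,
                                                             byrow = TRUE))))
  matrix(m[idx], n, k, byrow = TRUE)
}

#' Stage-permutation null counts per module
#'
#' For each permutation, every gene's five per-stage mean abundances are
#' independently shuffled, the log2 fold-change profile is recomputed
#' anchored at the new first position, and genes are reassigned to modules.
#' The mean count per module over permutations is the null expectation used
#' by [module_enrichment()]; the permutation respects that some trajectory
#' shapes are intrinsically likelier than others.
#'
#' @param stage_means Genes x 5 matrix of per-stage mean abundances.
#' @param n_perm Number of permutations (>= 1). Default 1000.
#' @param seed Integer seed for the permutation stream.
#' @param pseudocount,flat_epsilon,modules Passed to the profile/assignment
#'   steps; must match the observed-data pipeline.
#' @return Named numeric vector over all 81 module ids: mean null count.
#' @export
permuted_null_counts <- function(stage_means, n_perm = 1000, seed = 1,
                                 pseudocount = 1, flat_epsilon = 1e-8,
                                 modules = enumerate_module_profiles()) {
  stopifnot(n_perm >= 1)
  set.seed(seed)
  ids <- rownames(modules)
  acc <- stats::setNames(numeric(length(ids)), ids)
  for (b in seq_len(n_perm)) {
    perm <- .permute_rows(stage_means)
    prof <- log2((perm + pseudocount) / (perm[, 1] + pseudocount))
    prof[, 1] <- 0
    asg <- assign_profiles(prof, modules = modules,
                           flat_epsilon = flat_epsilon)
    tab <- table(factor(asg$module, levels = ids))
    acc <- acc + as.numeric(tab)
  }
  acc / n_perm
}

#' One-sided binomial module enrichment
#'
#' Tests, per module, whether the observed gene count exceeds the
#' permutation-null expectation: an upper-tail binomial test of
#' `observed` successes in `n_genes` trials with success probability
#' `null_mean / n_genes`. Significance uses a Bonferroni-corrected
#' family-wise rate over the 81 modules with strict inequality
#' (`p < alpha / 81`). A null mean of exactly 0 is floored at
#' `0.5 / n_genes` (continuity correction) so the test stays defined.
#'
#' @param observed Named counts per module (from an assignment).
#' @param null_means Named null mean counts from [permuted_null_counts()].
#' @param n_genes Total analysed genes; must equal `sum(observed)`.
#' @param alpha Family-wise error rate before Bonferroni. Default 0.05.
#' @return `data.frame` (class `EnrichmentReport`) with columns `module`,
#'   `observed`, `null_mean`, `p_value`, `significant`.
#' @export
module_enrichment <- function(observed, null_means, n_genes, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  ids <- names(null_means)
  obs <- stats::setNames(numeric(length(ids)), ids)
  obs[names(observed)] <- observed
  if (abs(sum(obs) - n_genes) > 1e-9)
    stop("sum of observed counts (", sum(obs),
         ") must equal n_genes (", n_genes, ")")
  p0 <- ifelse(null_means == 0, 0.5 / n_genes, null_means / n_genes)
  p0 <- pmin(p0, 1)
  p <- stats::pbinom(obs - 1, size = n_genes, prob = p0, lower.tail = FALSE)
  sig <- (p < alpha / length(ids)) & (obs > null_means)
  out <- data.frame(module = ids, observed = as.numeric(obs),
                    null_mean = as.numeric(null_means), p_value = p,
                    significant = sig, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("EnrichmentReport", "data.frame")
  out
}

#' Observed counts per module from an assignment
#' @param assignment `data.frame` from [assign_profiles()].
#' @param modules Module matrix (for the id universe).
#' @return Named integer vector over all module ids.
#' @export
module_counts <- function(assignment, modules = enumerate_module_profiles()) {
  tab <- table(factor(assignment$module, levels = rownames(modules)))
  stats::setNames(as.integer(tab), rownames(modules))
}

#' Run the full module-mining stage for one tissue stratum
#'
#' Stage means -> log2 fold-change profiles -> module assignment ->
#' stage-permutation null -> binomial enrichment.
#'
#' @param expr `ExpressionMatrix`.
#' @param tissue,nurse_type,caste Stratum selectors.
#' @param genes Optional gene subset (e.g. from [expression_filter()]).
#' @param n_perm,seed,pseudocount,alpha,flat_epsilon Pipeline parameters.
#' @return List with `stage_means`, `profiles`, `assignment`, `null_means`,
#'   `enrichment` and `enriched` (ids of significantly enriched modules).
#' @export
tissue_module_report <- function(expr, tissue, nurse_type = NULL,
                                 caste = NULL, genes = NULL, n_perm = 1000,
                                 seed = 1, pseudocount = 1, alpha = 0.05,
                                 flat_epsilon = 1e-8) {
  sm <- stage_means(expr, tissue = tissue, nurse_type = nurse_type,
                    caste = caste)
  if (!is.null(genes)) sm <- sm[genes, , drop = FALSE]
  prof <- log2fc_profiles(sm, pseudocount = pseudocount)
  modules <- enumerate_module_profiles()
  assignment <- assign_profiles(prof, modules = modules,
                                flat_epsilon = flat_epsilon)
  null_means <- permuted_null_counts(sm, n_perm = n_perm, seed = seed,
                                     pseudocount = pseudocount,
                                     flat_epsilon = flat_epsilon,
                                     modules = modules)
  enr <- module_enrichment(module_counts(assignment, modules), null_means,
                           n_genes = nrow(sm), alpha = alpha)
  list(stage_means = sm, profiles = prof, assignment = assignment,
       null_means = null_means, enrichment = enr,
       enriched = enr$module[enr$significant])
}

#' Parallel and anti-parallel shared modules between two tissues
#'
#' A module enriched in both tissues is shared in parallel; a module whose
#' negation is enriched in the partner is shared anti-parallel. The flat
#' module is its own negation and can only ever be shared in parallel.
#'
#' @param enriched_a,enriched_b Character vectors of enriched module ids for
#'   the two tissues (subsets of the 81 ids).
#' @return `data.frame` with columns `module_a`, `module_b`, `relation`
#'   (`"parallel"` or `"antiparallel"`).
#' @export
shared_modules <- function(enriched_a, enriched_b) {
  par <- sort(intersect(enriched_a, enriched_b))
  anti <- sort(Filter(function(m) {
    nm <- negate_module(m)
    nm != m && nm %in% enriched_b
  }, enriched_a))
  data.frame(
    module_a = c(par, anti),
    module_b = c(par, negate_module(anti)),
    relation = rep(c("parallel", "antiparallel"),
                   c(length(par), length(anti))),
    stringsAsFactors = FALSE)
}

#' Genes falling in shared modules, per tissue
#'
#' For each side, counts the genes assigned to any module participating in a
#' shared (parallel or anti-parallel) pair; each gene is counted once even
#' when its module participates in both kinds of pair.
#'
#' @param assignment_a,assignment_b Assignments from [assign_profiles()] for
#'   the two tissues.
#' @param shared `data.frame` from [shared_modules()].
#' @return `data.frame` with one row per side (`a`, `b`): `count`, `n`,
#'   `fraction`.
#' @export
shared_gene_counts <- function(assignment_a, assignment_b, shared) {
  mods_a <- unique(shared$module_a)
  mods_b <- unique(shared$module_b)
  ca <- sum(assignment_a$module %in% mods_a)
  cb <- sum(assignment_b$module %in% mods_b)
  data.frame(side = c("a", "b"), count = c(ca, cb),
             n = c(nrow(assignment_a), nrow(assignment_b)),
             fraction = c(ca / nrow(assignment_a), cb / nrow(assignment_b)),
             stringsAsFactors = FALSE)
}

#' Leave-one-out jackknife mean, SE and normal-theory CI
#'
#' Standard jackknife over the leave-one-out replicate values:
#' `SE = sqrt((n-1)/n * sum((x_i - mean(x))^2))`; the CI is
#' `mean(x) +/- z * SE`.
#'
#' @param replicates Numeric vector of leave-one-out statistic values.
#' @param conf Confidence level. Default 0.95.
#' @return List with `mean`, `se`, `ci` (length-2).
#' @export
jackknife_ci <- function(replicates, conf = 0.95) {
  n <- length(replicates)
  if (n < 2) stop("need >= 2 jackknife replicates")
  m <- mean(replicates)
  se <- sqrt((n - 1) / n * sum((replicates - m)^2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(mean = m, se = se, ci = c(m - z * se, m + z * se))
}

#' Drop-1 jackknife of the shared-module gene fraction
#'
#' Re-runs the profile -> assignment -> enrichment -> shared-count pipeline
#' with each nurse sample of the stratum dropped once, and summarises the
#' uncertainty of the genes-in-shared-modules fraction with a jackknife SE
#' and normal-theory CI.
#'
#' @param expr `ExpressionMatrix`.
#' @param nurse_tissue `"nurse_head"` or `"nurse_abdomen"`.
#' @param nurse_type `"stage_specific"` (default) or `"random"`.
#' @param count_side Whose genes to count: `"nurse"` (default) or `"larva"`.
#' @param genes Optional gene subset used on both sides.
#' @param n_perm,seed,pseudocount,alpha,flat_epsilon,conf Pipeline
#'   parameters; the same permutation seed is reused in every replicate so
#'   only the dropped sample varies.
#' @return List with `estimate` (full-data fraction), `jackknife_mean`,
#'   `se`, `ci` and the per-replicate `replicates` vector.
#' @export
jackknife_shared_counts <- function(expr, nurse_tissue,
                                    nurse_type = "stage_specific",
                                    count_side = c("nurse", "larva"),
                                    genes = NULL, n_perm = 100, seed = 1,
                                    pseudocount = 1, alpha = 0.05,
                                    flat_epsilon = 1e-8, conf = 0.95) {
  count_side <- match.arg(count_side)
  larva_rep <- tissue_module_report(expr, tissue = "larva", caste = "worker",
                                    genes = genes, n_perm = n_perm,
                                    seed = seed, pseudocount = pseudocount,
                                    alpha = alpha,
                                    flat_epsilon = flat_epsilon)
  nurse_ids <- .stratum_ids(expr$samples, tissue = nurse_tissue,
                            nurse_type = nurse_type)
  if (length(nurse_ids) < 3)
    stop("need >= 3 nurse samples in the stratum, found ",
         length(nurse_ids))
  frac_for <- function(e) {
    nurse_rep <- tissue_module_report(e, tissue = nurse_tissue,
                                      nurse_type = nurse_type, genes = genes,
                                      n_perm = n_perm, seed = seed,
                                      pseudocount = pseudocount,
                                      alpha = alpha,
                                      flat_epsilon = flat_epsilon)
    sh <- shared_modules(larva_rep$enriched, nurse_rep$enriched)
    counts <- shared_gene_counts(larva_rep$assignment, nurse_rep$assignment,
                                 sh)
    counts$fraction[counts$side == if (count_side == "larva") "a" else "b"]
  }
  estimate <- frac_for(expr)
  reps <- vapply(nurse_ids, function(drop_id) {
    keep <- setdiff(colnames(expr$values), drop_id)
    frac_for(subset_samples(expr, keep))
  }, numeric(1))
  jk <- jackknife_ci(reps, conf = conf)
  list(estimate = estimate, jackknife_mean = jk$mean, se = jk$se,
       ci = jk$ci, replicates = reps)
}
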