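# Meta-sample construction, random-forest importance matrices and
# connectivity statistics.

# Construct a MetaSampleMatrix directly from a feature x observation matrix.
meta_from_matrix <- function(vals, tissues) {
  structure(list(values = vals,
                 feature_tissue = setNames(tissues, rownames(vals)),
                 feature_gene = setNames(sub("^[^:]*:", "", rownames(vals)),
                                         rownames(vals)),
                 observations = data.frame(colony = colnames(vals),
                                           stage = "L1")),
            class = "MetaSampleMatrix")
}

test_that("meta-samples pair larva and nurse by colony and stage", {
  sim <- small_sim(seed = 4)
  g <- rownames(sim$expr$values)[1:30]
  meta <- build_meta_samples(sim$expr, g, g, "nurse_head")
  expect_equal(dim(meta$values), c(60, 20))  # 4 colonies x 5 stages
  expect_setequal(unique(meta$feature_tissue), c("larva", "nurse_head"))
  expect_equal(sum(meta$feature_tissue == "larva"), 30)
  # values are asinh-transformed
  larva_ids <- sim$expr$samples$sample_id[sim$expr$samples$tissue ==
                                            "larva"]
  expect_equal(unname(meta$values["larva:g0001", 1]),
               unname(asinh(sim$expr$values[
                 "g0001", larva_ids[sim$expr$samples$colony[
                   match(larva_ids, sim$expr$samples$sample_id)] == "r1" &
                     sim$expr$samples$stage[
                       match(larva_ids,
                             sim$expr$samples$sample_id)] == "L1"]])))
  # dropping one nurse sample drops exactly that observation
  nurse_ids <- sim$expr$samples$sample_id[
    sim$expr$samples$tissue == "nurse_head" &
      sim$expr$samples$nurse_type == "stage_specific"]
  cut <- subset_samples(sim$expr,
                        setdiff(colnames(sim$expr$values), nurse_ids[1]))
  meta2 <- build_meta_samples(cut, g, g, "nurse_head")
  expect_equal(ncol(meta2$values), 19)
  expect_error(build_meta_samples(subset_samples(
    sim$expr, sim$expr$samples$sample_id[sim$expr$samples$tissue ==
                                           "larva"]), g, g, "nurse_head"),
    "pairings")
})

test_that("a copied regressor dominates its target's importance column", {
  set.seed(5)
  n_obs <- 25; n_feat <- 60
  vals <- matrix(rnorm(n_feat * n_obs), n_feat, n_obs,
                 dimnames = list(c(paste0("larva:g", 1:30),
                                   paste0("nurse_head:g", 1:30)),
                                 paste0("o", 1:n_obs)))
  vals["larva:g1", ] <- vals["nurse_head:g1", ]   # exact copy
  meta <- meta_from_matrix(vals, rep(c("larva", "nurse_head"), each = 30))
  # default mtry = sqrt(p-1): the copy tops the column by a wide margin
  reg <- infer_regulatory_matrix(meta, n_trees = 200, n_runs = 1, seed = 1)
  col <- reg$importance[, "larva:g1"]
  expect_identical(names(which.max(col)), "nurse_head:g1")
  expect_gt(col[["nurse_head:g1"]] / sum(col), 8 / (n_feat - 1))
  expect_true(all(reg$importance >= 0))
  expect_true(all(diag(reg$importance) == 0))
  # with exhaustive candidate sets the copy absorbs most of the column
  reg_all <- infer_regulatory_matrix(meta, n_trees = 100, n_runs = 1,
                                     seed = 1, mtry = n_feat - 1)
  col_all <- reg_all$importance[, "larva:g1"]
  expect_gt(col_all[["nurse_head:g1"]] / sum(col_all), 0.5)
})

test_that("independent-noise features share importance evenly", {
  shares <- vapply(1:5, function(r) {
    set.seed(100 + r)
    vals <- matrix(rnorm(40 * 200), 40, 200,
                   dimnames = list(paste0("larva:g", 1:40), NULL))
    colnames(vals) <- paste0("o", 1:200)
    meta <- meta_from_matrix(vals, rep("larva", 40))
    reg <- infer_regulatory_matrix(meta, n_trees = 100, n_runs = 1,
                                   seed = r)
    csum <- colSums(reg$importance)
    max(apply(reg$importance, 2, max) / csum)
  }, numeric(1))
  expect_lt(median(shares), 3 / 39)
})

test_that("run averaging reduces matrix variance and is deterministic", {
  set.seed(8)
  vals <- matrix(rnorm(20 * 20), 20, 20,
                 dimnames = list(paste0("larva:g", 1:20),
                                 paste0("o", 1:20)))
  meta <- meta_from_matrix(vals, rep("larva", 20))
  var_of <- function(n_runs, reps)
    apply(simplify2array(lapply(seq_len(reps), function(r)
      infer_regulatory_matrix(meta, n_trees = 50, n_runs = n_runs,
                              seed = 1000 * r)$importance)), c(1, 2),
      var)
  v1 <- mean(var_of(1, 5))
  v10 <- mean(var_of(10, 5))
  expect_lt(v10, v1)
  a <- infer_regulatory_matrix(meta, n_trees = 50, n_runs = 2, seed = 3)
  b <- infer_regulatory_matrix(meta, n_trees = 50, n_runs = 2, seed = 3)
  expect_identical(a$importance, b$importance)
})

test_that("an independent forest implementation agrees on the top edge", {
  skip_if_not_installed("randomForest")
  set.seed(11)
  vals <- matrix(rnorm(20 * 30), 20, 30,
                 dimnames = list(c(paste0("larva:g", 1:10),
                                   paste0("nurse_head:g", 1:10)),
                                 paste0("o", 1:30)))
  vals["larva:g2", ] <- vals["nurse_head:g5", ] + rnorm(30, 0, 0.2)
  meta <- meta_from_matrix(vals, rep(c("larva", "nurse_head"), each = 10))
  reg <- infer_regulatory_matrix(meta, n_trees = 300, n_runs = 1, seed = 2)
  ours <- names(which.max(reg$importance[, "larva:g2"]))
  X <- t(scale(t(vals)))
  rf <- randomForest::randomForest(
    x = t(X[rownames(X) != "larva:g2", ]), y = X["larva:g2", ],
    ntree = 300, importance = FALSE)
  theirs <- names(which.max(rf$importance[, "IncNodePurity"]))
  expect_identical(ours, theirs)
  expect_identical(ours, "nurse_head:g5")
})

test_that("connectivity matches a brute-force loop to 1e-12", {
  brute <- function(m, tis) {
    t(vapply(seq_len(nrow(m)), function(i) {
      w <- s <- nw <- ns <- 0
      for (j in seq_len(ncol(m))) {
        if (i == j) next
        if (tis[i] == tis[j]) { w <- w + m[i, j]; nw <- nw + 1 }
        else { s <- s + m[i, j]; ns <- ns + 1 }
      }
      c(within = if (nw) w / nw else 0, social = if (ns) s / ns else 0)
    }, numeric(2)))
  }
  set.seed(13)
  for (r in 1:10) {
    p <- sample(6:14, 1)
    m <- matrix(abs(rnorm(p * p)), p, p)
    diag(m) <- 0
    rownames(m) <- colnames(m) <- paste0("f", seq_len(p))
    tis <- setNames(sample(c("larva", "nurse_head"), p, replace = TRUE),
                    rownames(m))
    ct <- connectivity_summary(m, feature_tissue = tis)
    bf <- brute(m, tis)
    expect_equal(ct$within_connectivity, unname(bf[, "within"]),
                 tolerance = 1e-12)
    expect_equal(ct$social_connectivity, unname(bf[, "social"]),
                 tolerance = 1e-12)
    expect_equal(ct$sociality_index,
                 ct$social_connectivity - ct$within_connectivity)
  }
})

test_that("connectivity edge cases behave as documented", {
  m <- matrix(2, 4, 4); diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("f", 1:4)
  tis <- setNames(rep(c("larva", "nurse_head"), each = 2), rownames(m))
  ct <- connectivity_summary(m, feature_tissue = tis)
  expect_equal(ct$sociality_index, rep(0, 4))
  m2 <- matrix(0, 4, 4)
  dimnames(m2) <- dimnames(m)
  m2["f1", c("f3", "f4")] <- 1     # only cross-tissue edges
  ct2 <- connectivity_summary(m2, feature_tissue = tis)
  expect_equal(ct2$within_connectivity[1], 0)
  expect_gt(ct2$sociality_index[1], 0)
})

test_that("planted regulator roles separate in the within/social plane", {
  rhos <- numeric(3)
  for (s in 1:3) {
    cfg <- sim_config(n_genes_per_tissue = 80, n_colonies_per_stage = 5,
                      planted_module_fraction = 0,
                      n_social_regulators = 12, n_within_regulators = 12,
                      targets_per_regulator = 6, seed = s)
    sim <- simulate_experiment(cfg)
    genes <- rownames(sim$expr$values)
    meta <- build_meta_samples(sim$expr, genes, genes, "nurse_head")
    reg <- infer_regulatory_matrix(meta, n_trees = 100, n_runs = 3,
                                   seed = s)
    ct <- connectivity_summary(reg)
    tr <- sim$truth$genes
    soc <- ct$sociality_index[ct$feature %in%
                                paste0("nurse_head:",
                                       tr$gene_id[tr$is_social_regulator])]
    wit <- ct$sociality_index[ct$feature %in%
                                paste0("larva:",
                                       tr$gene_id[tr$is_within_regulator])]
    # social regulators sit on the social side of the index, within
    # regulators on the within side
    expect_gt(median(soc), median(wit))
    rhos[s] <- cor(ct$within_connectivity, ct$social_connectivity,
                   method = "spearman")
  }
  # with only regulatory structure planted, the two connectivities are
  # not positively coupled (trade-off side of the plane)
  expect_lt(median(rhos), 0.05)
})

test_that("cross-tissue Spearman correlation handles the trivial cases", {
  sim <- small_sim(seed = 6)
  expr <- sim$expr
  larva_ids <- expr$samples$sample_id[expr$samples$tissue == "larva"]
  nurse_ids <- expr$samples$sample_id[expr$samples$tissue == "nurse_head" &
                                        expr$samples$nurse_type ==
                                          "stage_specific"]
  # gene in larva = monotone transform of gene in nurse -> rho 1
  expr$values["g0002", larva_ids] <-
    exp(asinh(expr$values["g0001", nurse_ids]))
  up <- cross_tissue_gene_correlation(expr, "g0001", "g0002")
  expect_equal(up$rho, 1)
  expect_equal(up$n, 20)
  # negated ranks -> rho -1
  expr$values["g0003", larva_ids] <-
    max(expr$values["g0001", nurse_ids]) + 1 -
    expr$values["g0001", nurse_ids]
  down <- cross_tissue_gene_correlation(expr, "g0001", "g0003")
  expect_equal(down$rho, -1)
  expr$values["g0004", larva_ids] <- 5
  flat <- cross_tissue_gene_correlation(expr, "g0001", "g0004")
  expect_true(is.na(flat$rho))
  expect_identical(flat$flag, "constant")
})

test_that("planted anti-correlated pairs are recovered across seeds", {
  # Gaussian copula with rho = -0.5 at the study pairing count (n = 25)
  rhos <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 25
    z <- rnorm(n)
    x <- z
    y <- -0.5 * z + sqrt(1 - 0.25) * rnorm(n)
    cor(x, y, method = "spearman")
  }, numeric(1))
  expect_true(mean(rhos > -0.8 & rhos < -0.2) >= 0.9)
  expect_lt(median(rhos), -0.3)
})
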