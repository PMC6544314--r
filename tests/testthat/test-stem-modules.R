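# Module enumeration, Pearson assignment, permutation null, enrichment and
# shared-module logic.

modules <- enumerate_module_profiles()

test_that("the module grid has 81 profiles, closed under negation", {
  expect_equal(nrow(modules), 81)
  expect_equal(anyDuplicated(rownames(modules)), 0)
  expect_true(all(modules[, 1] == 0))
  steps <- t(apply(modules, 1, diff))
  expect_true(all(steps %in% c(-1, 0, 1)))
  expect_true(all(negate_module(rownames(modules)) %in% rownames(modules)))
  self_inverse <- rownames(modules)[negate_module(rownames(modules)) ==
                                      rownames(modules)]
  expect_identical(self_inverse, "0,0,0,0,0")
  expect_true(all(c("0,0,0,0,0", "0,1,2,3,4", "0,-1,-2,-3,-4",
                    "0,0,-1,-2,-3", "0,0,1,2,3") %in% rownames(modules)))
  # canonical order is lexicographic on the values
  expect_identical(rownames(modules),
                   rownames(modules)[do.call(order,
                                             as.data.frame(modules))])
})

test_that("assignment matches a brute-force correlation oracle", {
  brute <- function(p) {
    nonflat <- modules[rownames(modules) != "0,0,0,0,0", ]
    cs <- apply(nonflat, 1, function(m) cor(p, m))
    best <- names(cs)[cs >= max(cs) - 1e-12]
    if (length(best) > 1) {
      d <- vapply(best, function(b)
        sum((as.numeric(strsplit(b, ",")[[1]]) - p)^2), numeric(1))
      best <- best[which.min(d)]
    }
    best
  }
  set.seed(42)
  profs <- matrix(rnorm(300 * 5), 300, 5)
  profs[, 1] <- 0
  got <- assign_profiles(profs)$module
  want <- apply(profs, 1, brute)
  expect_identical(got, unname(want))
})

test_that("assignment handles exact, noisy and flat profiles", {
  exact <- assign_to_module(c(0, 1, 2, 3, 4))
  expect_identical(exact$module, "0,1,2,3,4")
  expect_equal(exact$correlation, 1)
  expect_identical(assign_to_module(c(0, 0.9, 2.1, 2.9, 4.2))$module,
                   "0,1,2,3,4")
  flat <- assign_to_module(c(0, 1e-12, 0, 0, 0))
  expect_identical(flat$module, "0,0,0,0,0")
  expect_true(is.na(flat$correlation))
})

test_that("assignment is invariant to positive rescaling (Pearson)", {
  set.seed(7)
  for (i in 1:20) {
    p <- c(0, rnorm(4))
    base <- assign_to_module(p)$module
    for (c_mult in c(0.1, 3, 50))
      expect_identical(assign_to_module(p * c_mult)$module, base)
  }
})

test_that("permutation null conserves genes and keeps flat genes flat", {
  set.seed(3)
  sm <- rbind(matrix(rexp(50 * 5, 0.2), 50, 5),
              matrix(5, 10, 5))          # 10 exactly flat genes
  rownames(sm) <- paste0("g", 1:60)
  nm <- permuted_null_counts(sm, n_perm = 50, seed = 1)
  expect_equal(sum(nm), 60)
  expect_gte(nm[["0,0,0,0,0"]], 10)      # flat under every permutation
})

test_that("null means track observed counts for structureless genes", {
  # at 1000 genes the multinomial fluctuation of the observed counts is
  # small enough for the two module distributions to agree closely
  set.seed(12)
  n <- 1000
  sm <- matrix(exp(rnorm(n * 5, 3, 0.5)), n, 5)
  rownames(sm) <- paste0("g", seq_len(n))
  obs <- module_counts(assign_profiles(log2fc_profiles(sm)))
  nm <- permuted_null_counts(sm, n_perm = 200, seed = 4)
  tv <- sum(abs(obs / n - nm / n)) / 2
  expect_lt(tv, 0.15)
})

test_that("binomial enrichment flags excess counts, strict threshold", {
  ids <- rownames(modules)
  nm <- setNames(rep(500 / 81, 81), ids)
  obs <- setNames(round(nm), ids)
  obs[1] <- obs[1] + (500 - sum(round(nm)))   # conserve the total
  none <- module_enrichment(obs, nm, 500)
  expect_false(any(none$significant[none$observed <= none$null_mean]))
  # a strong excess: 50 genes where 5 expected
  obs2 <- obs; obs2[["0,1,2,3,4"]] <- obs2[["0,1,2,3,4"]] + 45
  obs2[["0,0,0,0,0"]] <- obs2[["0,0,0,0,0"]] - 45
  nm2 <- nm; nm2[["0,1,2,3,4"]] <- 5
  rep2 <- module_enrichment(obs2, nm2, 500)
  row <- rep2[rep2$module == "0,1,2,3,4", ]
  expect_lt(row$p_value, 0.05 / 81)
  expect_true(row$significant)
  expect_equal(row$p_value,
               pbinom(row$observed - 1, 500, 5 / 500, lower.tail = FALSE))
  # the boundary is strict: alpha chosen so alpha/81 equals p exactly
  alpha_edge <- row$p_value * 81
  rep3 <- module_enrichment(obs2, nm2, 500, alpha = alpha_edge)
  expect_false(rep3[rep3$module == "0,1,2,3,4", "significant"])
  # zero null mean stays defined via the probability floor
  nm0 <- nm; nm0[["0,1,2,3,4"]] <- 0
  rep4 <- module_enrichment(obs2, nm0, 500)
  expect_true(is.finite(rep4[rep4$module == "0,1,2,3,4", "p_value"]))
  expect_error(module_enrichment(obs2, nm, 400), "n_genes")
})

test_that("shared-module logic separates parallel from anti-parallel", {
  a <- c("0,1,2,3,4", "0,0,-1,-2,-3", "0,1,1,1,1")
  b <- c("0,1,2,3,4", "0,0,1,2,3", "0,-1,-2,-3,-4")
  sh <- shared_modules(a, b)
  expect_setequal(sh$module_a[sh$relation == "parallel"], "0,1,2,3,4")
  expect_setequal(sh$module_a[sh$relation == "antiparallel"],
                  c("0,1,2,3,4", "0,0,-1,-2,-3"))
  expect_identical(sh$module_b[sh$module_a == "0,0,-1,-2,-3"], "0,0,1,2,3")
  # disjoint non-inverse sets share nothing
  expect_equal(nrow(shared_modules("0,1,1,1,1", "0,0,0,1,1")), 0)
  # the flat module is self-inverse: one parallel pair only
  fl <- shared_modules("0,0,0,0,0", "0,0,0,0,0")
  expect_equal(nrow(fl), 1)
  expect_identical(fl$relation, "parallel")
})

test_that("shared gene counts and fractions match hand counts", {
  asg_a <- data.frame(gene_id = paste0("g", 1:10),
                      module = c(rep("0,1,2,3,4", 4), rep("0,0,0,1,1", 6)),
                      correlation = 1)
  asg_b <- data.frame(gene_id = paste0("h", 1:5),
                      module = c(rep("0,1,2,3,4", 2), rep("0,0,0,0,0", 3)),
                      correlation = 1)
  sh <- shared_modules("0,1,2,3,4", "0,1,2,3,4")
  counts <- shared_gene_counts(asg_a, asg_b, sh)
  expect_equal(counts$fraction[counts$side == "a"], 0.4)
  expect_equal(counts$fraction[counts$side == "b"], 0.4)
  none <- shared_gene_counts(asg_a, asg_b,
                             shared_modules("0,1,1,1,1", "0,0,0,1,1"))
  expect_equal(none$count, c(0, 0))
})

test_that("jackknife SE matches the closed form", {
  jk <- jackknife_ci(c(10, 12, 14))
  expect_equal(jk$se, sqrt(16 / 3))
  expect_equal(jk$mean, 12)
  expect_true(jk$ci[1] < jk$mean && jk$mean < jk$ci[2])
  same <- jackknife_ci(rep(3, 8))
  expect_equal(same$se, 0)
  expect_equal(diff(same$ci), 0)
})

test_that("drop-1 jackknife of shared counts runs and brackets the mean", {
  sim <- simulate_experiment(sim_config(n_genes_per_tissue = 150,
                                        n_colonies_per_stage = 4, seed = 2))
  jk <- jackknife_shared_counts(sim$expr, "nurse_head", "stage_specific",
                                n_perm = 30, seed = 5)
  expect_length(jk$replicates, 4 * 5)
  expect_true(jk$ci[1] <= jk$jackknife_mean &&
                jk$jackknife_mean <= jk$ci[2])
  small <- subset_samples(sim$expr, sim$expr$samples$sample_id[
    sim$expr$samples$tissue == "larva" |
      sim$expr$samples$sample_id %in%
        sim$expr$samples$sample_id[sim$expr$samples$tissue ==
                                     "nurse_head"][1:2]])
  expect_error(jackknife_shared_counts(small, "nurse_head",
                                       "stage_specific"),
               ">= 3 nurse samples")
})
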