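# socialinteractome

Tools for studying **social gene regulation** between interacting
individuals — specifically, between caregiving ant nurse workers and the
larvae they feed across a five-stage larval developmental series. When
nurses adjust their physiology to the larvae they rear (and vice versa),
the two transcriptomes become coupled; this package detects that coupling,
reconstructs the putative regulatory network that spans the two bodies,
and asks how a gene's position in that *social* network relates to its
molecular evolution.

It is aimed at researchers analysing paired expression data from
interacting partners (host–symbiont, parent–offspring, caregiver–brood)
who want a tested, reproducible implementation of the full workflow, plus
a synthetic-data generator with planted ground truth for validating every
stage without access to raw sequencing data.

## What it computes

**Co-expression modules.** Gene trajectories are summarised as five-point
log2 fold-change profiles relative to the first stage,
`p_s = log2((m_s + c) / (m_L1 + c))`, and assigned by Pearson correlation
to the closest of the 81 predefined modules built by doubling, halving or
holding expression at each of the four steps after L1 (3^4 = 81). Module
enrichment is judged against a stage-permutation null with a one-sided
binomial test, Bonferroni-corrected across the 81 modules. Modules
enriched in both partners are *parallel* shared; modules whose negation is
enriched in the partner are *anti-parallel*. Uncertainty on the fraction
of genes in shared modules comes from systematic drop-1 jackknifing of
nurse samples.

**Candidate screening.** Per-gene linear models of asinh-transformed
abundance with stage and colony-replicate terms identify stage-associated
genes per tissue (nominal p < 0.05); genes also stage-associated in
*random* nurses (a biological control collected feeding any larval stage)
are removed, and the top-k candidates by p-value are retained.

**Social regulatory networks.** Larval and nurse expression vectors from
the same colony and time point are joined into meta-samples with features
labelled by tissue of expression. For each target gene a random-forest
regression on all other features yields impurity-importance scores — entry
(i, j) of the resulting directed matrix is the importance of gene i for
predicting gene j — averaged over repeated independently-seeded runs. Each
gene's mean outgoing importance is split into **within-tissue
connectivity** and **social connectivity** (cross-tissue), and the
**sociality index** is their difference.

**Evolutionary statistics.** Spearman correlations of connectivity with
selective constraint, Wilcoxon contrasts (secreted vs non-secreted
proteins; within vs social connectivity), a Gaussian GLM of sociality
index on evolutionary age class + constraint + tissue with per-term
likelihood-ratio tests and Tukey post-hoc age contrasts, percentile
bootstrap CIs per age class, and two-sample Kolmogorov–Smirnov gene-set
enrichment on connectivity.

**Synthetic data.** `simulate_experiment()` emulates the study design (5
stages × 6 colonies, pooled larva / nurse head / nurse abdomen /
random-nurse samples per colony) with planted, recoverable structure:
module blocks shared between larvae and stage-specific nurses (parallel or
anti-parallel) but absent in random nurses, cross-tissue regulator→target
edges injected as colony-level covariation, and annotation tables whose
constraint, age and secretion columns correlate with planted sociality.

## Worked example

```r
library(socialinteractome)

sim <- simulate_experiment(sim_config(n_genes_per_tissue = 600, seed = 5))

larva <- tissue_module_report(sim$expr, "larva", caste = "worker",
                              n_perm = 200, seed = 1)
nurse <- tissue_module_report(sim$expr, "nurse_head",
                              nurse_type = "stage_specific",
                              n_perm = 200, seed = 1)
sh <- shared_modules(larva$enriched, nurse$enriched)
head(sh, 3)
#>        module_a      module_b relation
#> 1 0,-1,-1,-2,-1 0,-1,-1,-2,-1 parallel
#> 2 0,-1,-1,-2,-3 0,-1,-1,-2,-3 parallel
#> 3   0,-1,-1,0,1   0,-1,-1,0,1 parallel
shared_gene_counts(larva$assignment, nurse$assignment, sh)
#>   side count   n  fraction
#> 1    a   309 600 0.5150000
#> 2    b   274 600 0.4566667
```

About half of all genes fall in modules shared between larvae and
stage-specific nurses (the generator planted coherent trajectories in 50%
of genes); running the same contrast against the random-nurse stratum
gives a shared fraction near zero. Downstream, `build_meta_samples()` +
`infer_regulatory_matrix()` + `connectivity_summary()` produce the
per-gene connectivity table consumed by the evolutionary statistics, and
`run_pipeline(pipeline_config(...), "out/")` executes everything with a
manifest of seeds, parameters and checksums.

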