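---
title: "Models and methods behind socialinteractome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind socialinteractome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the models, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, the numerical choices, and the known
limitations. The package analyses paired transcriptomes of interacting ant
nurse workers and larvae across five larval stages (L1–L5): co-expression
module mining, a differential-expression candidate screen, random-forest
regulatory network inference across the two bodies, and statistics
relating a gene's network position to its molecular evolution.

## Expression model and transformations

The universal input is a gene × sample matrix of FPKM-like, non-negative
abundances with typed sample metadata (tissue, nurse type, stage, colony
replicate, caste, queen presence). Two transformations are used:

* **Log2 fold-change stage profiles.** For a stratum, per-stage means are
  computed first and the profile is `log2((m_s + c)/(m_L1 + c))` with
  pseudocount `c` (default 1 FPKM), anchored so the first entry is exactly
  0. Ratio-of-means was chosen over mean-of-log-ratios because a single
  zero-FPKM replicate leaves it finite and it commutes with pooled
  sampling; the pseudocount choice for zero expression at L1 is ours (no
  established convention exists for this situation), and `c = 1` on the
  FPKM scale compresses only genes expressed near or below 1 FPKM.
* **asinh.** Network inference and the linear-model screens operate on
  `asinh(x) = ln(x + sqrt(x^2+1))`: variance-stabilising, ~`log(2x)` for
  large `x`, linear near zero, defined at zero.

An expression filter retains genes whose per-stage mean reaches
`min_mean` (default 1 FPKM) in at least `min_stages` (default 1) stages;
the thresholds are deliberately permissive defaults since the appropriate
cut depends on sequencing depth.

## Module mining

Modules are the 81 five-point trajectories that start at 0 and double
(+1 in log2), halve (−1) or hold (0) at each of the four steps after L1.
Genes are assigned to the module with the highest Pearson correlation to
their observed profile. Numerical choices:

* **Flat rule.** Pearson correlation is undefined against the constant
  module, so profiles with variance below `flat_epsilon` (default 1e-8)
  are assigned to the flat module with the correlation recorded as
  missing. Ties among non-flat modules are broken by smaller Euclidean
  distance, then canonical (lexicographic) module order.
* **Permutation null.** Each gene's five per-stage means are shuffled
  independently, the profile re-anchored at the new first position, and
  genes reassigned; the per-module mean count over `n_perm` permutations
  (default 1000) is the null expectation. We permute all five stages and
  re-anchor rather than permuting only the four post-L1 stages: the
  re-anchoring makes the null invariant to which stage happens to be
  first, and the two readings agree in expectation for exchangeable
  profiles.
* **Enrichment.** One-sided upper-tail binomial test of the observed
  count in `n` genes against success probability `null_mean/n`,
  significant iff `p < alpha/81` (strict), Bonferroni within each tissue
  separately. A null mean of exactly zero is floored at `0.5/n`
  (continuity correction) to keep the test defined.
* **Sharing.** Parallel pairs are modules enriched in both tissues;
  anti-parallel pairs are modules whose negation is enriched in the
  partner. The flat module is the unique self-inverse and can only be
  parallel. A gene is counted once in the shared-gene fraction even if
  its module participates in both kinds of pair.
* **Jackknife.** The shared-gene fraction's uncertainty comes from
  dropping each nurse sample once and re-running assignment, null and
  enrichment (same permutation seed, so only the dropped sample varies):
  `SE = sqrt((n-1)/n * sum((x_i - mean)^2))`, CI = mean ± 1.96 SE. The
  statistic inherits genuine discreteness — a module near the
  significance boundary can flip with one sample — and the jackknife SE
  honestly reflects that.

## Candidate screen

Per gene and stratum, a Gaussian linear model of asinh abundance with
colony-replicate and stage terms is compared against the replicate-only
model by likelihood ratio. The default reference distribution is the
finite-sample F — exact under the Gaussian working model and therefore
calibrated at the study's sample sizes (~30 samples per stratum), where
the chi-square asymptotic reference is visibly anti-conservative; a
`test = "chisq"` switch provides the conventional deviance form. P-values
are left nominal (no FDR) because this stage is a screen, not an
inference endpoint. Genes significant in both the stage-specific and the
matching random-nurse stratum are removed (colony-specific environmental
effects), and the `k` smallest stage-specific p-values are kept (default
1000; ties broken lexicographically by gene id for determinism). A
negative-binomial count path is intentionally absent: the data model is
FPKM-like, and re-implementing count-model machinery would add a second
statistical engine without adding information.

The same engine provides a binary-factor screen (e.g. queen presence,
with Benjamini–Hochberg FDR) and a per-gene stage × group interaction
test (ordinal stage, LRT on the interaction term).

## Network inference

Meta-samples join the larval and nurse expression vectors from the same
colony and time point; features are genes labelled by tissue of
expression, so a gene expressed in both bodies contributes two features.
For each target feature a random-forest regression on all other features
yields impurity (variance-reduction) importances — entry (i, j) of the
regulatory matrix is the importance of feature i for predicting feature
j. Choices, following the standard forest-based network-inference
conventions:

* candidate features per split `mtry = floor(sqrt(p-1))`; 1000 trees at
  full scale (100 in desk-scale tests); features standardised to unit
  variance; importances on the per-tree-average scale.
* no per-target renormalisation of importances, so columns remain
  comparable across targets; an incoming-mode switch exists but outgoing
  (row) means are the default, matching the "effect of gene i on others"
  reading.
* the whole matrix is averaged over `n_runs` independently seeded runs
  (seed + run index) because single runs are stochastic; zero-variance
  targets get a zero column with a warning.
* two networks are built independently (larva × nurse head, larva × nurse
  abdomen).

Within-tissue connectivity is a feature's mean outgoing importance over
same-tissue targets, social connectivity the mean over cross-tissue
targets, and the sociality index their difference (social − within,
exact).

## Evolutionary statistics

Spearman correlations (pairwise-complete) relate constraint to the three
connectivity measures per tissue. Group contrasts are Wilcoxon rank-sum
or signed-rank tests with direction from the median difference; the
within-vs-social contrast defaults to paired (per gene). The sociality ~
age + constraint + tissue model is a Gaussian GLM with identity link (the
response is a real-valued difference); per-term drop-one LRTs use the
deviance chi-square (adequate at thousands of genes), and pairwise
age-class contrasts use Tukey–Kramer on the equivalent least-squares fit.
Age is coded categorically (ordinal coding would impose a monotone
spacing the data should be allowed to contradict). Bootstrap CIs for
age-class means are percentile intervals. Gene-set enrichment is a flat
two-sample KS test of members vs non-members with unadjusted p-values —
deliberately simpler than ontology-graph-aware methods, and read
accordingly.

## The synthetic-data generator

`simulate_experiment()` emulates the sampling design: five stages × 6
colony replicates (both configurable), each colony sampled once,
contributing one pooled worker-destined larva sample, one stage-specific
nurse head and abdomen, and one random-nurse head and abdomen. Colony
labels are replicate-block labels reused across stages, which is what
makes the stage + replicate screen estimable; queen presence is
randomised balanced across colonies and has no expression effect, so the
queen screen is a true null.

Planted structure and the reasoning behind the defaults:

* **Module blocks.** Half the genes (`planted_module_fraction = 0.5`,
  echoing the observation that shared modules hold roughly half to
  three-quarters of expressed genes) follow one of
  `n_planted_modules = 8` distinct trajectories drawn from profiles with
  dynamic range ≥ 2 log2 units — developmental series concentrate
  co-expressed genes in a handful of strong programmes, and shallow
  oscillatory shapes are left to the noise background. Nurse profiles
  equal the larval profile or its negation
  (`antiparallel_fraction = 0.3` per nurse tissue). Abundance is
  `baseline * 2^(profile[s] + N(0, profile_noise_sd))` with log-normal
  baselines (median ~55 FPKM) and `profile_noise_sd = 0.25` absorbing
  pooling variance (pools are modelled as a single noisy draw per
  colony).
* **Random nurses** are modelled as abundance-space pools of
  `pool_size = 10` nurses, each expressing the profile at her own
  uniformly drawn fed stage, so no stage trend survives the average.
  Stage draws are independent per gene, matching the gene-independence
  the permutation null assumes; a real pool shares one stage mix across
  genes, which induces weak block correlation this generator
  deliberately omits (see limitations).
* **Regulatory edges** are cross-tissue (nurse-head regulator → larval
  target) and within-tissue (larva → larva) effects injected at the
  colony level: the target's log2 abundance gains
  `regulator_effect_size` (default 1) times the regulator's realised
  colony deviation. This is exactly the covariation meta-sample inference
  can see — time-lagged dynamics are intentionally not simulated, since
  the developmental spacing makes lags unobservable at this design.
  Edge targets are disjoint from planted-module genes so each planted
  structure is individually recoverable.
* **Annotations.** A latent sociality score (social-regulator indicator −
  within-regulator indicator + N(0, 0.5)) drives constraint via a
  Gaussian copula targeting `rho_sociality_constraint` (default −0.2,
  the order of magnitude reported for such correlations), age classes by
  quantile cuts (40/25/20/15% ancient/insect/hymenoptera/ant) on a noisy
  copy of the score — so ancient genes are least social — and a secreted
  flag with log-odds increasing in the score from a 10% base rate. Five
  percent of constraint and age values are masked to exercise pairwise
  deletion.

What passing tests on this generator do **not** show about real data: the
generator has no compositional/normalisation artefacts, no count noise or
mean–variance trend, no correlated gene blocks beyond the planted
modules, no batch effects, and its regulatory effects are linear and
colony-level. Recovery results are therefore upper bounds on what the
same pipeline achieves on real sequencing data.

## Problem sizes and determinism

Desk-scale analyses in the tests and the acceptance script use 600–1000
genes, 5 × 6 colonies, 100–1000 permutations, and 100 trees × 10 runs —
sizes chosen so the full validation battery runs on a laptop while
keeping every statistical property measurable; the same code scales to
the full design (10⁴ genes, 1000 permutations, 1000 trees × 1000 runs) by
changing configuration values. Every stochastic step takes an explicit
seed, derived seeds are `seed + offset`, and forests run single-threaded
so repeated runs are bitwise identical; the pipeline manifest records
seeds, parameters and output checksums.

## Known limitations

* Importance scores are not tested edge-wise for significance; only
  aggregate connectivity is interpreted.
* The permutation null treats genes as independent; correlated gene
  blocks inflate the variance of module counts and the binomial test is
  anti-conservative for strongly co-expressed blocks (mitigated here by
  judging sharing, not single-tissue enrichment alone, and quantified by
  the jackknife).
* Directionality of co-expression (nurse → larva vs larva → nurse) is
  not identifiable from this design; "social" edges are directional only
  in the random-forest sense.
* The Gaussian-on-asinh screen is a pragmatic working model for
  FPKM-like input, not a replacement for count models when counts are
  available.
* Real paired transcriptomes show a within/social connectivity
  *trade-off* (genes central within a tissue are peripheral socially).
  The generator cannot reproduce that sign under its default config:
  planted parallel modules make the same trajectory informative both
  within and across tissues, coupling the two connectivities positively.
  The trade-off is only planted — and tested — in the edges-only
  configuration, where social and within regulators separate cleanly on
  the sociality index.
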