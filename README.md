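# microcoda

Compositional data analysis of microbiome OTU count tables across sample
cohorts, in one coherent workflow.

16S rRNA sequencing yields *relative* counts: the total read depth of a
sample is an instrument artifact, so only the ratios between taxa carry
information. `microcoda` works entirely in the Aitchison geometry of
compositions and is aimed at studies that compare the gut (or any) microbiota
across discrete cohorts — age groups, sites, treatments — with hundreds of
samples and hundreds of OTUs.

## What it computes

For a count matrix `X` (samples × OTUs) with per-sample depth `n_s`:

- **Zero replacement and clr.** Zeros are imputed with the
  count-zero-multiplicative rule `δ_sj = prior/n_s` (non-zeros shrunk
  multiplicatively to preserve closure), then the centered log-ratio
  transform `clr(x)_j = log₂ x_j − mean_j log₂ x_j` maps each sample into a
  zero-sum Euclidean space. Distances there are **Aitchison distances**.
- **Dirichlet Monte-Carlo instances.** Each sample's unobserved composition
  is drawn `K = 128` times from `Dirichlet(counts + 0.5)`; every inferential
  statistic is reported as its expected value over these clr-transformed
  instances, which propagates count uncertainty for rare OTUs.
- **Ordination.** SVD of the column-centered clr matrix: form biplots
  (sample distances ≈ Aitchison distances) and covariance biplots (loading
  length ≈ OTU clr standard deviation), plus Ward.D2 clustering.
- **Differential abundance.** The expected standardized effect size per OTU
  and group pair: `effect = E[ median( (x_B − x_A) / max(|x_A − x_A'|, |x_B −
  x_B'|) ) ]` over resampled sample pairs and Dirichlet instances.
  `|effect| ≥ 1` means the between-group difference exceeds the within-group
  dispersion.
- **Proportionality.** The symmetric association metric
  `ρ(i,j) = 1 − var(x_i − x_j)/(var x_i + var x_j)` on clr columns, averaged
  over instances; pairs with `E(ρ) > 0.65` form threshold-graph clusters of
  concordant OTUs, with slope/correlation diagnostics per pair.
- **Community statistics.** PERMANOVA (pseudo-F, R², permutation P) and
  within-group dispersion (median/IQR distance to centroid) on the Aitchison
  distance; Shannon diversity with a read-depth confounding check and a
  loess-style age trend.
- **Synthetic data.** A Dirichlet-multinomial generator with known spiked
  OTUs, proportional OTU blocks, lognormal depths and realistic sparsity, so
  every stage has a ground truth to test against.

## Worked example

```r
library(microcoda)
spec <- synthetic_spec(n_groups = 3, samples_per_group = 40, n_otus = 120,
                       group_shifts = data.frame(group = 3, otu = c(8, 21),
                                                 shift = c(3, -3)),
                       proportional_blocks = list(c(5, 15, 25)), seed = 7)
sim <- generate_table(spec)                      # counts + metadata + truth
tab <- filter_otus(sim$table, filter_spec())     # >0.1% anywhere, >=20% prevalence
clr <- clr_from_counts(tab)                      # CZM zeros + clr (log2)
pca <- compositional_pca(clr)
mc  <- dirichlet_instances(tab, K = 128, seed = 42)
eff <- pairwise_effects(mc, tab$metadata$cohort, pairs = "successive", seed = 43)
rho <- expected_rho(mc)
sel <- select_explanatory(eff, rho)              # effect >= 1 OR E(rho) > 0.65
pm  <- permanova(aitchison_distance(clr), tab$metadata$cohort,
                 n_permutations = 999, seed = 44)
```

Output (abridged):

```
count_table: 120 samples x 114 OTUs
compositional PCA: 120 samples, 113 components
  variance explained: PC1 17.4%, PC2 9.4%
     otu_id     pair diff_btw diff_win effect
135 otu_021 G2 vs G3   -2.807    0.771 -3.785
122 otu_008 G2 vs G3    2.872    0.809  3.689
   otu_id reason max_abs_effect max_rho
1 otu_005    rho        0.03740   0.858
2 otu_008 effect        3.68943   0.143
3 otu_015    rho        0.00154   0.987
4 otu_021 effect        3.78518   0.120
5 otu_025    rho        0.04981   0.987
PERMANOVA: pseudo-F = 6.138 (df 2, 117), R2 = 0.0950, P = 0.001 (999 permutations)
```

Reading it: the two OTUs spiked by ±3 log₂ units in cohort G3 are the only
ones with `|effect| ≥ 1` (3.7–3.8, i.e. the group difference is ~3.7× the
within-group spread), and the planted proportional block {otu_005, otu_015,
otu_025} is exactly the set selected through `E(ρ) > 0.65` — 5 of 5 planted
features recovered with zero false selections. The cohort term explains 9.5%
of the Aitchison-distance variance at the smallest attainable P.

A one-command version of the same flow:

```sh
Rscript inst/cli/microcoda.R simulate --fixture spiked --dir fix/
printf 'counts: fix/counts.tsv\nmetadata: fix/metadata.tsv\nout_dir: out\n' > cfg.txt
Rscript inst/cli/microcoda.R run --config cfg.txt
```

which writes effect tables, ρ edges and clusters, PERMANOVA + dispersion,
diversity TSVs, PNG figures, and a `provenance.json` under `out/`.

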