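---
title: "Methods: compositional analysis of cohort microbiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional analysis of cohort microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

An OTU count table from amplicon sequencing carries only relative
information: each sample is a multinomial draw, at an arbitrary depth, from
an unobserved composition. `microcoda` treats the data accordingly. Every
analysis runs on one of two representations:

1. **The deterministic clr path.** Zeros are replaced by the
   count-zero-multiplicative rule — a zero in sample $s$ becomes
   $\delta_{sj} = \pi / n_s$ (prior mass $\pi = 0.5$, depth $n_s$), and the
   non-zero proportions are shrunk by $1 - z_s \delta_{s}$ ($z_s$ = number of
   zeros) so the row still closes to 1 — followed by
   $\mathrm{clr}(x)_j = \log_2 x_j - \overline{\log_2 x}$. This path feeds
   exploratory ordination, Ward clustering, PERMANOVA, dispersion, and the
   pair diagnostics, where a single reproducible point estimate is wanted.
2. **The Dirichlet Monte-Carlo path.** For inference, each sample's
   composition is drawn $K = 128$ times from
   $\mathrm{Dirichlet}(\text{counts} + 0.5)$ and clr-transformed; a statistic
   is reported as its arithmetic mean over instances ("expected value").
   This propagates the large relative uncertainty of low-count OTUs: an OTU
   observed 0–2 times cannot fake a stable large effect or a stable
   proportionality, because it fluctuates across instances.

Both paths exist because exploratory figures need a single embedding while
inference needs the posterior spread; which one a published ordination used
is often ambiguous, so both are exposed (`clr_from_counts()` vs
`dirichlet_instances()`).

Assumptions: samples are independent; within a cohort they are exchangeable;
taxa interact only through the composition (no phylogenetic covariance
model); depth is ignorable given the composition (checked empirically by
`depth_diversity_check`).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `prior_mass` | 0.5 | pseudo-counts/cell | Jeffreys-style prior; the convention of expectation-based differential-abundance tools |
| `K` | 128 | instances | effect/ρ Monte-Carlo error well below the decision thresholds; doubling K changes effects by ≪0.05 |
| `log_base` | 2 | — | effects read as fold-change doublings; ρ, PCA fractions and PERMANOVA are base-invariant |
| `min_prop_any` | 0.001 (strict >) | fraction | drops OTUs never exceeding 0.1% anywhere |
| `min_prevalence` | 0.2 (inclusive ≥) | fraction of samples | drops OTUs absent from >80% of samples |
| `effect_cut` | 1 | log₂ std. difference | between-group difference ≥ within-group dispersion |
| `rho_cut` | 0.65 (strict >) | — | proportionality strong enough that ratio variance < 35% of summed variances |
| `cluster_min_size` | 3 | OTUs | isolated pairs are too easily produced by noise |
| `n_permutations` | 999 | — | PERMANOVA/Spearman p resolution 0.001, add-one corrected |
| `span` | 0.75 | fraction of points | default local-regression window for age trends |

## Numerical and design choices

- **Filter conventions.** "greater than 0.1%" is read strictly (`>`), "at
  least 20%" inclusively (`≥`). Proportions are always computed against the
  sample's *original* depth, so the retained OTU set is independent of the
  order in which filters are applied and `filter(filter(x)) = filter(x)`
  exactly. Prevalence counts strictly positive cells.
- **Effect size.** The statistic is the median paired between-group clr
  difference divided by the elementwise max of the two within-group absolute
  differences, averaged over instances. Group sizes are equalized by uniform
  resampling with replacement (never truncation); a resampled within-group
  partner is redrawn if it coincides with its mate, so the denominator is
  never identically zero. The effect threshold is applied inclusively
  (`|effect| ≥ 1`). Exact antisymmetry under swapping the pair is guaranteed
  by computing on the sorted pair and flipping the sign.
- **ρ.** The symmetric form $1 - \mathrm{var}(x_i - x_j)/(\mathrm{var}\,x_i +
  \mathrm{var}\,x_j) = 2\,\mathrm{cov}/(\mathrm{var}\,x_i+\mathrm{var}\,x_j)$
  with unbiased ($n-1$) variances; ρ itself is denominator-convention
  invariant, the slope/corr diagnostics are not (documented here). A
  zero-variance column makes its pairs undefined: they are flagged `NA` and
  carry no graph edges. Clusters are connected components of the
  `E(ρ) > cutoff` graph — the simplest reading of "clusters"; components
  below `min_size` are discarded.
- **Pair diagnostics slope.** The *standardized major axis* slope
  $\mathrm{sign}(\mathrm{cov})\sqrt{\mathrm{var}_y/\mathrm{var}_x}$ is used
  rather than the major-axis (eigenvector) slope: it has the closed form the
  recovery tests verify, and a perfectly proportional pair gives slope 1,
  correlation 1.
- **PCA.** Column (OTU)-wise centering after clr — sample geometry is
  identical to double centering, and loadings stay interpretable as OTUs.
  Components below `max(dim) * max(d) * eps` are dropped; variance fractions
  are renormalized over the retained components and sum to 1. Signs are fixed
  so each component's largest-magnitude loading is positive. Ordination of a
  selected OTU subset *re-closes* the composition to the subset before clr
  (`subset_reclosure_clr`), rather than slicing the full clr matrix.
- **Ellipses.** Group ellipses are normal-theory 75% coverage ellipses
  (radius $\sqrt{\chi^2_{2,0.75}} \approx 1.665$ standard deviations),
  labeled as such; an empirical-quantile alternative was rejected as
  unstable for small cohorts.
- **Ward clustering** delegates to `stats::hclust(method = "ward.D2")`;
  tie-breaking follows hclust's deterministic internal order, which is all
  the reproducibility contract requires.
- **PERMANOVA** computes sums of squares directly from squared distances
  (the Gower-trace identity), with $F = (SS_B/(g-1))/(SS_W/(n-g))$ and the
  add-one permutation p-value, deterministic given a seed. Pairwise results
  are raw (no multiplicity correction) by design. Dispersion uses the exact
  clr-space centroid (with Euclidean/Aitchison distance this is the natural
  center and exactly computable), reporting median and IQR of member
  distances.
- **Shannon diversity** uses natural log; axis labels say "nats".
- **Age trends** use a tricube-weighted local *linear* regression over the
  `span` fraction of nearest points, evaluated on an integer age grid; the
  smoother is exact on linear data, returns the local weighted mean when a
  window degenerates (all ages tied), and is cross-checked against
  `stats::loess(degree = 1)`.
- **Seeds.** One pipeline seed; stage seeds are derived by a stable integer
  hash of (seed, stage name), recorded in `provenance.json`. All RNG use is
  wrapped so the caller's RNG state is untouched.

## What the synthetic generator emulates — and does not

`generate_table()` builds, per sample, a log₂ abundance vector: a shared base
composition (Normal(0, 2) across OTUs — a few dominant and many rare taxa),
plus its cohort's clr shift on spiked OTUs, plus a per-sample block latent
(sd 1.5) shared by each proportional block with small jitter (sd 0.1), plus
independent biological noise (sd 0.5). The vector is closed, optionally
Dirichlet-perturbed (precision θ; θ = ∞ is plain multinomial), and counted
at a lognormal depth (median 3×10⁴). Sparsity emerges from rare OTUs at
finite depth and grows as depth falls.

It deliberately does *not* emulate: phylogenetic correlation between taxa,
batch/run effects, within-cohort age gradients (ages are metadata dressing
unless a gradient is requested), or taxonomic realism (lineages are
synthetic labels). A green recovery test therefore establishes that the
pipeline detects the stated signal structure at the stated sizes — not that
it is robust to confounders the generator does not model.

Fixture sizes are part of the stated world: the null and spiked operating
characteristic fixtures use 2×50 samples at depth 10⁴ with 100 OTUs (the
post-filter scale of a typical 16S data set); the planted-block fixture uses
2×200 samples so that block proportionality survives counting noise at
moderate abundances.

## Limitations

- PERMANOVA is one-factor; no strata/nested designs.
- ρ clusters are connected components: one spurious bridging edge can merge
  two true blocks (a complete-linkage alternative would trade that for
  splitting).
- The CZM variant implemented is the simple depth-scaled rule; Bayesian
  multiplicative variants with column-informed priors are out of scope.
- Effect sizes are reported without p-values by design; users wanting error
  rates should use the operating-characteristic simulations as calibration.
- The full-size cohort reproduction (≈1,100 samples) requires the original
  deposited table and is not part of the offline test surface.
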