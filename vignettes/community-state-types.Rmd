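---
title: "Community state typing and co-occurrence networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community state typing and co-occurrence networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cstnet)
```

`cstnet` turns a species-level relative-abundance table into (i) a set of
community state types (CSTs) with high prevalence clusters (HPCs) flagged
among them, (ii) a ranked list of driver taxa, and (iii) signed
co-occurrence networks. This vignette explains the statistical model
behind each stage, the parameters that matter, and the design choices
made where several defensible readings existed.

## Input model and assumptions

The universal currency is a samples × species table of relative
abundances: every row is non-negative and sums to 1 (`read_abundance()`
renormalizes unconditionally, so tables whose unclassified fraction was
removed upstream are handled transparently; the operation is idempotent).
Species absent from a sample are explicit zeros, never missing values.
All downstream methods assume this compositional scale — fractions
internally, percentages only in printed summaries — which avoids
double-scaling bugs when results flow between modules.

Two caveats follow from compositionality. First, relative abundances of
different species are not independent: the closure to 1 induces weak
negative correlation of order −1/(S−1) for S species, which is negligible
at S ≈ 330 but visible in small synthetic tables. Second, rank
correlations between species measure co-variation of *relative*, not
absolute, abundance; `cstnet` deliberately implements plain rank
correlation (see below) rather than compositionality-aware network
inference, which is out of scope.

## Community state typing

Samples are clustered by agglomerative hierarchical clustering on the
correlation distance `1 − r`, where `r` is the Pearson correlation
between two samples' abundance profiles across **all** species (no
prevalence filter at this stage). Average linkage (UPGMA) is the
default: the clustering tool classically used for this analysis defaults
to it, and it is the conventional compromise between single-linkage
chaining and complete-linkage fragmentation. Complete and Ward linkage
are available through the `linkage` argument.

The number of clusters is selected by the silhouette criterion: one
dendrogram is fitted, cut at every `k` in `k_range` (default `2:15`,
wide enough to bracket the ~10 states typically reported for gut
cohorts of this size), and each partition is scored by the mean
silhouette width computed **on the same `1 − r` distances** used for
clustering. Evaluating the criterion on the clustering metric — rather
than on a Euclidean embedding — keeps model selection internally
consistent; this was a genuinely open choice and is the package's
documented convention. The selected `k` maximizes the mean silhouette,
with ties broken toward the smaller `k` (prefer the simpler model).
Silhouette conventions for degenerate cases: singleton clusters score 0,
and a sample with `a = b = 0` (all points coincident) scores 0.

Cluster ids are relabelled contiguously by decreasing size, so cluster 1
is always the most prevalent. `identify_hpcs()` flags clusters holding
at least `min_prevalence` of the samples (default 0.15, inclusive —
"at least 15 %") and reports their collective coverage;
`group_composition()` adds per-cluster group fractions.

## Driver taxa

`variance_explained()` quantifies, per species, how much inter-sample
variability the CST structure explains. The default design regresses
each species' abundance on indicator-coded cluster membership — a
one-way ANOVA design with `p = k − 1` predictors — and reports

`adj R² = 1 − (1 − R²)(n − 1)/(n − p − 1)`.

For a categorical predictor, polynomial terms are vacuous, so the
indicator coding is the natural reading of a "variance explained by each
species against the cluster structure" screen. A second mode
(`mode = "pcoa_poly"`) regresses abundance on powers `1..degree` of the
first principal coordinate of the Bray-Curtis distances, for users who
prefer a continuous-gradient reading. Both are exact least-squares fits;
zero-variance species report `adj R² = 0` with a note rather than an
error.

Drivers are the species with `adj R²` **strictly** greater than the
threshold (default 0.15). `driver_coverage()` reports, per cluster, the
percent of composition the drivers account for — by default the mean
over member samples of the summed driver abundance, with a pooled-ratio
variant available (`mode = "pooled"`); the two coincide for normalized
rows up to sample weighting. Per-taxon group differences use Welch's
unequal-variance t-test (abundance variances differ strongly between
groups, and the pooled test's equal-variance assumption buys nothing
here), with optional Benjamini-Hochberg adjustment that is off by
default to match per-taxon reporting practice.

## Diversity and PERMANOVA

Alpha diversity is threshold richness: the number of species strictly
above a relative-abundance cutoff. The default cutoff is 0.005 (0.5 %);
0.0005 (0.05 %) is a widely used alternative convention and both are
plain arguments, since reported analyses differ in which they use.

Beta diversity is Bray-Curtis, `1 − Σ min(pᵢ, qᵢ)` for normalized
profiles. PCoA Gower-centers `−d²/2` and eigendecomposes; axes with
eigenvalue ≤ 1e-10 are dropped, and negative eigenvalues (Bray-Curtis is
non-Euclidean) are excluded from the variance-explained denominator
rather than corrected by Lingoes/Cailliez — no correction is asserted
because none is standard for this analysis. Each axis is oriented so its
first nonzero coordinate is positive, making signs reproducible.

PERMANOVA uses Anderson's distance-based pseudo-F with free permutation
of labels (a `strata` argument restricts permutation within, e.g., study
of origin). The Monte-Carlo p-value uses the `+1/+1` convention —
`p = (1 + #{F* ≥ F})/(B + 1)` — which cannot return 0 and is valid at
finite B; ties count as exceedances (conservative). `permutations =
"all"` switches to exhaustive enumeration for small n, where the p-value
is the exact proportion of label orderings (identity included) with
`F* ≥ F`.

## Co-occurrence networks

Kendall's tau-b is the default association measure:
`τ_b = (C − D)/√((n₀ − n₁)(n₀ − n₂))` with tie corrections in both
margins. P-values are exact (dynamic-programming enumeration of the
inversion-count null) for n ≤ 10 without ties, and otherwise use the
normal approximation with tie-corrected variance and continuity
correction. Spearman correlation is available as an alternative engine
(`method = "spearman"`), since both measures appear in practice for this
analysis. For all-pairs testing the package computes the exact `C − D`
counts for every pair via one cross-product of per-column pairwise sign
vectors, which keeps a 330-species table tractable in seconds.

Species enter the network if present (abundance > 0) in at least
`min_prevalence` of the samples (default 0.2): rarely observed taxa
produce tie-degenerate rank statistics and their "edges" are mostly
artifacts of shared zeros. All retained pairs are tested, p-values are
Benjamini-Hochberg adjusted **across all tested pairs**, and edges with
q ≤ `alpha` (default 0.05) are kept, signed by the sign of τ. Raw-p
filtering is available via `correction = "none"` because published edge
counts do not always state a multiplicity rule.

Modules are found by greedy (fast-greedy) modularity maximization on the
graph weighted by |τ|: signed modularity is not a settled convention, so
the magnitude enters the weights and the sign stays an edge attribute.
The greedy merge path can terminate at a locally optimal split with
Q below that of the connected-components partition (whose Q is always
≥ 0); in that case the components partition is returned, so the reported
Q never falls below the trivial baseline. Keystone taxa are ranked by
degree, with ties broken by higher mean abundance and then species name,
making the ordering fully deterministic.

## The synthetic-cohort generator

`cohort_config()` describes the statistical structure the analysis
assumes, and its defaults are fixed at the conditions of a ~200-sample
athlete / non-athlete fecal meta-analysis profiled to species level:

* 207 samples × 330 species, 3 community states with weights
  (0.30, 0.40, 0.30) — chosen so the marginal athlete fraction
  `Σ wₛ·P(athlete | s) ≈ 0.49` matches a 100 / 107 athlete / non-athlete
  split;
* per-state dominant taxa with target mean abundances 43.9 % (a
  Prevotella-like state), 17.5 % + 5.9 % (a Bacteroides-like state) and
  15.2 % + 14.4 % + 7.1 % (a Faecalibacterium/Eubacterium-like state),
  converted internally to Dirichlet concentration boosts;
* athlete-label probabilities (0.52, 0.18, 0.87) per state;
* a symmetric Dirichlet background with concentration 0.1 — sparse,
  highly individual profiles of the kind stool metagenomes show;
* six planted rank correlations (three positive, three negative) of
  Gaussian-copula strength 0.8 between background taxa.

Each sample is a Dirichlet draw implemented through independent gamma
variates; planted pairs replace their two gamma draws with
copula-coupled ones (bivariate normal → uniform → gamma quantile), which
imposes rank dependence of the configured sign and strength while
leaving both marginals untouched. With `depth > 0`, multinomial read
counts are drawn and renormalized, adding sampling graininess and zeros.
The planted truth (state labels, driver taxa, edges) is a first-class
output so validation code never reaches into generator internals.
`generate_null_cohort()` produces exchangeable, structure-free samples
for calibration.

What the generator does **not** emulate: phylogenetic correlation among
related species, sequencing-protocol batch effects, taxonomic
misclassification, and compositional effects of absolute-load shifts.
Tests passing on these cohorts therefore demonstrate that the pipeline
recovers the structures it models — recurrent dominance patterns,
group-state association, planted dependence — not that it is robust to
every artifact of real metagenomes.

## Validation strategy and problem sizes

The test suite follows a dual-route principle: every core statistic is
checked against an independent brute-force oracle (literal pair counting
for τ, a double-loop silhouette, pair-sum PERMANOVA F with a separately
generated exhaustive permutation set), against an established package
where one exists (`vegan::adonis2`, `cluster::silhouette`, `ape::pcoa`,
`stats::cor.test`, `mclust::adjustedRandIndex`), and by calibration and
recovery simulation. Simulation sizes were chosen to give stable
rates at interactive runtimes: 500 null cohorts of n = 30 for PERMANOVA
type-I error (199 permutations, so attainable p-values align exactly
with α = 0.05), 200 null datasets for t-test calibration, 20 seeds of
the full 207 × 330 cohort for state/driver recovery and 10 for network
recovery.

## Known limitations

* Pearson-correlation distance treats abundances on their raw scale;
  dominant taxa dominate the metric. That matches the target analysis
  but differs from log-ratio approaches.
* PERMANOVA is one-factor; confounding between group and study must be
  addressed through `strata`, not through covariate adjustment.
* Rank-correlation networks on compositions can reflect closure rather
  than ecology when few species carry most of the mass; the prevalence
  filter mitigates tie artifacts but not compositional coupling between
  dominant taxa.
* Greedy modularity is a heuristic; it is deterministic here, but for
  small or nearly tied structures the returned partition is a local
  optimum.
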