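---
title: "Partitioning the drivers of microbial beta-diversity"
author: "commassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning the drivers of microbial beta-diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commassembly)
```

# The problem

Along a long environmental gradient, the compositional turnover
(β-diversity) of a microbial guild can arise from very different causes:
the regional species pool may simply differ in size (a γ-diversity
effect), the environment may select different taxa at different sites
(variable selection) or the same taxa everywhere (homogeneous selection),
dispersal may be too slow to homogenize communities (dispersal
limitation) or strong enough to erase local differences (homogenizing
dispersal), and pure demographic stochasticity (ecological drift) fills
the rest. This package chains the standard inferential tools that
separate these causes — distance-decay regressions, a random-sampling
species-pool test, βNTI/RC~bray~ null models, co-occurrence networks as a
proxy for biotic interactions, and multiple regression on distance
matrices (MRM) — into one tested, deterministic pipeline, and pairs them
with a generator of synthetic datasets assembled under each process at a
known strength, so every claim the pipeline makes can be checked against
a known truth.

# Data model and upstream boundary

The pipeline starts from an ASV count table (samples × taxa,
non-negative integers), a rooted phylogeny with branch lengths covering
the taxa, and per-sample metadata (region, steppe type, site, longitude,
latitude, environmental variables). Read denoising, frameshift checking
and taxonomic filtering are upstream of this package. The only
sequence-processing step retained is rarefaction: global singletons
(total count 1 across the table) are removed first, then every sample is
subsampled without replacement to a fixed depth — 800 reads by default,
the conventional depth for low-yield functional-gene surveys; samples
below the depth are dropped with a warning.

# The diversity layer

Bray–Curtis is computed from the formula
$BC(x,y)=\sum_j |x_j-y_j| / \sum_j (x_j+y_j)$; βMNTD is the
abundance-weighted mean patristic distance from each taxon to its
nearest relative in the other community. Shared taxa contribute zero by
construction (their nearest relative is themselves), which is what makes
βMNTD sensitive to *membership* turnover rather than abundance shifts.
Per-sample β-diversity is the distance to the group centroid in a
principal-coordinates embedding, with the standard imaginary-axis
correction for negative eigenvalues (computed via `vegan::betadisper`,
whose per-sample values the γ–β test consumes). γ-diversity is the
bias-guarded Chao2: $S_{obs} + \frac{N-1}{N} Q_1^2 / (2 Q_2)$ when
$Q_2>0$, else $S_{obs} + \frac{N-1}{N} Q_1 (Q_1-1)/2$.

# Distance decay

The decay of similarity with distance is fit by OLS of unfolded
lower-triangle dissimilarity on raw great-circle kilometres (haversine,
Earth radius 6371.0088 km). Slopes are small numbers of order 10⁻⁴ per
km, so distances are deliberately left untransformed; a log-distance
option exists. Pairwise observations are not independent: the parametric
p-value is reported as nominal, flagged as such, and a Mantel-style
permutation p (sample-label permutations) is available. Slope contrasts
between groups come from a single pooled model
`dissimilarity ~ 0 + group + distance:group`: the saturated coding makes
each group's marginal slope identical to its own separate regression,
while the shared residual variance gives the t-tests their degrees of
freedom (P pooled pairs − 2 × groups parameters). An optional `"All"`
pseudo-group enters the same pooled model with every pair; its
comparisons overlap the named groups and are flagged non-disjoint.

# The species-pool test

If local communities were random samples of the pool, β-dispersion would
rise with pool richness γ in a way that is fully computable: we draw pool
relative abundances (lognormal σ=1 by default; uniform as the analytic
sanity limit), assemble communities multinomially at the rarefaction
depth, and record Bray–Curtis β-dispersion over many replicates. The
observed counterpart regresses per-group Chao2 γ against mean
β-dispersion. The verdict is `"pool-driven"` only when the observed
relationship is significantly positive *and* its slope falls inside the
expected curve's 95 % Monte-Carlo band; everything else — negative,
absent, or out-of-band relationships — is `"decoupled"`, shifting the
explanatory burden to assembly processes. The regression unit (site,
region, steppe) is an explicit grouping key.

# Null models and the five-way classification

βNTI standardizes observed βMNTD against a null in which taxa are
reassigned to uniformly random tips of the **whole supplied tree** once
per replicate (all pairs share each replicate's shuffle; statistically
equivalent to per-pair shuffles and ~n² cheaper). The tree may hold more
tips than the table has taxa — it then plays the role of the reference
phylogeny from which the regional pool derives. RC~bray~ builds null
communities that preserve each sample's richness and read total:
membership is drawn without replacement proportional to occupancy, reads
are allocated multinomially proportional to total relative abundance
(one read guaranteed per member). One null community per sample per
replicate is shared across pairs — the same economy as the βNTI shuffle —
and ties count one half. Classification follows the published
thresholds: |βNTI| > 2 selection (sign decides variable vs homogeneous),
otherwise RC > +0.95 dispersal limitation, RC < −0.95 homogenizing
dispersal, |RC| ≤ 0.95 drift. Degenerate pairs (null spread below
10⁻⁶·(1+|μ|), e.g. on a star phylogeny) are flagged and scored 0; pairs
with fewer than two taxa in their union are flagged unevaluable.

# Networks and MRM

Taxa above 0.01 % overall relative abundance enter pairwise Spearman
correlations (mid-rank ties; p from the t approximation, BH-adjusted).
The edge cut-off is chosen by random-matrix theory: scan candidate
thresholds, unfold the thresholded matrix's eigenvalue spectrum with a
cubic smoothing spline on the cumulative spectral density (duplicate
eigenvalues dropped — they carry no spacing information), and accept the
smallest threshold whose nearest-neighbour spacing distribution is
consistent with the Poisson law by a KS test (p > 0.05) — the
Wigner→Poisson transition. When no candidate qualifies the configured
fallback 0.68 is used with a warning. Edges additionally require
FDR-adjusted p < 0.001. Topology (path length over connected pairs,
mean local clustering with zero for degree-<2 nodes, connectance,
greedy-modularity modules) is computed on the unweighted graph —
correlation weights can be negative and must not enter shortest paths.
Because MRM needs a sample × sample matrix while networks are built per
group, each sample receives the topology vector of the subgraph induced
by its own taxa; per-sample vectors are z-standardized per property and
compared by Euclidean distance (group-level vectors remain available).

MRM regresses the unfolded β matrix on unfolded predictor matrices;
significance comes from jointly permuting the rows and columns of the
response (preserving the distance-matrix dependence structure), with
$p = (1+\#\{stat_{perm} \ge stat_{obs}\})/(1+n_{perm})$, one-tailed on
R². The attribution suite runs three single-predictor families per
group: β ~ βNTI (signed values as-is; |βNTI| optional), β ~ topology
distance, and β ~ per-variable Euclidean distance of the z-scored
environmental variable — one R² per variable, ranked.

# The synthetic generator: what it emulates

`assembly_scenario()` encodes a three-region east–west transect survey:
10 sites per region at ≥ 80 km spacing (site spacing carries a 25 %
margin over the floor), 4 quadrats per site jittered ≤ 0.001°, 120
samples in the default design. Environmental variables are linear in
site longitude plus noise, with region-level means matching steppe
climatologies (MAT 9.13 / 2.52 / −3.02 °C; MAP 466 / 313 / 429 mm; AI
0.31 / 0.22 / 0.30; pH 8.06 / 7.96 / 7.81) and steppe type assigned by
the within-region aridity tercile (desert / typical / meadow). Default
read depth is 2,000 so rarefaction to 800 always succeeds.

Communities are multinomial draws from per-sample taxon weights built
from interpretable pieces:

* a **shared lognormal abundance term** (log-sd 2 — a heavy-tailed
  species-abundance distribution that yields realistic partial
  occupancy, which the RC null needs to have any membership randomness);
* **per-sample drift noise** (log-sd 0.3). This is deliberately small: the
  RC~bray~ null has no analogue of weight noise, so large drift pushes
  every observed pair outside the null band and reads as dispersal
  limitation rather than drift;
* process-specific terms. *Variable selection* penalizes log-weights by
  −strength·(trait − env)² with env the z-scored selective variable
  (MAT by default); *homogeneous selection* uses a constant optimum one
  SD above the gradient mean — a spatially uniform harsh environment
  favouring one tolerant clade — and additionally filters the regional
  pool itself by the same penalty; *dispersal limitation* multiplies
  weights by a Gaussian kernel around random home sites with scale
  500 km / strength; *homogenizing dispersal* pulls samples toward their
  region's pooled vector (regional vectors diverge with log-sd
  strength/(1+strength), and within-region noise shrinks by
  1/(1+strength)).

Two design choices deserve emphasis because they decide whether
phylogenetic null models can see selection at all:

* **Selection acts on a colonization lottery.** Under both selection
  processes the regional-abundance ranking is progressively replaced
  (mixing weight strength/(1+strength)) by an independent per-sample
  lottery (log-sd 2.5). Without it, selection makes all communities
  identical, and pairwise null models — which only see membership and
  abundance *differences* — have nothing to detect. Ecologically this is
  priority effects among environmentally permitted taxa.
* **Niche conservatism is deep.** Environmental optima follow a
  Brownian-motion trait simulated on the tree with an early-burst
  transform (evolutionary rate decaying as exp(−20·t/T)), so optima are
  nearly constant within deep clades and differ between them.
  `trait_conservatism` blends this trait with an i.i.d. one. We verified
  during design that with shallow conservatism (plain Brownian motion on
  small pools) trait isoclines are polyphyletic and βNTI is essentially
  blind to selection — an instructive negative result that also applies
  to real data: βNTI only works where niches are conserved at clade
  depth.

`strength = 0` reduces every process to neutral drift (enforced by the
constructor), and every output is bit-deterministic given the scenario
seed.

**What the generator does not emulate:** sequencing error and chimeras,
compositional biases of PCR, temporal dynamics, interaction-driven
co-occurrence (network edges in synthetic data reflect shared
environmental responses, not true biotic interactions), and the
taxonomic richness of real pools (hundreds to thousands of ASVs).
Passing recovery tests therefore show that the inference machinery is
correct and well calibrated at small scale — not that real soil data
meet the assumptions (deep conservatism above all).

# Problem sizes and numerical choices

The test suite runs at sizes chosen to make the statistical checks sharp
yet quick: metric oracles on 20 random 10 × 30 tables; null-model
calibration on 20 membership-randomized 30-sample × 80-taxon tables with
999 nulls; process recovery on 24-sample (3 regions × 2 sites × 4
quadrats), 60-taxon scenarios at strength 10 with a 360-tip reference
tree, depth 800 and 499 nulls, 20 seeded replicates per process. In the
recovery runs βMNTD is presence-weighted (`abundance_weighted = FALSE`,
the original formulation of the nearest-taxon index): abundance
weighting concentrates the statistic on the few unshared taxa of a pair,
which bounds how negative βNTI can get on small pools
(≈ −1 / CV of the null); presence weighting restores the effective
sample size. The package default remains abundance-weighted, matching
the framework the classification thresholds come from.

Other numerical decisions: βNTI null moments are accumulated by running
sums with a relative degeneracy floor of 10⁻⁶·(1+|μ|) (cancellation
dust on exactly-invariant trees); RC ties use a 10⁻¹² tolerance;
RMT unfolding uses a df-10 smoothing spline; modularity uses the
deterministic greedy algorithm so repeated runs agree bit-for-bit;
environmental predictors with missing values drop samples pairwise with
a message.

# Known limitations

The parametric DDR p-values ignore pair non-independence (flagged; use
the permutation option for honest inference). The RC null is shared
across pairs within a replicate, which leaves pair-to-pair correlations
in the null draws — the marginal null distribution per pair is
unaffected. The per-sample network-topology construction is one
defensible answer to an under-determined problem (any mapping from
group-level networks to sample-pairwise distances involves a choice);
the group-level alternative is exposed. Homogeneous selection remains
the hardest process to recover at small pool sizes even with deep
conservatism — its βNTI signal is the weakest of the four, a property of
the statistic rather than of this implementation.
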