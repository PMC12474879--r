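---
title: "Methods: subcommunity assembly, networks and multifunctionality along a restoration chronosequence"
author: "chronosere"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: subcommunity assembly, networks and multifunctionality}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`chronosere` analyses soil bacterial communities sampled along a restoration
chronosequence — sites of increasing restoration age sampled simultaneously
as a space-for-time substitution. Starting from an ASV count table, sample
metadata (restoration duration, stage, replicate), a rooted ASV phylogeny
and a table of measured ecosystem functions, it covers: rarity
classification, niche breadth, β-diversity structure, null-model
partitioning of community assembly processes, compositionality-aware
co-occurrence networks, ecosystem multifunctionality, and a piecewise path
model tying these together. A synthetic-data generator with known ground
truth backs every recovery test.

Everything upstream of the count table (read processing, denoising,
taxonomy) is out of scope; the pipeline starts from counts.

# Rarity classification

Taxa are classified purely by mean relative abundance across samples:
abundant above 0.028%, rare below 0.002%, intermediate in between
(boundaries inclusive to intermediate — the inequalities are strict). These
defaults correspond to the plateau a truncation profile locates on the
study system; both thresholds are arguments, and `multicola_profile()`
recomputes the profile on any dataset: ASVs are ranked ascending by total
count and removed until each cutoff fraction of total sequences is
discarded (1–95% by default, ties broken lexicographically), and each
truncated dataset is compared with the original by Spearman correlation of
Bray–Curtis distances and by symmetric Procrustes correlation
(`sqrt(1 - m2)`) of 2-d NMDS configurations. Threshold choice from the
profile is deliberately left to the analyst: the profile is emitted, not
auto-thresholded, because plateau reading on real data needs judgement.

Mean relative abundance is the mean of per-sample proportions (the two
candidate definitions coincide after rarefaction to even depth, which is
the intended workflow; `mode = "pooled"` gives the other reading).

# Niche breadth

Levins' breadth per ASV is `B = 1 / sum(p_i^2)` over its use of resource
states, normalized as `B_N = (B - 1)/(N - 1)`. Resource states default to
stage means rather than raw samples: with five replicates per stage,
per-sample states mostly measure replicate noise. A binned mode
(`levins_breadth_binned()`, five equal-frequency bins per measured
function) treats each function as an environmental gradient instead; both
readings are available because the choice is genuinely open.

The tolerance index places samples in the principal-component space of the
z-scored function matrix (axes with positive eigenvalue retained,
distances Euclidean) and reports each ASV's abundance-weighted mean squared
distance from its abundance-weighted centroid. Weights are the ASV's own
counts normalized to sum one, which makes tolerance exactly invariant to
uniform scaling of that ASV's abundance vector. Full outlying-mean-index
marginality testing is not implemented.

Group comparisons use Kruskal–Wallis with Dunn's post-hoc z tests,
Bonferroni-corrected (p times the number of pairs, capped at one), plus a
compact letter display.

# Community statistics

Bray–Curtis distances come from `vegan`; the Baselga decomposition into
balanced-variation (species replacement) and abundance-gradient components
is computed per pair as `min(B,C)/(A + min(B,C))` and the remainder, so the
two parts sum to the distance exactly. NMDS is Kruskal stress-1 with 20
seeded restarts (convergence tolerance 1e-6). ANOSIM and the Mantel test
are implemented as direct permutation engines (+1-corrected p-values,
optionally with an explicit permutation matrix so small cases can be tested
exhaustively); their statistics are cross-checked against `vegan` in the
test suite. SIMPER contributions use the per-pair identity
`delta_i = |x_i - y_i| / sum_j(x_j + y_j)`, averaged over between-group
pairs.

Richness-versus-duration model selection compares linear, quadratic,
logarithmic (`ln(t + 1)`, so age 0 is admissible) and the restoration curve
`y = a(1 - exp(-k t)) + c` — an initial increase followed by stabilization
— fitted by Levenberg–Marquardt least squares with `a, k > 0`, initialized
from the data range and `k = 1/median(t)`. Models are ranked by Gaussian
AIC, `n ln(RSS/n) + 2p`.

# Assembly processes

βMNTD between two communities is the abundance-weighted mean distance from
each taxon to its nearest taxon in the other community. βNTI standardizes
the observed βMNTD against a null that shuffles taxon labels across *every
tip of the supplied tree* with richness and abundances fixed. The tree
therefore defines the phylogenetic pool: pruning it to the taxa of one
filtered community would make the null blind to exactly the clustering it
is supposed to detect. RC_bray draws both members of a null pair
independently — taxa sampled without replacement with probability
proportional to regional occupancy up to the observed richness, then reads
allocated multinomially by regional relative abundance — and rescales the
percentile of the observed Bray–Curtis distance to [-1, 1].

Pairs are assigned to five processes: variable selection (βNTI > 2),
homogeneous selection (βNTI < -2), and among the rest dispersal limitation
(RC > 0.95), homogenizing dispersal (RC < -0.95) or undominated. All
thresholds are strict. One structural consequence worth knowing: for two
*identical* communities every null βMNTD is also zero (shared taxa keep a
shared shuffled label), so the null sd is zero and βNTI is reported as 0
with a `degenerate` flag rather than as a large negative value.

Null seeds derive from a master seed plus the pair index, so per-pair
results do not depend on evaluation order. Stage-wise analyses use all
within-stage pairs by default (consecutive-stage comparisons exist as the
`pairs` argument of `assembly_analysis()`); within-stage is the reading
that matches replicated stage sampling.

# Co-occurrence networks

Network membership is prefiltered to ASVs whose relative abundance responds
to duration (Pearson, p < 0.05) — "significant temporal change" made
concrete. SparCC estimates basis correlations from log-ratio variances
under a sparsity assumption: per Dirichlet resample of the counts (add-one
smoothing) the linear system for basis variances is solved, the most
strongly correlated pair above 0.1 is excluded and the system re-solved (20
iterations), and estimates are averaged over 100 resamples. Two-sided
pseudo p-values come from bootstrap datasets in which every taxon's counts
are shuffled independently across samples. Edges require |ρ| > 0.3 and
p < 0.05, both strict.

Topology uses standard unweighted definitions (closeness within connected
components). Modules come from greedy modularity maximization (Louvain as
an option); Zi is the within-module degree z-score and Pi the among-module
participation coefficient, with network hubs (Zi > 2.5, Pi > 0.62), module
hubs (Zi > 2.5, Pi ≤ 0.62), connectors (Zi ≤ 2.5, Pi > 0.62) and
peripherals. Robustness removes half the nodes uniformly at random (1000
iterations) and reports the share of survivors that keep at least one edge;
the largest-component share is available as an alternative mode since the
phrase "proportion of remaining nodes" admits both readings. Stage-level
subnetworks are emitted with an explicit warning below ten samples:
correlation estimates from five replicates are weak, and the per-stage
summary should be read as a trend, not as per-edge inference.

# Multifunctionality

Each of the 17 functions (plant productivity: AGB, PC, PN, PP;
decomposition: DNA, Suc, bGlu, Cel, Ure, ALP, Cat; nutrient pools: SOC,
NH4, NO3, STN, SAP, STP) is log10-transformed and z-scored; EMF is the mean
z-score per sample and PPI/DRI/SNPI average the three subsets. Zero raw
values are offset by half the smallest positive value of that function
(reported per column); negative values are an error. ASV–function
associations use raw per-test alpha with no multiplicity correction —
matching the convention of per-function screening in this literature — and
the per-ASV p-value matrix is returned so an FDR re-analysis is one
`p.adjust()` away.

# Path model

The default DAG: duration → cover, pH, EMF; cover and pH → richness;
cover, pH, richness → EMF; richness → degree; degree → EMF. Richness and
degree enter as composites of the three subcommunities' values, weighted by
standardized OLS coefficients against EMF. All variables are z-scored, so
each per-equation OLS yields standardized path coefficients directly.
Goodness of fit is Shipley's d-separation test: for every non-adjacent
ordered pair the topologically later variable is regressed on the earlier
one plus its own parents (conditioning on the parents of the later variable
is sufficient under the local Markov property), and Fisher's
C = -2 Σ ln p is referred to χ² with twice the number of claims. A
covariance-based SEM engine (χ² fit statistic, CFI) is intentionally not
included; the d-separation test is the piecewise approach's native
goodness-of-fit.

# The synthetic generator

`generate_chronosequence()` emulates the study design: 11 stages at 0, 1,
3, 4, 5, 6, 11, 20, 23, 26 and 53 years, five replicates each (55 samples),
a pool of 2000 taxa with lognormal abundances (sdlog 2, so the top 2.5% of
taxa carry over half the reads), a birth–death phylogeny, and 10,000 reads
per sample. A Brownian trait on the tree serves as each taxon's
environmental optimum — the phylogenetic conservatism that βNTI-based
inference presupposes is therefore true by construction, not assumed.
Availability ramps give the abundant tier saturating occupancy in time and
the rare tail a linear climb, reproducing asymptotic versus linear richness
growth. The 17 functions follow a log-linear model in (scaled) duration
response and abundant-tier richness (coefficients 0.25 and 0.8, noise sd
0.5 on the log10 scale), plus plant cover (saturating toward ~45%) and soil
pH (slowly declining) as path-model covariates.

Assembly regimes:

* *homogeneous_selection* — every sample filters taxa toward the same
  optimum, 2 trait-sd from the centre, with filter width 0.25. The optimum
  is deliberately extreme: under Brownian evolution many distant lineages
  hover near the ancestral value, so selection toward the centre produces
  communities that are environmentally filtered yet phylogenetically
  random — undetectable by design. Extreme optima are clade-restricted,
  which is the regime the label promises.
* *variable_selection* — the optimum sweeps from -1.5 to +1.5 trait-sd
  across stages (default regime, width 0.8, giving the stage-separated
  composition the chronosequence shows).
* *dispersal_limitation* — each sample drifts through 15 serial
  founder/regrowth generations (Ne = 1000) with 1–2% migration from the
  pool, producing replicate divergence without phylogenetic structure.
* *drift* — plain multinomial sampling of the pool.

All randomness flows from one master seed through fixed per-substream
offsets (tree, trait, pool, availability, one per sample, covariates,
functions), so outputs are reproducible and any substream can be varied in
isolation.

What the generator does *not* emulate: sequencing error, PCR/primer bias,
compositional depth variation (all samples share one depth), taxon–taxon
interactions, and spatial autocorrelation. Passing tests therefore show
that the estimators recover the processes they target under controlled
conditions with phylogenetic signal present — not that any particular field
dataset satisfies those preconditions.

# Numerical choices and problem sizes

* Permutation p-values use the +1 correction everywhere; null seeds derive
  deterministically from a master seed.
* SparCC basis variances are clipped below at 1e-12; correlations at ±1.
* Composite construction rejects predictor sets with condition number
  above 1e8.
* The test suite runs null-model calibrations at 200 pairs × 999
  randomizations (the regime where the 4–8% and 3–8% two-sided rejection
  bands are meaningful), scenario recovery at the generator's full default
  size with 40 sampled pairs × 199 randomizations, and SparCC simulations
  at 55 samples × 50 taxa — sizes chosen so each check is sharp enough to
  fail if the statistic is miscalibrated while the whole suite stays quick
  to iterate on.
* The acceptance script reruns the same computations from scratch at the
  same sizes and writes all headline quantities as JSON.

# Known limitations

* βNTI inference presumes phylogenetically conserved niches; the package
  does not test that precondition on user data (no Mantel correlogram of
  niche versus phylogenetic distance).
* Stage-level networks from five replicates are descriptive only.
* The rare subcommunity's richness and EMF both track duration in the
  generator's default world, so rare-richness–EMF correlations are
  expected there even though abundant-tier coupling is much stronger;
  distinguishing direct function coupling from shared temporal trends needs
  designs beyond a single chronosequence.
* Composite weights (and hence path coefficients downstream of composites)
  inherit OLS instability when subcommunity richnesses are strongly
  collinear.
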