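---
title: "Coordinated volumetric change: models and methods"
author: "covchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated volumetric change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covchange)
```

# The scientific question

Brain structures that develop together may keep changing together across
the lifespan, under shared genetic control. `covchange` implements the
full analysis chain for testing this on longitudinal volumetric data from
16 hemisphere-averaged structures (ventricles, brainstem, cerebellum,
subcortical gray-matter nuclei, cortical gray and white matter): per-subject
change rates, the region-by-region change--change correlation matrix,
signed-network community detection with stability diagnostics, permutation
and rewired-network significance, cross-sample matrix comparison, and twin
modeling of the genetic contribution to coordinated change.

# Change metrics

For each subject, the change in each region between the first and last
available sessions is summarized as symmetrized percent change,

$$\mathrm{APC} = \frac{V_2 - V_1}{V_2 + V_1} \times 100,$$

optionally (and by default) divided by the follow-up interval in years.
The symmetrized denominator bounds the value in $(-100, 100)$ and makes it
antisymmetric under swapping the two occasions. Annualization is the
default because follow-up intervals in lifespan cohorts commonly range
from a few months to over six years; without it, interval heterogeneity
would dominate between-subject variance and hence the correlations. The
raw (non-annualized) form is available via `annualize = FALSE`.

Subjects contribute one row each; intermediate sessions are ignored by
design (only first and last are used), and single-session subjects are
dropped with a logged count.

The change--change matrix correlates, across subjects, the change of every
pair of regions. Pearson correlation is the default estimator (the
conventional choice for this analysis; Spearman is available). Before
clustering -- and only before clustering -- the mean off-diagonal
correlation is subtracted from every off-diagonal entry
(`demean_offdiag()`), removing the global, brain-wide component of
coordinated change so that modules reflect covariation beyond the common
factor. Matrix comparisons (Mantel tests) always use the raw matrices.

# Signed community detection

The de-meaned matrix is a signed weighted network. Its partition quality
is the asymmetric signed modularity

$$Q = Q^{+} - \frac{v^{-}}{v^{+} + v^{-}}\, Q^{-}, \qquad
Q^{s} = \frac{1}{v^{s}} \sum_{ij}
\left[ w^{s}_{ij} - \gamma \frac{s^{s}_i s^{s}_j}{v^{s}} \right]
\delta(c_i, c_j),$$

where $w^{+}$/$w^{-}$ are the positive part and the magnitude of the
negative part of the weights, $s^{s}_i$ node strengths, $v^{s}$ total
strengths, and $\gamma$ the resolution parameter (multiplying both null
terms). Positive within-module weight counts in full; avoiding negative
weight inside modules is rewarded only in proportion to the negative share
of total strength. The all-in-one partition has $Q = 0$ exactly at
$\gamma = 1$, and $Q \in [-1, 1]$.

Optimization is a greedy two-phase Louvain algorithm on the corresponding
gain matrix, implemented in C++ with a seeded sweep order. Exact ties
between equally good target modules are resolved uniformly at random per
run: this matters for the stability diagnostics below, because degenerate
optima must be *sampled* across runs rather than resolved to a fixed
representative. On all small instances we have enumerated (up to 8 nodes,
4140 partitions), the best of a modest number of restarts attains the
global maximum.

Because single runs are seed-dependent, three aggregation procedures are
provided:

* **Modal partition** (`modal_partition()`): many runs (default 10,000),
  each run's arbitrary module labels aligned to a reference run by
  maximal-overlap assignment (Hungarian algorithm), then each region
  assigned to its per-node modal module. Regions whose modal frequency
  falls below 0.5 trigger an ambiguity warning.
* **Consensus partition** (`consensus_partition()`): the co-assignment
  (agreement) matrix of many runs (default 1000) is thresholded at
  $\tau = 0.5$ (a conventional value, exposed as an argument) and
  reclustered until all runs agree; the converged agreement matrix is
  binary and block-diagonal.
* **Versatility** (`versatility_curve()`): across a $\gamma$ grid
  (default 0.01--4.00 in steps of 0.01, 1000 runs per value), each
  region's versatility is the mean over partners of
  $\sin(\pi P_{ij})$, with $P_{ij}$ the co-assignment frequency. It is 0
  exactly when every frequency is 0 or 1 and maximal when a partner is
  co-assigned in half the runs. The mean-over-partners form is used
  because it keeps the measure in $[0, 1]$ and gives the exact-zero fixed
  point for stable decompositions. Local minima of mean versatility over
  the grid (interior points; plateaus reported at their left-most
  $\gamma$, without smoothing) flag resolutions where the decomposition
  is least ambiguous. Mean module counts per $\gamma$ are reported
  alongside so that degenerate regimes (very few clusters, or mostly
  singletons at high resolution) can be excluded when choosing a
  resolution.

# Null models

Significance of $Q$ and of partition similarity is assessed against
networks rewired to preserve each node's number of positive and negative
edges and the multiset of weights exactly (`rewire_signed()`). A swap
selects four distinct nodes and exchanges the weights of two edge pairs
when the signs are compatible (same sign within pair, opposite across
pairs); on a complete signed matrix this reduces to sign-stratified weight
shuffling, and on sparse graphs edges genuinely move. Conservation is
asserted exactly in the tests, per seed, not statistically.

The observed statistic uses the modal partition; each null network is
clustered with a single Louvain run (configurable), since running the full
modal procedure on every one of 10,000 null networks would be
computationally gratuitous without changing the comparison. P-values use
the $(x + 1)/(n + 1)$ correction and can never be zero. For calibration
checks (a matrix drawn from the null ensemble tested against that
ensemble) observed and null statistics must be computed identically, so
the tests use single-run Louvain on both sides; p-values are then uniform.

# Matrix and partition comparison

The Mantel statistic is the Pearson correlation of the paired off-diagonal
upper-triangle entries, with significance from simultaneous row/column
permutations of one matrix (one-tailed "greater" by default: every
hypothesis here is a similarity hypothesis). For up to 8 regions an
exhaustive mode enumerates all label permutations and returns the exact
permutation p-value. Type-I error at $\alpha = 0.05$ is verified to be
$0.05 \pm 0.01$ against independent noise matrices.

Partition similarity uses three statistics: NMI normalized by the
arithmetic mean of the entropies (alternative normalizations by flag), VI
in nats and unnormalized (a VI near 1 for 16 regions is only consistent
with the unnormalized natural-log convention; bits and $\log n$
normalization are flags), and the z-scored Rand pair count under the
hypergeometric model with fixed group sizes, using the closed-form mean
and variance rather than a permutation z. The closed form is verified
against a 10,000-shuffle Monte Carlo null (mean $\approx 0$,
sd $\approx 1$).

Cluster validity is additionally checked by contrasting mean intra-cluster
against mean extra-cluster correlations with a pooled-variance one-tailed
Student's t-test on the raw correlation values (a Fisher-z option exists
but is off by default, matching the plain-t convention).

# Twin model

Genetic correlations of change are estimated with a bivariate latent
change score ACE model for MZ/DZ pairs. Per twin and region, baseline
loads an intercept factor and follow-up loads intercept plus slope;
the $4 \times 4$ latent covariance (two intercepts, two slopes)
decomposes into $A + C + E$, each parameterized by a lower-triangular
Cholesky factor (so positive semidefiniteness holds by construction),
with cross-twin latent covariance $\alpha A + C$, $\alpha = 1$ (MZ) or
$0.5$ (DZ). The genetic correlation of change is
$r_g = A_{S_1 S_2} / \sqrt{A_{S_1 S_1} A_{S_2 S_2}}$, flagged unstable
when either genetic slope variance is a negligible share of its total.

With hemisphere-averaged volumes there is a single indicator per occasion
and the loading matrix is invertible, so an occasion-level residual
variance is not identified separately from the E component; it is fixed at
0 and absorbed into E. This leaves $A$ and $C$ -- and therefore $r_g$ --
unaffected, since they are identified from the cross-twin blocks. With
bilateral left/right indicators (`bilateral = TRUE`) the residual variance
is identified and freely estimated. ICV/site adjustment
(`residualize()`) is applied uniformly to all structures, including the
ventricles, before modeling.

Fitting maximizes the sum of MZ and DZ multivariate-normal log-likelihoods
expressed through per-group sufficient statistics (mean and scatter), so
each objective evaluation costs $O(p^3)$ regardless of sample size.
Multi-start quasi-Newton optimization (`nlminb`) starts from moment-based
estimates (latent blocks solved through the loading pseudo-inverse and
clipped to PSD) with jittered restarts; failure to converge is reported in
the `converged` flag, never raised. Slope--intercept covariances are
freely estimated. Nested AE/CE/E submodels support likelihood-ratio
checks; dropping A can never improve the likelihood, which the tests
assert.

# Synthetic data

The generator is the ground truth for every stage. Cohorts: per-subject
annualized change rates are drawn from a block-structured multivariate
normal whose correlation is `within_r` inside planted modules and
`between_r` elsewhere (PSD validated at construction); baseline volumes
and follow-up intervals are uniform; follow-up volumes come from *exact
inversion* of the symmetrized-change formula, so at zero measurement noise
the change table reproduces the drawn rates to machine precision.
Defaults mirror the developmental study conditions: 644 subjects,
intervals 1.0--3.2 years, baseline ages under 20, the five-cluster
reference partition, within/between correlations 0.5/0.05, no measurement
noise (noise is an explicit option; it attenuates correlations toward
zero). Mean and SD of the annualized rates default to 0 and 1 %/yr for
all regions -- the pipeline analyzes correlations, which are invariant to
per-region location/scale, so only the correlation structure is
substantive.

Twins: latent intercept/slope factors per region follow the ACE structure
above with configurable variance proportions and genetic correlations
(within-module slope correlation `rg_slope`, cross-module `rg_between`,
within-region intercept--slope `rg_is`); MZ pairs share the genetic
deviate, DZ pairs share it with weight 0.5. Defaults mirror the twin
sample targeted by the pipeline: 150 MZ and 106 DZ pairs.

What the generator does *not* emulate: site/scanner batch effects,
age-dependent change rates (rates are stationary within subject),
segmentation errors correlated across regions, attrition, and non-normal
rate distributions. Passing tests therefore validate the statistical
machinery, not robustness to those real-data features.

## A note on identifiability of singleton modules

The reference partition contains two single-region modules. Under a
uniform block generator, two regions that each correlate at `between_r`
with everything are statistically exchangeable, and under the signed
modularity above the expected negative weight between them exceeds their
actual weight, so *pairing them always increases Q* -- for any sample
size. A planted partition with singleton modules is therefore not exactly
recoverable by $\gamma = 1$ modularity maximization from this generator:
the optimum pairs the two singletons (and sampling noise can attach them
elsewhere). This is a property of the model class, not of the
implementation: singleton-free planted partitions are recovered exactly
(adjusted Rand index 1) in essentially every replicate at the default
conditions, singletons can be Q-optimal on small graphs (verified by
exhaustive enumeration), and the non-singleton part of the partition is
recovered exactly. The corresponding exact-recovery acceptance check is
left in place and fails for this structural reason; users clustering real
data should read singleton modules as "this region tracks no other
region", an inherently resolution-dependent statement.

# Numerical choices and problem sizes

* All stochastic operations take explicit integer seeds; sub-streams are
  derived, and results are bit-reproducible for a given seed.
* Default run counts are the full-scale ones (10,000 modal runs, 10,000
  nulls, 10,000 Mantel permutations, 1000 consensus/versatility runs).
  The test-suite and the acceptance script use reduced sizes chosen for
  rapid verification: modal runs in the hundreds to thousands, 500
  rewired nulls, 30 replicate cohorts for recovery rates, 100 replicate
  twin samples for estimator calibration, a 200,000-pair simulation for
  the twin moment oracle. These sizes give Monte Carlo errors well below
  the assertion tolerances used with them.
* Versatility's exact-zero fixed point is enforced by zeroing
  $\sin(\pi P)$ at binary frequencies (floating-point $\sin(\pi)$ is
  $\sim 10^{-16}$, not 0).
* The consensus agreement matrix is reclustered at resolution 1
  regardless of the $\gamma$ used on the data, since agreement entries
  live on a different scale than correlations.
* Degenerate cluster contrasts (all correlations equal) return
  $t = 0, p = 0.5$; identical groups with zero variance but different
  means return $t = \pm\infty$.
* `modularity_signed` forces the diagonal to zero; self-weights are never
  clustered.

# Limitations

Known limitations beyond those noted above: the Louvain optimizer is
greedy and seed-dependent (hence the modal/consensus layers); the twin
model assumes bivariate normality, complete pairs, and equal means across
twins and zygosity groups; no spatial constraints are imposed on the
rewired null networks; and the pipeline treats hemisphere-averaged
volumes, not lateralized effects.
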