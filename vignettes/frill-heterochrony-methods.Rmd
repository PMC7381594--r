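---
title: "Methods: shape, modularity, and heterochrony on a fossil phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape, modularity, and heterochrony on a fossil phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frillmorph)
```

This vignette documents the statistical machinery in `frillmorph`: the
models each stage assumes, the parameters that matter and their defaults,
the numerical choices, and what the synthetic-data generator does and does
not emulate. The motivating application is the evolution of the
parieto-squamosal frill in ceratopsian dinosaurs — a structure hypothesized
to form a semi-independent developmental module and to have diversified
through heterochrony — but every function is generic 2D landmark
machinery.

## Landmark data model

A specimen is an ordered set of k points in 2D: discrete homologous
landmarks plus evenly spaced semilandmarks resampled along curves
(`resample_curve()`, equal arc-length spacing with endpoints preserved).
TPS files carry only coordinates, `ID=` and `SCALE=`, so role information
(fixed vs semilandmark, curve membership, body side) travels in a sidecar
CSV (`index,role,curve,side`). Indices are 1-based everywhere — in files,
reports, and internally — since R indexes from 1.

Fossil skulls are often better preserved on one side. `mirror_fill()` fits
the sagittal axis as the total-least-squares line through the midline
landmarks, replaces each point on the discarded side by the reflection of
its bilateral partner, and projects midline points exactly onto the axis.
The projection step is deliberate: it guarantees exact bilateral symmetry,
so downstream symmetry-sensitive statistics see no residual asymmetry
artifact from the reconstruction.

## Superimposition

`gpa()` implements partial generalized Procrustes analysis: every
configuration is centered, scaled to unit centroid size, and rotated to a
provisional consensus; the consensus (the plain arithmetic mean of the
aligned shapes) is recomputed until its root-mean-square change falls
below `tol` (default 1e-8). Reflections are never allowed — mirroring is
an explicit preprocessing decision, not something the optimizer may do.
Centroid size is carried separately as the size variable for allometry.

Three choices deserve comment:

- **Semilandmarks are not slid.** Sliding requires a curve specification
  defining the tangent directions; the interface records curve membership
  so a sliding step can be added, but superimposition currently treats all
  points as fixed.
- **Tangent projection** (orthogonal projection onto the tangent space at
  the consensus) is on by default, the standard preliminary to PCA and
  regression on shape coordinates.
- **Frame fixing.** A Procrustes solution is defined only up to a global
  rotation, and with widely dispersed shapes the iterative algorithm can
  even reach different local optima from different starts. The
  implementation therefore starts from the lexicographically first
  specimen and afterwards rotates the whole sample so the consensus point
  farthest from the centroid lies on the positive x-axis. Output is thus
  deterministic, invariant to input order, and invariant to rigid motions
  of any input.

## Phylogenetic PCA

With per-species shape vectors X (species x 2k) and the Brownian-motion
tree covariance C (shared root-to-MRCA path lengths), `phylo_pca()`
computes the GLS mean `a = (1'C^-1 1)^-1 1'C^-1 X`, the evolutionary
covariance `R = (X-1a)' C^-1 (X-1a)/(n-1)`, and its eigendecomposition;
scores are `(X-1a)V`. On a star tree with equal branch lengths this is
ordinary PCA. Covariance mode is the default (Procrustes coordinates share
a scale); correlation mode is available. Axis signs are fixed by making
each axis's largest-magnitude loading positive. Percent variance per axis
is computed from the eigenvalues of R.

## The covariance-ratio modularity test

For a partition of landmarks into modules (both coordinates of a landmark
stay together), `cr()` computes the ratio of between-module to
within-module covariation from the coordinate covariance matrix, with
within-module block diagonals zeroed. CR < 1 indicates modularity.
`cr_test()` builds the null by reassigning whole landmarks to modules of
the same sizes, uniformly at random (default 10,000 partitions), and
reports the left-tail p-value with the (1+b)/(1+m) estimator, which is
unbiased under exchangeability and can never return exactly zero.
`semilandmark_sensitivity()` repeats the test with randomly removed
semilandmarks (stratified across modules, with replicates, since no single
removal set is canonical) to check that a modularity signal is not an
artifact of semilandmark density.

One interaction matters when simulating: if module deviations are close to
rigid translations of a whole module (as happens when all coordinates in a
module are correlated ~0.7), Procrustes centering redistributes that
variation across the other module and induces strong *between*-module
covariance — CR can exceed 1 after GPA even though the generating model is
strongly modular. Real biological modularity has internal structure that
survives superimposition better. The package's calibration and power
experiments therefore evaluate `cr_test()` on registered shape-space
specimens; conclusions about GPA-processed data must rely on the test's
permutation null, which is computed after whatever processing was applied.

## Time-scaling a fossil phylogeny

`timescale()` dates nodes from first-appearance dates (FADs): every tip
sits at its FAD, every internal node initially at its oldest descendant's
FAD, and the root is extended by `root_extension` (default 1 Ma) so it has
positive duration. Minimum-age dating leaves zero-length branches wherever
a clade's oldest tip appears; two rules remove them:

- **equal** — time from the nearest strictly older ancestor is shared
  evenly along each chain of equal-aged nodes (tip ages stay fixed).
- **punctuated** — exactly 1 Ma is added to each initially zero-length
  branch, pushing ancestral nodes deeper while descendant ages and all
  positive branch durations are preserved. This emulates a punctuated
  reading in which change concentrates at speciation.

Polytomies are resolved to a binary tree deterministically (fixed,
input-order-based resolution with zero-length branches, which the dating
rules then make positive). Both calibrations can be run side by side to
assess how sensitive downstream reconstructions are to branch lengths.

## Comparative methods

`pic_contrasts()` wraps Felsenstein's independent contrasts;
`pic_regression()` regresses y-contrasts on x-contrasts through the origin
(the GLS regression under Brownian motion, verified against a direct GLS
oracle in the tests) with an F test on n-2 denominator degrees of freedom.

`sqcp_ancestral()` minimizes the branch-length-weighted sum of squared
changes by solving the associated sparse linear system; with 1/length
weights this equals the maximum-likelihood Brownian ancestral states
(cross-checked against an independent implementation).

`fit_bm_model()` fits, by maximum likelihood, Brownian motion with an
optional directional trend (mean linear in root-to-tip path length;
identifiable only off-ultrametric trees) or one of three covariance
transformations: lambda scales off-diagonal covariances (phylogenetic
signal, bounded [0,1]), kappa raises branch lengths to a power ([0,3]),
delta raises node depths to a power ((0,3]; < 1 early burst, > 1
late/accelerating). The rate and mean parameters are profiled
analytically; the scaling parameter is optimized numerically with boundary
candidates checked explicitly. Model comparison uses AICc and likelihood
ratios against plain Brownian motion (`model_table()`), a desk-scale ML
analog of Bayesian marginal-likelihood comparisons.

## Heterochrony inference

`pooled_regression()` regresses every shape coordinate on log centroid
size; the stacked slopes b define the allometric direction, and each
specimen's *regression score* is its projection onto b/||b||. One
deliberate deviation from common practice: because b is estimated from the
same specimens, the parametric F-test of the score-on-size regression is
grossly anti-conservative (empirical type-I error near 0.8 in simulation).
The reported p-value therefore comes from a permutation test that
reshuffles log centroid size and refits the full multivariate regression
each round (999 permutations by default); the F statistic is still
reported descriptively.

Per species, `ontogenetic_vector()` connects the smallest and largest
specimens (by centroid size — the analysis's size variable) in the
(log CS, score) plane. `ancestral_vectors()` reconstructs the four
endpoint coordinates independently at every internal node by
squared-change parsimony on the time-scaled tree. `shift_table()` then
takes, for every branch, the adult-score difference (descendant minus
ancestor; positive significant shifts are peramorphosis, negative
paedomorphosis) and flags it when |delta| exceeds 1.5 times the 95%
t-based CI half-width of the mean branch difference — the CI level is
configurable since conventions differ. Rates are deltas per Ma with
rank-based quartile labels (robust to ties).

Angles between ontogenetic displacement vectors use the atan2 form (exact
0/180 degrees for parallel/antiparallel vectors, no acos domain error).
`angle_randomization_test()` draws 200 random vectors uniformly within the
per-axis bounds of the observed displacements and measures angles between
the 100 disjoint successive pairs; pairing disjointly (1-2, 3-4, ...) is
the reading that reconciles "200 vectors" with "100 angles".
`classify_modes()` maps the evidence to the classical vocabulary:
substantial angle change (percentile above 0.85 by default) means
acceleration or deceleration; near-parallel vectors shifted toward/away
from the origin mean pre-/postdisplacement; a parallel vector extended to
larger adult size and score is consistent with hypermorphosis.

A known sensitivity, visible in simulation: squared-change parsimony
shrinks a tip's signal into its ancestor in proportion to 1/branch-length,
so a shifted species on a very short terminal branch with a close sister
can have most of its shift absorbed by the reconstructed ancestor and
escape classification. Recovery experiments should therefore fix a
reference topology with a non-negligible focal branch; the packaged
experiments use a 6-tip fossil tree with a 2 Ma focal terminal branch.

## Group comparisons

`pairwise_perm_anova()` computes the classical one-way F between two
groups on one ordination axis and a permutation p-value over label
reshuffles (1,000 by default). The raw proportion of permuted F >= observed
is reported — the convention in the morphometric literature, under which
p = 0 is possible — alongside the (1+b)/(1+m) corrected estimate.

## The synthetic-data generator

`sim_config()` fixes the study conditions: a fossil tree with staggered
tip ages (default 8 tips over 5-25 Ma — non-ultrametric, which exercises
time-scaling and makes the directional model identifiable); species mean
shapes evolving by Brownian motion with a block trait covariance
(within-module correlation 0.7, between 0.1, rate 1e-4 per Ma — deviations
of a few percent of the template size over the tree depth); per-species
linear allometry along a frill-elongation direction (score slope 0.15 over
centroid sizes 50-400, the order of magnitude of published skull
allometries); and isotropic digitization noise (sd 0.005 in unit-shape
space, i.e. sub-percent of size, typical of careful 2D digitization).
Every stage draws from its own seeded stream derived from the master seed,
so stages are reproducible in isolation.

What the generator does *not* emulate: taphonomic distortion fields
(only isotropic noise), ornament growth, within-module covariance
structure beyond exchangeable correlation, and measurement error in the
age table. Passing recovery tests therefore demonstrate correctness of the
estimators under the assumed model, not robustness to violations of it.

`simulate_heterochrony_study()` composes the whole chain — tip shapes,
growth series (optionally with tree-correlated per-species size factors
and a shared allometric centering point, which creates the cross-species
allometry a contrasts regression can detect), pooled regression, vectors,
ancestral reconstruction, shift table — and is the engine of the
end-to-end recovery experiments.

## Problem sizes used by the packaged experiments

The test suite and `scripts/acceptance.R` run entirely on synthetic data:
rotation-grid oracles at 0.001-degree resolution; GLS oracles on random
trees of up to 12 tips; lambda recovery on 200 Brownian simulations over a
25-tip tree; CR calibration on 1,000 null datasets of 30 specimens
(Monte-Carlo se of the rejection rate < 0.007) and power on 20 datasets of
50 specimens; heterochrony recovery over 100 replicates; permutational
ANOVA calibration over 500 replicates. These sizes keep each experiment's
Monte-Carlo error small relative to the acceptance bands while completing
in seconds to tens of seconds.

## Known limitations

- 2D only; no semilandmark sliding; no asymmetry decomposition.
- The CR test is implemented for m modules but exercised for two.
- ML point estimates of lambda/kappa/delta on small fossil trees are noisy
  and frequently sit on a bound; they are reported with AICc rather than
  posterior distributions.
- Heterochrony classification inherits the branch-length sensitivity of
  squared-change parsimony discussed above.
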