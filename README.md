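# frillmorph

Landmark-based geometric morphometrics and phylogenetic comparative methods
for studying how a skull structure — the motivating case is the
parieto-squamosal frill of ceratopsian dinosaurs — changes shape across
ontogeny and phylogeny. The package covers the full analysis chain on 2D
landmark data:

- **TPS input/output** with a sidecar role table (fixed landmarks vs evenly
  spaced semilandmarks), curve resampling, bilateral mirroring across the
  sagittal axis, and landmark subsetting (e.g. excluding the parietal
  fenestra so fenestra-less taxa fit the same configuration).
- **Generalized Procrustes analysis** (partial Procrustes: translation,
  unit-centroid-size scaling, rotation; optional tangent projection), with
  centroid size carried separately as the size variable.
- **Phylogenetic PCA** of shape under Brownian motion: GLS mean,
  evolutionary covariance `R = (X-1a)' C^-1 (X-1a)/(n-1)`, eigenanalysis,
  axis-extreme shape deformations.
- **Covariance-ratio (CR) modularity test**: for a landmark partition into
  modules, `CR = sqrt( tr(S12 S21) / sqrt(tr(S~11 S~11) tr(S~22 S~22)) )`
  (within-module blocks with zeroed diagonals); values below 1 indicate
  modularity, assessed against a null of random same-size landmark
  partitions, plus a semilandmark-removal sensitivity analysis.
- **Fossil time-scaling** of a phylogeny from first/last appearance dates
  (minimum-age dating with either the "equal" redistribution rule or a
  punctuated +1 Ma rule for ghost-lineage-free branches), the
  Brownian-motion tree covariance, independent contrasts, and
  squared-change-parsimony ancestral states (equivalent to ML Brownian
  states).
- **Evolutionary model fits**: ML Brownian motion with directional trend
  and Pagel's lambda / kappa / delta tree transformations, compared by AICc
  and likelihood ratios.
- **Heterochrony inference**: pooled multivariate regression of shape on
  log centroid size, regression scores, per-species ontogenetic vectors
  (smallest to largest skull), squared-change-parsimony ancestral vectors,
  allometric shifts classified as peramorphosis/paedomorphosis by the
  1.5 x CI criterion, per-branch rates, vector angles with a randomization
  test, and narrative mode labels (acceleration, hypermorphosis, ...).
- **A synthetic-data generator** producing landmark datasets with known
  phylogenetic, modular, and allometric structure, so every stage has a
  ground-truth recovery test without any fossil data.

## Worked example

Simulate a small fossil study with modular shape covariance and a shared
allometric slope of 0.15, then run the core analyses:

```r
library(frillmorph)

tt  <- simulate_fossil_tree(n_tips = 8, seed = 1)       # time-scaled tree
cfg <- sim_config(seed = 1, bm_rate = 1e-4, slope = 0.15)
study <- simulate_heterochrony_study(
  tt, slopes = setNames(rep(0.15, 8), tt$tree$tip.label), config = cfg)

study$model
#> Pooled allometric regression (n = 48)
#>   regression-score slope on log CS = 0.1474, F = 342.2, p = 0.01

head(study$shifts[, c("ancestor", "descendant", "delta_score",
                      "classification")], 3)
#>   ancestor descendant  delta_score classification
#> 1  node_13        sp3  0.028146222  peramorphosis
#> 2  node_13        sp4 -0.064227565 paedomorphosis
#> 3  node_10    node_11  0.006144453           none
```

The slope estimate (0.147 here) recovers the generating value 0.15. All
species share one ontogenetic slope, so the flagged branches reflect
Brownian drift of the species mean shapes along the allometric axis —
score shifts that exceed the 1.5 x CI threshold even without a slope
change. In a designed recovery experiment (no drift, one species given a
slope 1.5 times its relatives'), only that terminal branch is flagged, as
`peramorphosis`.

The modularity statistic on 50 registered specimens with within-module
correlation 0.7 vs between-module 0.1:

```r
star <- ape::stree(50, "star"); star$edge.length <- rep(1, 50)
star$tip.label <- paste0("ind", 1:50)
spec <- simulate_tip_shapes(star, sim_config(seed = 4, bm_rate = 0.003))
cr_test(spec$shapes, spec$partition, n_permutations = 10000, seed = 1)
#> Covariance-ratio modularity test
#>   observed CR = 0.2874, p = 9.999e-05 (10000 random partitions, seed 1)
```

CR far below 1 with the observed value in the extreme left tail of the
random-partition null: strong modular signal, as built into the generator.

## Vignette

`vignettes/frill-heterochrony-methods.Rmd` documents the statistical model
behind each stage, the default parameter choices, what the synthetic
generator does and does not emulate, and known limitations.
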