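---
title: "Methods: diversity-based conservation planning with dominant markers"
author: "RGUCkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity-based conservation planning with dominant markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RGUCkit)
```

This vignette is the package's own account of the statistical machinery:
the models and their assumptions, the tunable parameters with their
defaults and units, the synthetic-data generator's scope, and the
numerical and design decisions taken where the methodology left room.

## Data model

Dominant markers (AFLP bands, ISSRs, presence/absence SNP calls) score
each individual 0/1 per locus; heterozygotes are indistinguishable from
band-carrying homozygotes. The `BandMatrix` class stores these scores as
a `SummarizedExperiment` (loci × individuals) with the population label
in `colData`. Validity demands a complete binary matrix and at least two
individuals per population; missing cells are rejected at load time
(`readBandMatrix(..., impute = TRUE)` optionally fills them with rounded
population means and reports the count loudly, for matrices scored with
occasional failures).

Two frequency scales coexist and must not be conflated:

* **band (phenotype) frequency** `f` — the fraction of carriers; used by
  the diversity descriptors, rarity rules, and the turnover model;
* **allele frequency** — for Hardy–Weinberg biallelic loci the null
  allele has frequency `q = sqrt(1 - f)`; `alleleFrequencies()`
  estimates it with the first-order Taylor bias correction
  `q = sqrt(x) (1 + V(x) / (8 x^2))`, `V(x) = x(1-x)/n`, dropping the
  correction below the usual reliability bound `x < 3/n` and clamping
  fixed-band cells to `x = 1/(2n+1)` so no allele is ever estimated as
  absent. Coancestry and the leave-one-out decompositions work on this
  scale.

The within-population Nei gene diversity is, by default, the phenotype
form `GD = mean_l (n/(n-1)) 2 f (1-f)`; the allele-frequency route
(`method = "lynch"`) is provided because published tables rarely state
which estimator was used, and the two differ systematically. The
phenotype form is the default because it makes no Hardy–Weinberg
assumption.

## Selecting conservation units

The retention rule solves `P = 1 - FST^n` for the number of populations
`n` whose joint protection keeps a fraction `P` of total diversity. The
assumptions are strong — populations equally differentiated, diversity
exchangeable — so `n` is a planning anchor, not an estimate with an
interval; `nPopulations()` therefore reports the continuous solution and
always rounds **up** (never half-even), so conservation goals are not
undershot by rounding.

Rarity uses two strict thresholds (defaults 10% overall frequency, 40%
population occupancy, both configurable — stricter published variants
10%/10% and 10%/20% exist). The loss probability of a rare band,
`L = (1-p)^(2N)`, is the chance that a sample misses it entirely. Two
regressions of `-ln L` on the band's mean frequency across occupied
populations — one at observed occupancy (`L_o`), one at `N = 1`
(`L_e`, "sampling a single population") — give the R-value as
`slope_e / slope_o`. Defined this way R lies in (0, 1] and is exactly
`1/N` when every band occupies `N` populations. The literature prints
the formula both ways up; we follow the interpretation (proportion of
rare bands captured by one population), which forces the expected slope
into the numerator.

Each rare band's preferred sampling area is the cluster maximizing the
fraction of its populations that carry the band; ties break by carrier
count, then by lower cluster index — every tie-break is deterministic
and flagged in the output. Cluster labels are an *input* (typically from
a Bayesian structure analysis); `surrogateClusters()` provides a k-means
stand-in on population band-frequency vectors (50 restarts, silhouette
selection of K when unspecified) so synthetic pipelines run end to end.
It is a surrogate, not a reimplementation of spatial Bayesian
clustering.

The optimal per-cluster sampling proportions combine PSA shares with
per-cluster R-values. No canonical combination rule exists; the default
averages the two after normalization and renormalizes, and
`optimalProportions()` accepts any replacement strategy. Published
proportions are approximately, but not exactly, reproduced by this
default — the original rule behind such tables is not stated, which is
why the strategy is pluggable and the choice logged.

RGUC selection itself is intentionally simple: top-`n` populations per
cluster by Nei gene diversity, DW rarity as tie-break, then label order.
The DW index sums each population's share of every band's total
occurrences, so a private band contributes exactly 1 and the per-band
shares always sum to 1. Capture percentages (all bands / rare bands in
at least one selected population) are compared against a seeded
random-selection baseline (default 100 draws).

## Structure diagnostics

Genetic distance between individuals is the proportion of mismatched
loci; geographic distance is the haversine arc on a 6371 km sphere
between population coordinates, log-transformed as `log(km + 1)` in the
Mantel test so that zero within-population distances are defined. The
Mantel correlation is delegated to `vegan::mantel`; spatial
autocorrelation uses equal-pair-count distance classes (the published
class constructions vary and equal counts avoid empty classes), with the
class statistic `Ay` = mean genetic distance among pairs in the class
and two-sided permutation p-values. All permutation p-values in the
package use the `+1/(n+1)` convention and never return 0.

Φ_ST comes from an AMOVA on pairwise squared Euclidean distances between
binary phenotypes (equal to mismatch counts): variance components from
the within/among sums of squares with the unequal-size correction
`n' = (N - Σ n_k² / N)/(k - 1)`, significance by permuting individuals
among populations.

## Seed-bank optimization

The pooled gene diversity of a mixture `c` of populations is
`1 - c'Fc`, `F` the average coancestry matrix
(`f_ij = mean_l (p_i p_j + q_i q_j)`, uncorrected gene identity on the
diagonal — whether a self-coancestry sample-size correction should
apply is not recoverable from the sources, so the plain form is the
documented default). `maximizeDmax()` minimizes the quadratic form on
the simplex by projected gradient descent (Duchi-style simplex
projection, backtracking step, 500-iteration cap) from 100 random
Dirichlet starts, keeping the best; `F` need not be positive definite,
which is why multi-start matters. Contributions below 1e-6 are reported
as exact zeros and renormalized; counts out of a synthetic pool of 1000
individuals are reported alongside. On all 2–3 population instances the
optimum matches an exhaustive 0.01-resolution simplex grid within 1e-3
(tested).

Leave-one-out contributions use the sign convention "positive = the
indicator *decreases* when the population is removed": ΔH_nei for mean
within-population expected heterozygosity, ΔH_dist for the mean pairwise
Nei minimum distance `D_ij = mean_l ((p_i-p_j)² + (q_i-q_j)²)/2`, both
in percent; ΔH_t is their sum, additive to 1e-6 by construction, and
negative values are legitimate (redundant populations inflate the pool).
Degenerate scopes (all populations identical) report 0 rather than 0/0.

## Genotype–environment turnover

The turnover stage asks a different question from outlier scans: not
"which loci are under selection", but "how does composition as a whole
turn over along each environmental gradient". Predictors are filtered
for collinearity first (iterative pairwise rule at R² > 0.7, dropping
the member of the worst pair with the larger mean R² against the rest;
deterministic order).

Each locus is then fitted with a bagged ensemble of CART classification
trees: bootstrap rows, a random predictor subspace per tree
(`mtry = ceiling(sqrt(p))`), per-split Gini improvements recorded, 500
trees by default. This ensemble is the package's own design; its role
is to yield per-split improvements that can be localized on each
predictor's range. A locus is retained when its out-of-bag error is
strictly below the majority-class null error, and weighted by
`1 - oobError/nullError` (an out-of-bag R² analogue). Both stricter and
looser retention readings exist in applied work (all loci "related" to
climate versus only those with error ≤ 0.5); the threshold here is the
strict-improvement rule, and the per-locus table in the fitted object
lets users apply any cut they prefer. Improvements are binned into 200
fixed-width bins per predictor range (a deliberate simplification of
density-standardized binning), normalized per locus, weighted, and
averaged over retained loci; cumulative sums give non-decreasing,
right-continuous genetic-importance functions whose maxima are the
overall predictor importances. Fits are seeded per locus (a hash of the
locus name), so results are invariant to locus order and to subsetting
the matrix.

`transformClimate()` pushes any value through these step functions
(out-of-range values clamp to the endpoints, counted and reported);
`mapGroups()` fits a PCA on the transformed grid, projects populations
into the same space, Ward-clusters the population scores (first 3 axes
by default) into 3 groups by default — the natural check being whether
climate reproduces the genetic cluster count — and assigns every pixel
to the nearest centroid. Future scenarios are transformed, averaged per
pixel, and assigned against the *frozen* current-climate centroids so
group identities remain comparable across time slices.

Rasters are ESRI ASCII grids (plain text, cell-centred, row-major from
the north-west corner, WGS84 decimal degrees); all layers of a stack
must share geometry and nodata masks are unioned. The inverse-distance
surface (`interpolateSurface`, power 2, exact at population cells) is a
display aid only and carries no inferential weight.

## The synthetic-data generator

`simulateStudy()` emulates the statistical structure of a range-wide
dominant-marker survey so that every stage has a testable truth record:

* **Shape** (defaults): 11 populations of 17–27 individuals (255 total)
  in K = 3 clusters, 203 loci, on a 16° × 8° bounding box.
* **Neutral drift**: two-level Balding–Nichols model — cluster means
  Beta-distributed around a Uniform(0.1, 0.9) ancestral frequency,
  population frequencies Beta around cluster means, the two levels
  composed so the intraclass correlation of population band frequencies
  equals `fstTarget` (default 0.247, the published species-wide value);
  `clusterShare` (default 0.5) splits the drift between levels. Because
  the AMOVA Φ_ST on Bernoulli phenotypes estimates exactly this
  intraclass correlation, realized Φ_ST is calibrated to the target
  (within ±0.05 over replicates, tested).
* **Diversity heterogeneity**: populations receive a log-uniform factor
  (`divHet = 0.8`) scaling their drift down or up, normalized so the
  mean drift stays on target. Real surveys show a ~2× spread in
  within-population gene diversity and a strong coupling between
  diversity and rarity; rare-band placement is therefore weighted
  toward the more diverse populations. Without this coupling,
  diversity-ranked selection would be uninformative about rare-band
  capture by construction.
* **Rare loci** (`rareFraction = 0.3`): occupancy drawn below the 40%
  bound, in-population frequencies Uniform(0.05, ·) capped so the
  expected overall frequency stays below 80% of the 10% bound;
  realized matrices are re-checked and violators re-drawn (shrinking
  frequencies, final fallback a single carrier), so the strict rarity
  bounds hold in every realization.
* **Climate**: each layer is a random quadratic trend plus smoothed
  Gaussian noise, standardized; `nAdaptiveLoci = 10` loci follow
  `logit^-1(alpha + beta z)` of the standardized first layer
  (`beta = 6`), emulating genotype–environment association at a
  strength detectable but not overwhelming at 11 populations.

What the generator does **not** emulate: linkage, coalescent genealogy,
selection dynamics beyond the static logistic link, scoring error, or
spatial autocorrelation of genotypes within populations. Passing tests
therefore demonstrate the pipeline's statistical correctness on data
satisfying its assumptions, not robustness to the full messiness of
real AFLP scoring.

All stochastic functions take an explicit integer `seed` and call
`set.seed` internally (the R idiom standing in for passing a generator
object); derived stage seeds stay below 2^31.

## Numerical choices and problem sizes

* Permutation p-values: `+1/(n+1)`; two-sided class p-values are
  `min(1, 2 min(p_low, p_high))`.
* Dmax optimizer: gradient step initialized at `1/(2 max|F|)`, grown
  20% on success, halved on failure, stopped below 1e-14; zero
  threshold 1e-6.
* Turnover binning: 200 bins per predictor; transform values outside
  the training range clamp to function endpoints.
* Tie-breaks (PSA cluster, RGUC ranking, pixel assignment) are
  deterministic and documented at each site.
* The test suite runs the full generator defaults where the property
  being checked concerns the study conditions (Φ_ST calibration,
  rarity bounds) and deliberately smaller configurations — 8–11
  populations, 40–120 loci, 20–300 trees — for ensemble-heavy
  properties, keeping the suite at a few minutes on one CPU while
  leaving every assertion a property of the method, not of a size.

## Known limitations

* The allele-frequency estimator assumes Hardy–Weinberg equilibrium
  within populations; inbreeding biases both coancestry and the
  leave-one-out terms.
* The retention rule treats F_ST as exchangeable across populations;
  strong hierarchical structure argues for applying it per cluster
  (as the workflow does) rather than species-wide alone.
* The turnover ensemble is a bagged-subspace forest, not the reference
  gradient-forest implementation; importances agree qualitatively but
  are not numerically interchangeable with it.
* Group maps are nearest-centroid classifications in PCA space;
  uncertainty in group membership is not propagated.
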