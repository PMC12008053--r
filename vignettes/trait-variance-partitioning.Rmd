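---
title: "Partitioning trait variance into phylogenetic, environmental, and intraspecific components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait variance into phylogenetic, environmental, and intraspecific components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvrpart)
```

## The problem

Functional traits such as specific leaf area (SLA, leaf area per unit dry
mass, cm^2 g^-1) vary along climatic and edaphic gradients, but related
species also resemble each other because they inherit their trait values from
common ancestors. Any attempt to attribute trait variation to "environment"
without accounting for shared evolutionary history conflates the two. This
package quantifies, for a table of trait records (several measurements per
species, each tied to a site with climate and soil descriptors) joined to a
dated phylogeny, how much of the total variation is attributable to

* **phylogenetic relatedness** between species,
* **climatic conditions** and **soil properties** of the sites,
* **intraspecific variation** among records of the same species,

and where along the tree the interspecific variation was generated. SLA is
analysed as `log10(sla)` throughout; the log transform is applied at read
time and all variances are on the log10 scale.

## The estimator

### Phylogenetic eigenvector regression (PVR) with commonality analysis

Phylogeny enters the regression through principal coordinates of the
patristic distance matrix: Gower-center `-d^2/2`, eigendecompose, keep the
axes with positive eigenvalues. Each axis is a species-level coordinate,
broadcast to all records of the species. With three predictor classes --
phylogenetic axes `P`, climate `C`, soil `S` -- all `2^3 - 1 = 7` class
subsets are fitted as ordinary least-squares models on the identical record
set, each reduced to its most parsimonious form by forward AIC selection.
The seven R^2 values are decomposed by commonality analysis into unique
(`U_P`, `U_C`, `U_S`), pairwise shared (`C_PC`, `C_PS`, `C_CS`), and
three-way shared (`C_PCS`) components, which sum to `R2_PCS` by an exact
algebraic identity. Class totals are the single-class R^2 values. Negative
shared components are legitimate (suppression) and reported as-is.

The residuals of the full (PCS) model are regressed on species indicators
(model R); the **intraspecific contribution** is
`(1 - R2_PCS) * (1 - R2_R)` -- the share of variance that neither the three
classes nor species identity explains. With one record per species model R
is saturated and the contribution is exactly zero.

### How many eigenvectors?

A distance-matrix PCoA concentrates its eigenvalue mass in the deep
structure of the tree, but a trait evolving by Brownian motion accumulates
variance at *all* depths: shallow axes with little distance mass still carry
real trait signal. Restricting the pool to a high cumulative-eigenvalue
fraction therefore systematically understates the phylogenetic total. On the
package's default simulation scenario (known truth: phylogenetic fraction
0.52), a 95%-mass pool recovers `total_P` near 0.38, while the full
positive-axis pool recovers 0.58 -- inside the simulator's sampling
tolerance. The default is therefore `eigvec_threshold = 1` (every positive
axis enters the candidate pool) and parsimony is enforced where it belongs,
in the forward-AIC selection. Both a mass threshold and a fixed axis count
remain available for sensitivity analysis; lowering the threshold is the
main way to make the phylogenetic total smaller and more conservative.

### Forward AIC selection

Selection starts at the intercept-only model and adds, per step, the
candidate with the largest AIC decrease (Gaussian OLS AIC, parameters =
coefficients + error variance), stopping when no addition lowers AIC. For a
fixed step the best candidate is the one maximizing the residual-sum-of-
squares drop, computed by incremental Gram-Schmidt projection, so the whole
path costs O(n x candidates) per step. Ties break toward the earlier column
in canonical order (eigenvectors by eigenvalue rank, then variables
alphabetically, then interaction products), making results bit-reproducible.
Candidates whose addition would leave the design rank-deficient are skipped
with a warning. Stepwise paths are greedy: a model with more candidates can
end at a slightly lower R^2 than one of its subsets, which propagates into
individual commonality components; the components-sum identity holds
regardless.

### Quadratic terms and the interaction variant

Second-order terms enter the candidate pool only for variables whose
single-predictor mixed-model screen (below) prefers the quadratic candidate
by AIC. Quadratic and interaction terms are built from centered variables to
limit collinearity. In the `interactions` variant all climate x soil
products join the candidate pool -- only for subsets containing both C and
S, so single-class totals are identical across variants and the variant
changes only `R2_CS`, `R2_PCS` and the shared components. Eigenvectors are
coordinates, not gradients: they are never squared and never interact.

### Records, not species, are the unit

All seven models are fitted on records, with species-level axes broadcast.
Records with a missing value in any class variable are removed once,
listwise on the union of the seven models' variables, so the AIC and R^2 of
all models refer to the same data. Species with many records implicitly
carry more weight; no reweighting is applied.

## Phylogenetic signals

Four standard indices, each with a tip-permutation test (one-sided greater;
`p = (exceedances + 1) / (n_perm + 1)`, so 999 permutations give a floor of
0.001):

* **Moran's I** with inverse patristic distances as weights (not
  row-standardized by default; a switch enables row standardization).
* **Abouheif's C_mean**: the same Moran form with the Abouheif proximity --
  the product over internal nodes on the tip-to-tip path (MRCA included) of
  one over the node's daughter count; polytomies contribute their true
  daughter count.
* **Blomberg's K**: observed MSE ratio standardized by its Brownian
  expectation; exactly 1 for any data on a star tree, and calibrated so its
  mean is near 1 for Brownian data on any tree.
* **Pagel's lambda** by maximum likelihood: off-diagonal covariances scaled
  by lambda, mean and rate profiled out in closed form, lambda optimized on
  [0, 1] by a 21-point grid scan plus Brent refinement (tolerance 1e-6);
  the grid guards against flat or multimodal profiles.

Signals operate on one value per species; the default aggregation is the
mean of the log10-transformed records (median available). The choice is
exposed because record-to-species aggregation is not standardized in trait
databases.

## Variance decomposition and environment screens

`variance_decomposition()` fits nested random-intercept models by REML
(lme4) -- e.g. site, then species-within-site -- and reports each component
as a fraction of the summed variances. On balanced designs the REML
estimates equal the classical ANOVA method-of-moments estimators, which the
tests verify to 1e-6. The nesting is fully configurable (spatial or
taxonomic hierarchies of any depth) because variance attributions depend
strongly on which levels the hierarchy includes.

`env_screen()` regresses the response on one environment variable with a
species random intercept, comparing linear vs quadratic fixed effects by
AIC on ML fits (the candidates differ in fixed effects, so REML likelihoods
are not comparable); the winner is refit by REML for reporting. The
predictor is standardized internally (centering constant and scale are
returned). The explained fraction is the Nakagawa-Schielzeth marginal R^2:
fixed-effect prediction variance over the sum of fixed, random-intercept,
and residual variances. `group_interaction_test()` adds a two-level group
factor and tests the group x environment interaction by a likelihood-ratio
test on ML fits at the AIC-chosen degree.

## Node contributions along the tree

`aot_report()` implements analysis-of-traits node statistics. Node means are
recursive: a node's mean is the unweighted average of its daughters' means,
each daughter counting once regardless of size, which removes
sampling-imbalance bias (a tip-count-weighted variant exists for sensitivity
analysis). The divergence size `D` at a bifurcation is the absolute
difference of the two daughter means; at a true polytomy it is the standard
deviation of the daughter means. Each node's divergence sum of squares
`SS_k = sum_j (mean_dj - mean_k)^2` is weighted by the node's descendant tip
count (`weighting = "tips"`, the default) and normalized over all internal
nodes to a contribution index CI summing to 1. Tip-count weighting is the
default because a deep split separating two large clades moves many species
at once: with ~1000 tips, only a weighted score lets one ancient divergence
dominate a thousand shallow ones, which is the behavior expected of the
statistic; the unweighted variant is kept as an option. Significance of `D`
comes from shuffling tip values across all tips (999 permutations by
default; p floor 0.001). The report lists all nodes with CI above a floor
(default 0.005), ranked by CI, with tip counts, node ages, and daughter
clade summaries.

## The synthetic-data generator

`simulate_sla_dataset()` generates the package's study conditions with known
ground truth:

* **Tree**: ultrametric, root depth 325 Myr, one deep split at half the root
  depth into a minor clade (3% of tips, gymnosperm-like) and a major clade;
  pure-birth topologies within clades. The deep two-clade split mirrors the
  seed-plant gymnosperm/angiosperm divergence.
* **Species trait**: multivariate normal with covariance `sigma2 * V(lambda)`
  (lambda-rescaled Brownian covariance) around clade means; the minor clade
  is offset by -0.351 log10 units (gymnosperm leaves are heavier per area).
  Default rate `sigma2 = 4e-4` per Myr on the log10 scale.
* **Sites**: 16 climate/soil variables from a latent-factor Gaussian model;
  climate variables share a block factor (pairwise correlation 0.5), each
  soil variable is correlated `env_corr` (default -0.5) with a designated
  climate partner (total phosphorus with mean annual temperature, total
  nitrogen with precipitation), echoing observed climate-nutrient
  correlations; affine maps put each variable on a plausible field range.
* **Records**: each species is assigned 3-5 records (the default scenario;
  the generic generator defaults to 1-4, the sparser ratio typical of trait
  databases) at uniformly random sites;
  `log_sla = species value + environmental effect + Normal(0, tau^2)`, with
  linear effects on standardized coldest-month temperature, precipitation,
  soil nitrogen and evapotranspiration ratio, and centered quadratic effects
  on precipitation and moisture index; `tau = 0.141`.

Effect sizes were set by variance bookkeeping so the realized fractions land
near 0.5 phylogenetic / 0.3 environmental / 0.2 intraspecific at the default
300 species x 40 sites; with seed 1 they realize as 0.52 / 0.27 / 0.21. The
truth ledger stores the three latent components per record and recomputes
realized fractions from them (each component's variance over the sum), so
recovery tests compare against an exact decomposition rather than nominal
targets.

What the generator does **not** emulate: real biogeography or spatial
autocorrelation of sites; non-Gaussian trait distributions;
Ornstein-Uhlenbeck or rate-shifted evolution (only lambda-rescaled Brownian
motion); species-environment interactions (effects are additive at the
record level); phylogenetically clustered site occupancy. Passing recovery
tests therefore show the estimator works under its own assumptions, not that
those assumptions hold for any particular field dataset.

## Numerical choices

* PCoA eigenvalues below `1e-10 x` the largest are discarded and counted
  (patristic matrices need not be Euclidean-embeddable); each axis is
  flipped so its largest-magnitude entry is positive, making output
  reproducible across linear-algebra backends.
* Brownian covariances are factored by Cholesky; a singular covariance
  (duplicate tip depths) raises an informative error rather than being
  jittered.
* The lambda likelihood returns `-Inf` for any lambda making `V(lambda)`
  non-positive-definite, so the optimizer stays inside the feasible region;
  on ultrametric trees the feasible upper bound is 1.
* Permutation p-values use the add-one convention, so `p >= 1/(n_perm+1)`
  always.
* `intraspecific_contribution()` computes `R2_R` from within-species sums of
  squares directly; all-singleton species give `R2_R = 1` exactly, not just
  numerically.
* One global seed expands into fixed per-stage sub-seeds, so any stage can
  be re-run in isolation with identical draws.

## Problem sizes

The test-suite simulations use 40-80 species and 10-20 sites for
pipeline-level checks, 200-tip trees for estimator calibration
(lambda recovery over 20 replicates per generating value; K over 100
Brownian replicates), 200 replicates for the permutation-test type-I check,
and the full default scenario (300 species, ~1200 records) for partition
recovery -- sizes at which each check's sampling error is comfortably inside
the tolerance it asserts.

## Known limitations

* Stepwise selection is greedy; individual commonality components inherit
  its path-dependence (see above), and selection bias inflates single-class
  R^2 slightly upward. The class *totals* are the stable quantities.
* The intraspecific estimate relies on an OLS R^2 of species indicators on
  residuals; with very few records per species this R^2 is mechanically
  inflated, shrinking the intraspecific share. The record-per-species ratio
  of the data should be kept in mind when interpreting it.
* Moran's I with raw inverse-distance weights has low power on small trees;
  its magnitude is not comparable across weighting conventions.
* The PVR phylogenetic total absorbs any species-level signal, including
  environmental preferences that are themselves phylogenetically conserved;
  it is an upper-bound-style attribution, which is exactly why the shared
  commonality components are reported alongside the unique ones.
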