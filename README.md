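# pvrpart

Partitioning trait variance into phylogenetic, environmental, and
intraspecific components.

## The problem

Plant functional traits such as specific leaf area (SLA, leaf area per unit
leaf dry mass, cm² g⁻¹) vary along climate and soil gradients — but related
species also resemble each other because trait values are inherited. For
trait databases that hold several records per species across many sites,
`pvrpart` answers: *how much of the total variation in `log10(SLA)` is
attributable to phylogenetic relatedness, to climatic conditions, to soil
properties, and to variation within species — and where along the phylogeny
was the interspecific part generated?*

It is written for trait ecologists and comparative biologists working with
a species-by-record trait table (CSV/TSV) and a dated phylogeny (Newick).

## What it computes

* **Phylogenetic signals** with tip-permutation tests: Moran's *I* (inverse
  patristic-distance weights), Abouheif's *C*<sub>mean</sub> (node-count
  path-product proximity), Blomberg's *K*, and Pagel's *λ* by maximum
  likelihood.
* **PVR variance partition** — the core estimator. Phylogeny is represented
  by principal-coordinate axes of the patristic distance matrix
  ("phylogenetic eigenvectors"); the 2³−1 = 7 OLS models over the predictor
  classes {P, C, S} are each reduced by forward AIC, and their R² values are
  decomposed by commonality analysis:
  U<sub>P</sub> + U<sub>C</sub> + U<sub>S</sub> + C<sub>PC</sub> +
  C<sub>PS</sub> + C<sub>CS</sub> + C<sub>PCS</sub> = R²<sub>PCS</sub>.
  The intraspecific contribution is (1 − R²<sub>PCS</sub>)(1 − R²<sub>R</sub>),
  where model R regresses the full-model residuals on species identity.
* **Nested variance decomposition** (REML random intercepts) across spatial
  or taxonomic scales, and **mixed-model environment screens** with
  AIC-based linear/quadratic choice and group-interaction tests.
* **Node contribution indices**: recursive (analysis-of-traits) node means,
  divergence sizes *D*, tip-weighted contribution index CI per internal node
  (ΣCI = 1), permutation *p*-values, and a ranked report.
* **A synthetic-data generator** (trees, λ-rescaled Brownian traits,
  correlated climate/soil gradients, intraspecific noise) that carries an
  exact ground-truth variance decomposition, so every stage has a recovery
  test.

## Worked example

```r
library(pvrpart)

ds <- simulate_sla_dataset(seed = 1)   # 300 species, 40 sites, known truth
ds$truth
#> Synthetic ground truth (realized variance fractions)
#>   phylogenetic    0.523
#>   environmental   0.268
#>   intraspecific   0.210

phylo_signal(ds, n_perm = 199, seed = 1)
#> Phylogenetic signals
#>   Moran's I            0.4074   p = 0.025
#>   Abouheif's C_mean    0.6326   p = 0.005
#>   Blomberg's K         0.0241   p = 0.005
#>   Pagel's lambda       0.9227   p = 0.005

pvr_partition(ds, variant = "interactions", quad_screen = TRUE)
#> PVR variance partition (interactions variant; 1188 records, 297 eigenvectors)
#>   Relative contributions (% of total variance):
#>     phylogenetic relatedness (total)  57.92
#>     intraspecific variation           17.69
#>     climatic conditions (total)       20.80
#>     soil properties (total)           13.68
#>     three-way joint (C_PCS)            0.34

head(aot_report(ds$tree, species_trait(ds), n_perm = 199, seed = 2), 3)
#>   rank node        ci         d     p   n      age
#> 1    1  302 0.1858414 0.2905821 0.010 291 162.5000
#> 2    2  303 0.1822234 0.3148786 0.005 243 128.8681
#> 3    3  301 0.1694026 0.2732396 0.005 300 325.0000
```

Reading the output: the partition recovers the generating fractions — the
phylogenetic total (57.9%) sits close to the realized truth (52.3%; PVR
deliberately absorbs as much species-level signal as the axes can carry),
and the intraspecific estimate (17.7%) tracks the generated 21.0%. Blomberg's
*K* is far below 1 because record noise and environmental effects dilute the
Brownian species signal, while λ stays near 1 — the same qualitative pattern
(tiny *K*, large λ, both highly significant) that real continental SLA
compilations show. In the node report, the deepest splits carry the largest
contribution indices, with permutation *p*-values at or near the attainable
floor.

Real data enter through the same interface:

```r
rec  <- read_trait_table("records.csv", column_map = c(sla = "SLA_cm2_g"))
tree <- read_tree("phylogeny.nwk")
ds   <- harmonize(rec, tree)
res  <- run_full_analysis(ds, list(n_perm = 999, seed = 1))
write_results(res, "results/")
```

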