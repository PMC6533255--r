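# strategyspace

Trait-based ecological strategy surfaces, strategy-space hypervolumes,
and probabilistic extinction forecasts for terrestrial mammals and
birds.

## The scientific problem

A species' *ecological strategy* is its position in a multivariate
trait space summarizing how it acquires, uses and releases resources.
This package works with the five-trait parameterization standard for
mammal/bird macroecology: body mass (g), litter/clutch size, habitat
breadth (number of suitable IUCN habitat classes), generation length
(years), and a continuous diet axis derived from ten compositional
diet categories. It answers three questions for any species pool with
these traits:

1. **What are the major strategy gradients?** Traits are transformed
   (log10 for mass, litter/clutch and generation length; square root
   for habitat breadth), z-scored, and ordinated by PCA. The first two
   components form the *ecological strategy surface*; occurrence
   probability across the surface is mapped with a bivariate
   kernel density estimate and highest-density-region contours at the
   0.5, 0.95 and 0.99 quantiles.
2. **How much of trait space is actually occupied?** The
   five-dimensional strategy space of a species set is the region
   enclosed by a Gaussian-kernel one-class SVM fitted to the
   standardized trait cloud; its volume (in SD^5 units) is measured by
   uniform Monte-Carlo sampling of an expanded bounding box:

   `V = box volume x Pr(uniform box sample classified 'in')`

   Observed volumes are compared against four null models of trait
   variation — independent uniform margins (a hypercube), independent
   normal margins (a hypersphere), independently permuted observed
   margins, and a correlated multivariate normal (a hyperellipsoid) —
   with occupation = V_obs / mean(V_null) over replicate null fits and
   a rank-based permutation p-value.
3. **What does the extinction debt cost?** Each IUCN Red List category
   carries a 100-year extinction probability (CR 0.999, EN 0.667, VU
   0.1, NT 0.01, LC 0.0001; Data Deficient species configurable). A
   *projected* scenario removes the expected per-category counts;
   a *randomized* scenario removes the same total blind to identity.
   Replicated scenario ensembles yield volume-contraction
   distributions (compared by a Kolmogorov-Smirnov test and effect
   sizes against the observed volume) and per-trait shift tests with
   rank-based p-values.

Missing trait values are filled by chained-equation multiple
imputation (predictive mean matching) informed by the other traits and
by phylogenetic eigenvectors of class-level trees, producing an
ensemble of completed datasets over which ordination scores are
averaged.

A synthetic-data module generates communities with the statistical
structure the analysis assumes — log-normal body mass spanning orders
of magnitude, the reported pairwise trait correlations, guild-structured
compositional diets, realistic IUCN category frequencies optionally
coupled to a trait, per-trait missingness — so every stage is testable
without any data download.

## Worked example

```r
library(strategyspace)

spec <- synth_spec(n_species = 600,
                   risk_trait_coupling = list(trait = "body_mass",
                                              strength = 1.5))
table <- generate_trait_table(spec, seed = 42)
masked <- inject_missingness(table, spec, seed = 43)

ids <- split(table$species_id, table$taxon_class)
trees <- list(
  mammal = generate_tree(length(ids$mammal), seed = 44, tip_labels = ids$mammal),
  bird   = generate_tree(length(ids$bird),   seed = 45, tip_labels = ids$bird))

config <- run_config(seed = 1, n_replicates = 99, n_imputations = 5,
                     svm_params = list(nu = 0.01, gamma = NULL,
                                       samples_per_point = 50,
                                       max_samples = 5e6,
                                       box_expansion = 0.2))
result <- run_pipeline(masked$table, config, trees = trees, quiet = TRUE)
print(result)
```

prints (about half a minute on one CPU):

```
Ecological strategy pipeline
  species: 600 (PC1+PC2 explain 57% of trait variation)
  combined strategy space: 658.3 SD^5
  mammal 548.4 / bird 409.6 SD^5, intersection 36% of union
  occupation of null 1: 13% (p = 0.01)
  occupation of null 2: 77% (p = 0.02)
  occupation of null 3: 87% (p = 0.01)
  occupation of null 4: 92% (p = 0.14)
  scenarios: projected mean 591 vs randomized mean 644.7 SD^5 (KS D = 0.73, p = 1.29e-25)
  body mass: 39.4 g -> 31.4 g (decrease, p = 0.01); median mass -13.6% (12.9-13.8%)
```

Reading the output: the five traits collapse onto a surface whose two
leading axes carry 57% of the variation; the realized strategy space
fills only 13% of the hypercube null (every trait combination equally
likely), and occupation rises as the null gets more realistic
(77% hypersphere, 87% permuted margins, 92% correlated normal).
Because extinction risk was coupled to body mass in this synthetic
community, the projected scenario contracts strategy space well below
the trait-blind randomized scenario losing the same number of species
(KS D = 0.73), and the surviving pool is downsized: geometric-mean
body mass drops from 39.4 g to 31.4 g at the smallest p the 99
replicates can resolve (p = 1/(99+1) = 0.01).

`masked$table` can be written with `write_trait_table()` and re-read
with `read_trait_table()`, which also accepts the EltonTraits /
figshare column conventions of the real mammal-bird trait databases;
real class-level phylogenies load via `read_tree()`.

A thin CLI over the same functions ships in
`inst/scripts/strategyspace` with `synth`, `run`, `impute`, `surface`,
`hypervolume`, `nulls` and `extinction` subcommands.

## Vignette

`vignettes/ecological-strategy-space.Rmd` documents the model and its
assumptions, every tunable that matters (SVM kernel width, bandwidth
rules, imputation settings, extinction probabilities), what the
synthetic generator does and does not emulate, and known limitations.
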