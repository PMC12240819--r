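# coretrans

Biogeographical regions — bioregions — hold distinct regional species
pools, but how is biodiversity organised *inside* them? `coretrans`
implements a network-based pipeline that answers this for any
species-by-grid-cell presence dataset: it delineates bioregions, measures
four complementary biodiversity aspects per grid cell, groups cells into
recurring **biogeographical sectors**, and tests whether those sectors form
the ordered core-to-transition layering — species-rich endemic cores
grading into transition zones of widespread and foreign species — together
with its environmental and compositional signatures.

The package is written for macroecologists and biogeographers working with
rasterized range maps or inventory data (tibbles in, tibbles out,
`tidy()`/`glance()`/`autoplot()` methods on fitted objects), and ships a
synthetic-landscape generator with full ground truth so every stage can be
validated end to end.

## The method

With cells and species as the two node types of a bipartite presence
network, a map-equation community detection yields modules = bioregions
plus their characteristic species. For each cell of a retained module:

* relative species richness: `(I_c - mean(I_c)) / sd(I_c)` over the
  module's cells, where `I_c` counts the cell's links to its module's
  species;
* biota overlap: `O_c / L_c`, the fraction of the cell's links that leave
  its module (0 = no non-characteristic species);
* endemicity: median over the present characteristic species of
  `I_s / L_s`, the share of a species' range inside its bioregion;
* relative occupancy: median over the same species of the within-module
  z-score of `I_s`.

Cells are clustered on the standardized aspects in two steps — per taxon
(k by GoF elbow, k-means best of 100 restarts) and jointly across taxa
(k by maximal mean adjusted mutual information with the per-taxon
partitions). Downstream, the package tests sector adjacency (one-sided
binomial tests against a 1-in-6 chance null), environmental distinctness
(multinomial logit vs intercept-only null, AICc difference > 10, McFadden
pseudo-R²), nestedness vs turnover of sector biotas (multi-site Sørensen
partition), variance partitioning of cell richness (regional pool vs
species sorting), and core-area richness (within-region randomization).

## A worked example

```r
library(coretrans)

# a synthetic landscape with known regions, hotspots and permeable borders
land <- generate_landscape(landscape_config(seed = 42))

res <- run_pipeline(land, n_trials = 30, restarts = 50, seed = 7)
res
#> <ct_pipeline> 1 taxa, 3583 cells clustered into 5 sectors

glance(res$sectors)
#> # A tibble: 1 x 6
#>   k_general   gof mean_ami n_cells n_taxa weight_by_taxon
#>       <int> <dbl>    <dbl>   <int>  <int> <lgl>
#> 1         5 0.776    1        3583      1 FALSE

# sectors are ordered core -> transition; compare with ground truth
library(dplyr)
inner_join(tidy(res$sectors), land$truth_cells, by = "cell_id") |>
  summarise(rho = cor(sector, core_rank, method = "spearman"))
#> # A tibble: 1 x 1
#>     rho
#>   <dbl>
#> 1 0.837

report(res)   # aspect medians by sector, adjacency frequencies,
              # nestedness and variance-partition tables
```

The Spearman correlation near 0.84 says the inferred sector order tracks
the planted core-to-transition layering; in `report(res)` the aspect
medians fall monotonically from sector 1 (rich, endemic) outward, the
significant adjacency pairs concentrate on consecutive sectors, and
between-sector dissimilarity of characteristic species is mostly
nestedness. (Numbers above are from the shown seeds; any seed reproduces
the pattern.)

Plotting: `autoplot(res$sectors, land$grid)` draws the sector map,
`plot_sector_aspects(res$aspects, res$sectors)` the aspect distributions,
`plot_gof_elbow()` a GoF curve with its elbow.

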