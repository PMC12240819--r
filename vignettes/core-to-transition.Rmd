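---
title: "The core-to-transition organization of bioregions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The core-to-transition organization of bioregions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coretrans)
```

## The question and the model

Biogeographical regions (bioregions) are sets of grid cells that share a
distinct regional species pool. `coretrans` asks how biodiversity is
organised *within* such regions: whether cells arrange into a small number
of recurrent area types — "sectors" — running from species-rich, endemic-rich
cores to transition zones dominated by widespread species and by species
whose affinity lies with neighbouring regions.

The analysis chain is:

1. **Bioregion delineation.** Species and grid cells are the two node types
   of a bipartite network, linked by presence. A flow-compression community
   detection (the map equation, via Infomap in `igraph`) jointly assigns
   cells and species to modules: a module's cells are a bioregion, its
   species the characteristic pool. The heuristic is run many times and the
   partition with the lowest two-level map-equation codelength is kept.
2. **Four cell-level aspects** from network cartography, per retained
   module: relative species richness (within-module z-score of the cell's
   characteristic richness), biota overlap (share of the cell's presences
   that are non-characteristic), endemicity and relative occupancy (cell
   medians over the present characteristic species of, respectively, the
   species' inside-range fraction and its within-module occupancy z-score).
3. **Two-step sector clustering.** Per taxon, k-means over the standardized
   aspects with k chosen at the elbow of the goodness-of-fit curve; then a
   joint k-means over all taxa with k chosen to maximise the mean adjusted
   mutual information (AMI) with the taxon-specific partitions. Sectors are
   reported in a canonical core-to-transition order (decreasing centroid
   relative richness).
4. **Downstream tests**: one-sided binomial tests of sector adjacency,
   multinomial logit models of sector versus environment compared to a null
   by AICc, a multi-site Sorensen partition of between-sector dissimilarity
   into turnover and nestedness, a variance partition of cell richness into
   regional-pool and sorting components, and a randomization test of core
   richness.

## Numerical conventions

Several conventions are under-determined by the verbal description of the
method; `coretrans` fixes them as follows and surfaces each choice in the
relevant function documentation.

* **Standard deviation** in all z-scores is the sample (n − 1) convention,
  the default of the statistical environments this analysis style is run
  in; a `sd_convention = "population"` switch exists.
* **Medians** of even-length sets are midpoints of the two central values.
* **Degenerate modules** — no cells, no species, all cells with identical
  characteristic richness, or all species with identical occupancy — are
  excluded before any aspect is computed, with logged reasons; their cells
  never enter the clustering feature matrix and are not imputed.
* **Tiny modules.** Community detection on permeable landscapes sometimes
  isolates a genuine but minuscule "transition community" — a boundary
  strip of cells held together by a handful of widespread species — and
  such a partition can be the true codelength optimum, not a search
  failure. A module that small is not a biogeographical region: its
  within-module z-scores are statistics of three or four species.
  `filter_modules()` therefore accepts `min_cells`/`min_species` size
  thresholds (off by default), and `run_pipeline()` excludes modules with
  fewer than 5 species by default, logging each exclusion.
* **Biota overlap counts all non-characteristic links**, including links to
  species of excluded modules: those are real presences.
* **Codelength** is evaluated by the package's own implementation of the
  two-level map equation (degree-proportional visit rates, boundary-link
  exit rates) for *every* backend, so best-of-N selection is uniform whether
  partitions come from the Infomap heuristic, from connected components, or
  are injected labels. The evaluator is pinned by hand-computed examples in
  the test suite.
* **Elbow selection** fits a continuous two-segment linear model at every
  interior candidate breakpoint and minimises the residual standard error;
  ties (within 1e-10 relative) go to the smallest k. The same rule is
  enumerated independently as a test oracle.
* **AMI** uses the exact hypergeometric expected mutual information and
  arithmetic-mean normalisation; two single-cluster labelings compare as 1.
* **Adjacency tests** default to the exact binomial tail rather than the
  continuity-corrected normal approximation. The two rules disagree on a
  few dozen (n, x) pairs below n = 200 at the 0.05 level, and the exact
  tail is the defensible decision rule at these sample sizes; the
  prop.test-compatible approximation remains available
  (`method = "prop"`). The null stays 1/6 even when fewer than seven
  sectors are present in a region, mirroring the global chance expectation,
  and is flagged in the output.
* **AICc** uses k = (K − 1)(p + 1) parameters and n = cells in the region;
  the environmental verdict requires the null's AICc to exceed the model's
  by strictly more than 10.
* **Variance partition** fractions are drops in *multiple* R² when the
  focal variable leaves the saturated weighted least-squares fit — for
  nested OLS fits these are non-negative by construction, which an adjusted
  R² would not guarantee; the adjusted R² is reported alongside. Weights
  (inverse region size) are normalised to sum to the cell count, so
  inference is scale-invariant.
* **Permutation p-values** use the add-one rule (1 + hits)/(1 + draws) and
  can never be exactly zero.
* The default **core** of a region is the leading sectors, in
  core-to-transition order, that jointly cover about 30% of its cells;
  any sector set can be supplied instead.

## The synthetic landscape: what it emulates, and what not

No quantitative generative model exists for the study system, so the
generator makes explicit, documented stand-in choices. It emulates the
statistical structure the analysis expects from rasterized range maps:

* a regular lattice tiled by contiguous rectangular regions, each with its
  own species pool and a **hotspot** (the block centre);
* species ranges as Chebyshev discs (compatible with queen adjacency)
  whose centroids concentrate near the hotspot with density
  `exp(-hotspot_concentration * distance)`;
* **right-skewed range sizes** (log-normal), with the location parameter
  growing with the centroid's distance from the hotspot
  (`range_size_gradient`), so boundary species are the most widespread —
  occupancy rises toward boundaries;
* **permeable boundaries**: a species whose range touches a region border
  spills up to `spill_depth` cells into the neighbour with a probability
  `permeability` scaled by a logistic preference for large-ranged species,
  so boundary biotas are dominated by widespread, low-endemicity species;
* environmental covariates with region-level means plus a within-region
  radial trend and Gaussian noise.

Range sizes are parameterised relative to region area
(`range_size_frac`, default 0.12 of the region at the hotspot): regional
pools must overlap broadly within their region for bioregion delineation to
be meaningful at any lattice size — with absolute range sizes, enlarging
the lattice would fragment regions into spatially local communities, which
is a different (and for this purpose degenerate) regime.

What the generator does **not** emulate: irregular region shapes and
coastlines, spatial autocorrelation of the environment beyond the radial
trend, abundance structure, taxon-specific grid resolutions, or
eco-evolutionary dynamics. Passing recovery tests on these landscapes
therefore shows that the pipeline recovers planted core-to-transition
structure under the stated assumptions — not that real data possess that
structure.

The defaults (60 x 60 lattice, 4 regions, 200 species per region) are the
reference study conditions used by the recovery tests; the tiny-landscape
variants in the unit tests only shrink the lattice for speed.

## Design choices where the design was open

* **Blocks, not Voronoi regions.** Adjacency tests need contiguous regions;
  rectangular blocks guarantee it and make the hotspot and distance ranks
  unambiguous. Irregular-border generation was considered and dropped as
  adding realism orthogonal to what the downstream statistics test.
* **Queen adjacency** is the default neighbour scheme on square cells (rook
  available); each adjacent ordered cell pair counts once.
* **Uniform k-means weights** by default; `weight_by_taxon` reproduces the
  sensitivity variant that weights cells by the inverse cell count of their
  taxon. k-means restarts use seeded random centroid selection with
  independent per-restart streams derived from one master seed, and every
  stochastic operation in the package takes an explicit seed, so a single
  master seed makes the whole pipeline reproducible.
* **Reference class** of the multinomial model is the largest sector;
  covariates are standardized inside the fit (constant columns carry no
  information and are zeroed rather than erroring).
* **Within-region permutation** for the core-richness null: per-sector cell
  counts are preserved region by region, which is the sharper null when
  region sizes differ.
* The general clustering sweep stops at k = 14; beyond the largest
  taxon-specific optimum there is nothing for the AMI criterion to reward.

## Problem sizes and accuracy of the shipped checks

The recovery and calibration checks shipped with the package run the full
pipeline on the reference landscape (3,600 cells, 800 species, one taxon)
with 10-30 partition trials and 25-50 k-means restarts per k, and the
archetype recovery check on 3 taxa x 240 cells over 10 seeds; these sizes
give stable results while keeping a complete run in minutes. A
production-scale analysis (several taxa, tens of thousands of cells, many
thousands of partition trials, 100 restarts) is a straightforward scale-up
of the same calls.

## Known limitations

* The map-equation backend is two-level; hierarchical partitions are out of
  scope, as are weighted (abundance) links.
* Aspects are undefined for cells with no characteristic species; such
  cells are excluded (and logged), so sector maps can have holes.
* The multinomial environment models ignore spatial autocorrelation of
  residuals; on strongly autocorrelated data the AICc verdicts are
  anti-conservative.
* With fewer than seven sectors present, the fixed 1-in-6 adjacency null is
  conservative in one direction and liberal in the other; the package keeps
  it fixed (flagged) to match the global chance expectation.
* On the synthetic landscapes, the core-richness randomization is expected
  to be non-significant: ranges are contiguous discs, so a spatially
  scattered random "core" intersects at least as many ranges as the true
  contiguous core, and the pooled core richness is not elevated. Detecting
  the elevation reported for real data requires many narrow-ranged species
  wholly confined to the core, a feature the disc generator produces only
  weakly. The test's mechanics (permutation scheme, add-one p-value) are
  validated on constructed cases instead.
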