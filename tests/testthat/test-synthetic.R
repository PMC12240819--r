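test_that("landscapes are reproducible and structurally valid", {
  ls1 <- small_landscape(seed = 5)
  ls2 <- small_landscape(seed = 5)
  expect_identical(ls1$occurrences, ls2$occurrences)
  expect_identical(ls1$env, ls2$env)
  expect_identical(ls1$truth_species, ls2$truth_species)

  # every cell has a region; core_rank in (0, 1]
  expect_equal(nrow(ls1$truth_cells), 400)
  expect_true(all(ls1$truth_cells$core_rank > 0 &
                    ls1$truth_cells$core_rank <= 1))
  expect_equal(sort(unique(ls1$truth_cells$region_id)), 1:4)
  # regions tile as contiguous blocks: every region is a rectangle
  grid <- dplyr::left_join(ls1$grid, ls1$truth_cells, by = "cell_id")
  rect <- dplyr::summarise(
    dplyr::group_by(grid, region_id),
    filled = dplyr::n() == (max(row) - min(row) + 1) * (max(col) - min(col) + 1))
  expect_true(all(rect$filled))
  # no duplicate presences; all presence cells exist
  expect_equal(nrow(ls1$occurrences),
               nrow(dplyr::distinct(ls1$occurrences)))
  expect_true(all(ls1$occurrences$cell_id %in% ls1$grid$cell_id))
})

test_that("zero permeability confines species to their origin region", {
  ls <- small_landscape(seed = 6, permeability = 0)
  occ <- dplyr::left_join(ls$occurrences,
                          dplyr::select(ls$truth_cells, cell_id, region_id),
                          by = "cell_id")
  origin <- ls$truth_species$origin_region[
    match(occ$species_id, ls$truth_species$species_id)]
  expect_true(all(occ$region_id == origin))
  # the bipartite graph is disconnected across regions
  g <- build_bipartite(ls$occurrences)
  pt <- detect_bioregions(g, backend = "components")
  expect_gte(dplyr::n_distinct(tidy(pt)$module), 4)
})

test_that("mean biota overlap is non-decreasing in permeability", {
  overlap_at <- function(perm) {
    mean(sapply(1:10, function(seed) {
      ls <- small_landscape(seed = seed, permeability = perm)
      occ <- dplyr::left_join(ls$occurrences,
                              dplyr::select(ls$truth_cells, cell_id, region_id),
                              by = "cell_id")
      origin <- ls$truth_species$origin_region[
        match(occ$species_id, ls$truth_species$species_id)]
      # per-cell share of presences from foreign species, averaged
      mean(sapply(split(origin != occ$region_id, occ$cell_id), mean))
    }))
  }
  o <- sapply(c(0, 0.25, 0.75), overlap_at)
  expect_true(all(diff(o) > 0))
})

test_that("boundary-centred species are the most widespread", {
  sizes <- dplyr::bind_rows(lapply(1:5, function(seed) {
    ls <- small_landscape(seed = seed)
    dplyr::left_join(ls$truth_species,
                     dplyr::select(ls$truth_cells, cell_id, core_rank),
                     by = c(centroid_cell = "cell_id"))
  }))
  outer <- sizes$true_range_size[sizes$core_rank > 0.5]
  inner <- sizes$true_range_size[sizes$core_rank <= 0.5]
  expect_gt(mean(outer), mean(inner))
})

test_that("truth layers bin core rank evenly and deterministically", {
  truth <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:100), region_id = 1L,
    distance_to_hotspot = 1:100, core_rank = (1:100) / 100)
  layered <- truth_sector_layers(truth, 4)
  expect_equal(unname(table(layered$layer)), rep(25L, 4), ignore_attr = TRUE)
  expect_true(all(layered$layer[layered$core_rank <= 0.25] == 1))

  expect_error(truth_sector_layers(truth, 1), class = "coretrans_config_error")
  small <- truth[1:3, ]
  expect_warning(lay2 <- truth_sector_layers(small, 4), "fewer cells")
  expect_lte(max(lay2$layer), 3)

  # ties at bin edges: broken by cell_id order, reproducibly
  tied <- dplyr::mutate(truth, core_rank = rep(c(0.25, 0.5, 0.75, 1), 25))
  l1 <- truth_sector_layers(tied, 4)
  l2 <- truth_sector_layers(tied[sample(1:100), ], 4)
  expect_equal(l1, dplyr::arrange(l2, cell_id))
})

test_that("landscape config validates its inputs", {
  expect_error(landscape_config(n_regions = 0), class = "coretrans_config_error")
  expect_error(landscape_config(permeability = 1.5),
               class = "coretrans_config_error")
  expect_error(landscape_config(hotspot_concentration = -1),
               class = "coretrans_config_error")
  expect_error(landscape_config(species_per_region = 0),
               class = "coretrans_config_error")
})

test_that("archetype aspect simulator plants recoverable structure", {
  asp <- simulate_archetype_aspects(n_taxa = 2, n_archetypes = 4,
                                    cells_per_taxon = 100, seed = 3)
  expect_equal(nrow(asp), 200)
  expect_equal(dplyr::n_distinct(asp$archetype), 4)
  # same seed twice
  expect_identical(asp, simulate_archetype_aspects(
    n_taxa = 2, n_archetypes = 4, cells_per_taxon = 100, seed = 3))
  # archetype centroids separated by >= spacing
  cent <- dplyr::summarise(
    dplyr::group_by(asp, archetype),
    dplyr::across(c(relative_richness, biota_overlap, endemicity,
                    relative_occupancy), mean))
  d <- as.matrix(dist(cent[, -1]))
  expect_gt(min(d[d > 0]), 8 - 1)
})
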