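test_that("species aspects follow the endemicity and z-score identities", {
  # module 1: species a (3 cells in, 1 out), b (2 in), c (1 in)
  occ <- occ_from(a = c("x1", "x2", "x3", "y1"), b = c("x1", "x2"), c = "x1",
                  d = c("y1", "y2"), e = "y2")
  g <- build_bipartite(occ)
  pt <- manual_partition(g, list(x1 = 1, x2 = 1, x3 = 1, y1 = 2, y2 = 2,
                                 a = 1, b = 1, c = 1, d = 2, e = 2))
  pt <- suppressMessages(filter_modules(pt, g))
  spp <- species_aspects(g, pt)
  expect_equal(spp$c_endem[spp$species_id == "a"], 3 / 4)
  expect_equal(spp$c_endem[spp$species_id == "b"], 1)    # endemic
  # module-1 I_s = {3, 2, 1}: species b sits on the mean -> z = 0
  expect_equal(spp$z_spp[spp$species_id == "b"], 0)
  expect_equal(spp$z_spp[spp$species_id == "a"], 1)      # (3 - 2) / sd{1,2,3}
})

test_that("cell aspects reproduce the worked ratios", {
  # cell x1 carries 10 links, 4 of them to outside species
  inside <- sprintf("in%d", 1:6)
  outside <- sprintf("out%d", 1:4)
  args <- c(
    setNames(lapply(inside, function(s) c("x1", "x2")), inside),
    list(in_extra = "x2"),                    # vary richness within module 1
    setNames(lapply(outside, function(s) c("x1", "y1")), outside),
    list(y_anchor = c("y1", "y2"), y_other = "y2")
  )
  occ <- do.call(occ_from, args)
  g <- build_bipartite(occ)
  labs <- c(setNames(rep(1, 7), c(inside, "in_extra")),
            setNames(rep(2, 6), c(outside, "y_anchor", "y_other")),
            x1 = 1, x2 = 1, y1 = 2, y2 = 2)
  pt <- suppressMessages(filter_modules(manual_partition(g, as.list(labs)), g))
  cells <- suppressMessages(cell_aspects(g, pt))
  x1 <- cells[cells$cell_id == "x1", ]
  expect_equal(x1$L_c, 10L)
  expect_equal(x1$biota_overlap, 0.4)
  # x2 has no outside links
  expect_equal(cells$biota_overlap[cells$cell_id == "x2"], 0)
  # module-1 richness {6, 7}: z under sample sd = -1/sqrt(2), +1/sqrt(2)
  expect_equal(sort(cells$relative_richness[cells$module == x1$module]),
               c(-1, 1) / sqrt(2))
})

test_that("relative richness is an exact within-module z-score", {
  # module cells with I = {2, 4, 6}: the I = 6 cell scores z = 1 (sample sd)
  sp <- sprintf("s%d", 1:6)
  occ <- occ_from(s1 = "x3", s2 = "x3", s3 = c("x3", "x2"), s4 = c("x3", "x2"),
                  s5 = c("x3", "x2", "x1"), s6 = c("x3", "x2", "x1"))
  g <- build_bipartite(occ)
  labs <- as.list(setNames(rep(1, 9), c("x1", "x2", "x3", sp)))
  pt <- suppressMessages(filter_modules(manual_partition(g, labs), g))
  cells <- suppressMessages(cell_aspects(g, pt))
  expect_equal(cells$I_c[match(c("x1", "x2", "x3"), cells$cell_id)], c(2L, 4L, 6L))
  expect_equal(cells$relative_richness[cells$cell_id == "x3"], 1)
  # z-scores have mean 0 and sample sd 1 within the module, exactly
  expect_equal(mean(cells$relative_richness), 0, tolerance = 1e-12)
  expect_equal(sd(cells$relative_richness), 1, tolerance = 1e-12)
})

test_that("aspects match the brute-force oracle on random graphs", {
  for (seed in 1:20) {
    occ <- suppressMessages(validate_occurrences(
      random_occ(n_cells = 8, n_species = 12, p_link = 0.35, seed = seed)))
    g <- build_bipartite(occ)
    # random 2-3 module partition over nodes
    nodes <- c(g$cells, g$species)
    modules <- withr::with_seed(seed + 1000, {
      setNames(sample.int(2 + seed %% 2, length(nodes), replace = TRUE), nodes)
    })
    pt <- manual_partition(g, as.list(modules))
    pt <- suppressMessages(filter_modules(pt, g))
    retained <- pt$modules$module[pt$modules$retained]
    if (length(retained) == 0) next
    cells <- suppressMessages(cell_aspects(g, pt))
    node_modules <- setNames(pt$nodes$module, pt$nodes$node)
    ora <- oracle_aspects(as.data.frame(g$links), node_modules, retained)
    ora <- ora[order(ora$cell_id), ]
    cells <- cells[order(cells$cell_id), ]
    expect_equal(cells$I_c, ora$I_c)
    expect_equal(cells$relative_richness, ora$relative_richness)
    expect_equal(cells$biota_overlap, ora$biota_overlap)
    expect_equal(cells$endemicity, ora$endemicity)
    expect_equal(cells$relative_occupancy, ora$relative_occupancy)
  }
})

test_that("aspect correlations flag only strong pairs and handle constants", {
  n <- 1000
  x <- withr::with_seed(7, tibble::tibble(
    cell_id = as.character(seq_len(n)), taxon = "tx",
    relative_richness = rnorm(n), biota_overlap = runif(n),
    endemicity = runif(n), relative_occupancy = rnorm(n), valid = TRUE))
  tab <- aspect_correlations(x)
  expect_equal(nrow(tab), 6)
  expect_true(all(abs(tab$r) < 0.2))          # independent aspects
  expect_false(any(tab$flagged))

  y <- dplyr::mutate(x, biota_overlap = relative_richness * 0.9 +
                       rnorm(n, 0, 0.1))
  expect_true(any(aspect_correlations(y)$flagged))

  z <- dplyr::mutate(x, endemicity = 1)
  tz <- aspect_correlations(z)
  expect_true(all(tz$undefined[tz$aspect_a == "endemicity" |
                                 tz$aspect_b == "endemicity"]))
})

test_that("three qualitative levels over four aspects give 81 combinations", {
  combos <- aspect_level_combinations()
  expect_equal(nrow(combos), 81)
  expect_equal(ncol(combos), 4)
  expect_equal(nrow(dplyr::distinct(combos)), 81)
  expect_equal(nrow(aspect_level_combinations(c("lo", "hi"))), 16)
})
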