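test_that("richness decomposition centres within regions and adds up", {
  ls <- small_landscape(seed = 31)
  g <- build_bipartite(ls$occurrences)
  pt <- suppressMessages(filter_modules(
    detect_bioregions(g, backend = "truth",
                      truth_labels = truth_labels_of(ls)), g))
  cl <- classify_presences(g, pt)
  dec <- decompose_richness(cl, pt)
  expect_equal(dec$S, dec$richness_char + dec$richness_nonchar)
  sums <- dplyr::summarise(dplyr::group_by(dec, module),
                           sc = sum(centred_char), sn = sum(centred_nonchar))
  expect_true(all(abs(sums$sc) < 1e-9))
  expect_true(all(abs(sums$sn) < 1e-9))

  # worked example: 6-species pool, two cells with char richness {3, 5}
  toy <- tibble::tibble(
    species_id = c(sprintf("s%d", 1:3), sprintf("s%d", 2:6)),
    cell_id = c(rep("c1", 3), rep("c2", 5)),
    cell_module = 1L,
    species_module = 1L, characteristic = TRUE,
    origin_module = NA_integer_, excluded = FALSE)
  toy_pt <- list(modules = tibble::tibble(module = 1L, retained = TRUE))
  dec2 <- decompose_richness(toy, toy_pt)
  expect_equal(dec2$pool_size, rep(6L, 2))
  expect_equal(sort(dec2$centred_char), c(-1, 1))
})

test_that("permeability-zero landscapes have no non-characteristic sorting", {
  ls <- small_landscape(seed = 32, permeability = 0)
  g <- build_bipartite(ls$occurrences)
  pt <- suppressMessages(filter_modules(
    detect_bioregions(g, backend = "components"), g))
  dec <- decompose_richness(classify_presences(g, pt), pt)
  expect_true(all(dec$richness_nonchar == 0))
  expect_true(all(dec$centred_nonchar == 0))
})

test_that("variance partition isolates constructed signals", {
  # response exactly equal to pool_size -> its fraction dominates
  dec <- withr::with_seed(41, tibble::tibble(
    cell_id = as.character(1:200),
    module = rep(1:4, each = 50),
    pool_size = rep(c(100, 140, 180, 220), each = 50),
    centred_char = rnorm(200),
    centred_nonchar = rnorm(200),
    region_size = 50))
  dec$centred_char <- dec$centred_char -
    stats::ave(dec$centred_char, dec$module)
  dec$centred_nonchar <- dec$centred_nonchar -
    stats::ave(dec$centred_nonchar, dec$module)
  dec$S <- dec$pool_size
  vp <- suppressWarnings(weighted_variance_partition(dec, weighting = "none"))
  fr <- setNames(vp$fractions$fraction, vp$fractions$term)
  expect_gt(fr["pool_size"], 0.99)
  expect_lt(max(fr[c("centred_char", "centred_nonchar")]), 0.01)
  expect_equal(vp$r2_full, 1, tolerance = 1e-9)

  # exactly orthogonal predictors: individual fraction = marginal R2
  # (within-module centring makes both sorting terms orthogonal to
  # pool_size; residualise one against the other to finish the job)
  dec$centred_nonchar <- stats::resid(
    lm(centred_nonchar ~ centred_char + factor(module), data = dec))
  dec$S <- dec$pool_size + 3 * dec$centred_char
  vp2 <- suppressWarnings(weighted_variance_partition(dec, weighting = "none"))
  marg <- summary(lm(S ~ centred_char, data = dec))$r.squared
  fr2 <- setNames(vp2$fractions$fraction, vp2$fractions$term)
  expect_equal(unname(fr2["centred_char"]),
               vp2$r2_full - summary(lm(S ~ pool_size + centred_nonchar,
                                        data = dec))$r.squared,
               tolerance = 1e-12)
  expect_equal(unname(fr2["centred_char"]), marg, tolerance = 1e-9)

  # constant response -> all fractions zero
  dec$S <- 7
  vp3 <- suppressWarnings(weighted_variance_partition(dec, weighting = "none"))
  expect_true(all(abs(vp3$fractions$fraction) < 1e-12, na.rm = TRUE))
})

test_that("fractions are non-negative and weights behave", {
  for (seed in 1:50) {
    dec <- withr::with_seed(seed, tibble::tibble(
      cell_id = as.character(1:60), module = rep(1:3, each = 20),
      pool_size = rep(sample(50:200, 3), each = 20),
      centred_char = rnorm(60), centred_nonchar = rnorm(60),
      region_size = rep(sample(10:100, 3), each = 20),
      S = rnorm(60, 50, 10)))
    vp <- weighted_variance_partition(dec)
    expect_true(all(vp$fractions$fraction >= -1e-12, na.rm = TRUE))
    expect_true(all(vp$fractions$fraction <= vp$r2_full + 1e-12, na.rm = TRUE))
  }
  # unweighted equals weighted with equal region sizes
  dec <- withr::with_seed(9, tibble::tibble(
    cell_id = as.character(1:40), module = rep(1:2, each = 20),
    pool_size = rep(c(80, 120), each = 20),
    centred_char = rnorm(40), centred_nonchar = rnorm(40),
    region_size = 20, S = rnorm(40, 30)))
  expect_equal(weighted_variance_partition(dec, "none")$fractions,
               weighted_variance_partition(dec, "inverse-region-size")$fractions)

  # single region: pool_size constant -> fraction missing with reason
  dec1 <- dplyr::mutate(dec, module = 1L, pool_size = 100)
  vp1 <- weighted_variance_partition(dec1)
  expect_true(is.na(vp1$fractions$fraction[vp1$fractions$term == "pool_size"]))
  expect_match(vp1$fractions$reason[vp1$fractions$term == "pool_size"],
               "constant")
})

test_that("core richness test mechanics: bounds, degeneracy, errors", {
  # core sector (5 of 30 cells) holds all 12 species; the 25 non-core cells
  # hold one common species each, so a random core covering every species
  # is a 1-in-142506 draw and the observed richness is effectively unbeatable
  core_cells <- sprintf("c%02d", 1:5)
  other_cells <- sprintf("c%02d", 6:30)
  cl <- dplyr::bind_rows(
    tibble::tibble(species_id = sprintf("s%d", 1:12),
                   cell_id = rep(core_cells, length.out = 12)),
    tibble::tibble(species_id = "s1", cell_id = other_cells)) |>
    dplyr::mutate(cell_module = 1L, species_module = 1L,
                  characteristic = TRUE, origin_module = NA_integer_,
                  excluded = FALSE)
  sec <- structure(list(cells = tibble::tibble(
    cell_id = c(core_cells, other_cells), taxon = "tx",
    sector = c(rep(1L, 5), rep(2L, 12), rep(3L, 13)))), class = "ct_sectors")
  res <- core_richness_test(sec, cl, core_sectors = 1L, n_perm = 99, seed = 2)
  expect_equal(res$observed, 12)
  expect_equal(res$p_value, 1 / 100)   # the add-one floor

  expect_error(core_richness_test(sec, cl, core_sectors = 1L, n_perm = 0),
               class = "coretrans_validation_error")
  expect_error(core_richness_test(sec, cl, core_sectors = 99L, n_perm = 10),
               class = "coretrans_validation_error")

  # degenerate core covering all cells is flagged
  expect_message(
    resd <- core_richness_test(sec, cl, core_sectors = 1:3, n_perm = 10, seed = 1),
    "covers all cells")
  expect_true(resd$degenerate)
})

test_that("core test p-values are roughly uniform under random labels", {
  pvals <- withr::with_seed(77, {
    replicate(300, {
      cells <- sprintf("c%d", 1:30)
      cl <- tibble::tibble(
        species_id = sample(sprintf("s%d", 1:40), 150, replace = TRUE),
        cell_id = sample(cells, 150, replace = TRUE),
        cell_module = 1L, species_module = 1L, characteristic = TRUE,
        origin_module = NA_integer_, excluded = FALSE) |>
        dplyr::distinct()
      sec <- structure(list(cells = tibble::tibble(
        cell_id = cells, taxon = "tx",
        sector = sample(rep(1:3, each = 10)))), class = "ct_sectors")
      core_richness_test(sec, cl, core_sectors = 1L, n_perm = 39,
                         seed = sample.int(1e6, 1))$p_value
    })
  })
  # add-one permutation p-values are super-uniform: check mean and spread
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.65)
  expect_gt(mean(pvals <= 0.25), 0.1)
  expect_lt(mean(pvals <= 0.05), 0.12)
})
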