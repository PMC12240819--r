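# Small in-code fixtures shared across test files.

# occurrence tibble from a compact "species = cells" spec, e.g.
# occ_from(s1 = c("c1", "c2"), s2 = "c1")
occ_from <- function(..., taxon = "tx") {
  sp <- list(...)
  dplyr::bind_rows(lapply(names(sp), function(s) {
    tibble::tibble(taxon = taxon, species_id = s, cell_id = sp[[s]])
  }))
}

# two disconnected blocks: species A,B on cells 1,2; C,D on cells 3,4
two_block_occ <- function() {
  occ_from(A = c("c1", "c2"), B = c("c1", "c2"),
           C = c("c3", "c4"), D = c("c3", "c4"))
}

# a partition built by hand from node -> module pairs
manual_partition <- function(graph, modules) {
  detect_bioregions(graph, backend = "truth",
                    truth_labels = tibble::tibble(
                      node = names(modules),
                      module = unname(unlist(modules))))
}

# random bipartite occurrence set with guaranteed non-empty nodes
random_occ <- function(n_cells, n_species, p_link = 0.3, seed = 1) {
  withr::with_seed(seed, {
    links <- expand.grid(
      species_id = sprintf("s%02d", seq_len(n_species)),
      cell_id = sprintf("c%02d", seq_len(n_cells)),
      stringsAsFactors = FALSE
    )
    keep <- stats::runif(nrow(links)) < p_link
    # make sure every node keeps at least one link
    for (s in unique(links$species_id)) {
      rows <- which(links$species_id == s)
      if (!any(keep[rows])) keep[sample(rows, 1)] <- TRUE
    }
    for (cl in unique(links$cell_id)) {
      rows <- which(links$cell_id == cl)
      if (!any(keep[rows])) keep[sample(rows, 1)] <- TRUE
    }
    dplyr::mutate(tibble::as_tibble(links[keep, ]), taxon = "tx")
  })
}

# small grid tibble for a rows x cols lattice
lattice_grid <- function(rows, cols, resolution_km = 111) {
  g <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  validate_grid(tibble::tibble(
    cell_id = sprintf("c%03d-%03d", g$row, g$col),
    row = g$row, col = g$col
  ), resolution_km = resolution_km)
}

# tiny landscape for fast end-to-end tests
small_landscape <- function(seed = 11, ...) {
  generate_landscape(landscape_config(
    grid_rows = 20, grid_cols = 20, n_regions = 4, species_per_region = 40,
    seed = seed, ...))
}

truth_labels_of <- function(landscape) {
  dplyr::bind_rows(
    dplyr::select(landscape$truth_cells, node = cell_id, module = region_id),
    dplyr::select(landscape$truth_species, node = species_id,
                  module = origin_region)
  )
}

expect_no_message_class <- function(expr) suppressMessages(expr)
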