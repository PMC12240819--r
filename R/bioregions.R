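#' Delineate bioregions by community detection on the bipartite network
#'
#' Runs a pluggable partitioner `n_trials` times and keeps the run with the
#' lowest two-level map-equation codelength (ties broken by run index).
#' Cells of one module define a biogeographical region; species of the same
#' module are its characteristic species pool.
#'
#' Backends: `"mapeq"` delegates each trial to the Infomap heuristic in
#' \pkg{igraph} (`cluster_infomap`); `"components"` is a deterministic
#' connected-components fallback (exact when regions share no species);
#' `"truth"` injects supplied labels, e.g. ground truth from
#' [generate_landscape()]. All backends are scored with [map_equation()], so
#' selection is uniform.
#'
#' @param graph A `ct_bigraph` from [build_bipartite()].
#' @param backend One of `"mapeq"`, `"truth"`, `"components"`.
#' @param n_trials Number of heuristic runs (only `"mapeq"` is stochastic).
#' @param seed Integer master seed; per-trial seeds are derived from it.
#' @param truth_labels For `backend = "truth"`: a data frame with columns
#'   `node` (cell and species ids) and `module`.
#' @return A `ct_partition`: tibble `nodes` (`node`, `type`, `module`),
#'   module summary `modules`, selected `codelength` (bits), the per-trial
#'   codelength table `trials`, and backend metadata.
#' @export
detect_bioregions <- function(graph, backend = c("mapeq", "components", "truth"),
                              n_trials = 100, seed = 1L, truth_labels = NULL) {
  stopifnot(inherits(graph, "ct_bigraph"))
  backend <- match.arg(backend)
  nodes <- c(graph$cells, graph$species)
  idx <- setNames(seq_along(nodes), nodes)
  edges <- cbind(idx[graph$links$cell_id], idx[graph$links$species_id])
  dimnames(edges) <- NULL

  memberships <- list()
  if (backend == "mapeq") {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      ct_abort(paste("the 'mapeq' backend needs the igraph package;",
                     "use backend = 'components' or 'truth' instead"),
               "coretrans_backend_error")
    }
    g <- as_igraph(graph)
    seeds <- derive_seeds(seed, n_trials)
    memberships <- purrr::map(seq_len(n_trials), function(t) {
      withr::with_seed(seeds[t], {
        as.integer(igraph::membership(igraph::cluster_infomap(g, nb.trials = 1)))
      })
    })
  } else if (backend == "components") {
    g <- as_igraph(graph)
    memberships <- list(as.integer(igraph::components(g)$membership))
  } else {
    if (is.null(truth_labels)) {
      ct_abort("backend = 'truth' needs `truth_labels` (columns node, module)",
               "coretrans_backend_error")
    }
    stopifnot_cols(truth_labels, c("node", "module"), "truth_labels")
    lab <- setNames(truth_labels$module, truth_labels$node)
    if (!all(nodes %in% names(lab))) {
      ct_abort("truth_labels must cover every cell and species node",
               "coretrans_backend_error")
    }
    memberships <- list(as.integer(factor(lab[nodes])))
  }

  codelengths <- purrr::map_dbl(memberships, ~ map_equation(edges, .x))
  best <- which.min(codelengths)  # first minimum = lowest trial index on ties
  membership <- memberships[[best]]

  nodes_tbl <- tibble(
    node = nodes,
    type = c(rep("cell", length(graph$cells)), rep("species", length(graph$species))),
    module = membership
  )
  partition <- structure(
    list(
      nodes = nodes_tbl,
      modules = module_summary(nodes_tbl),
      codelength = codelengths[best],
      trials = tibble(trial = seq_along(codelengths),
                      codelength = codelengths,
                      selected = seq_along(codelengths) == best),
      backend = backend,
      n_trials = length(memberships),
      seed = as.integer(seed),
      taxon = graph$taxon
    ),
    class = "ct_partition"
  )
  partition
}

module_summary <- function(nodes_tbl) {
  nodes_tbl |>
    group_by(.data$module) |>
    summarise(n_cells = sum(.data$type == "cell"),
              n_species = sum(.data$type == "species"),
              .groups = "drop") |>
    mutate(retained = TRUE, reason = NA_character_)
}

#' @export
print.ct_partition <- function(x, ...) {
  kept <- sum(x$modules$retained)
  cat(sprintf(
    "<ct_partition backend=%s> %d modules (%d retained), codelength %.4f bits, %d trial(s)\n",
    x$backend, nrow(x$modules), kept, x$codelength, x$n_trials))
  invisible(x)
}

#' Flag degenerate modules
#'
#' Marks modules as not retained when any of the four cell/species aspects
#' would be undefined on them: modules with no grid cells (species without a
#' clear biogeographical affinity), modules with no species, modules whose
#' cells all have identical characteristic richness (richness z-score
#' undefined), and modules whose species all occupy an identical number of
#' cells (occupancy z-score undefined). Exclusions are logged with reasons;
#' excluded modules' cells are later dropped from the clustering feature
#' matrix, not imputed.
#'
#' In addition to the degeneracy rules, modules smaller than `min_cells`
#' cells or `min_species` species can be flagged as tiny regions without
#' biogeographical relevance (both thresholds default to 1, i.e. off; the
#' pipeline raises `min_species` — see [run_pipeline()]).
#'
#' @param partition A `ct_partition`.
#' @param graph The `ct_bigraph` it was computed on.
#' @param min_cells,min_species Minimum module sizes; modules below either
#'   are flagged `tiny region`.
#' @return The partition with an updated `modules` table.
#' @export
filter_modules <- function(partition, graph, min_cells = 1, min_species = 1) {
  stopifnot(inherits(partition, "ct_partition"), inherits(graph, "ct_bigraph"))
  links <- link_modules(graph, partition)

  i_c <- links |>
    filter(.data$cell_module == .data$species_module) |>
    count(module = .data$cell_module, .data$cell_id, name = "I")
  i_s <- links |>
    filter(.data$cell_module == .data$species_module) |>
    count(module = .data$species_module, .data$species_id, name = "I")

  mods <- partition$modules |>
    dplyr::select("module", "n_cells", "n_species")
  cell_var <- partition$nodes |>
    filter(.data$type == "cell") |>
    left_join(i_c, by = c("module", node = "cell_id")) |>
    mutate(I = dplyr::coalesce(.data$I, 0L)) |>
    group_by(.data$module) |>
    summarise(distinct_Ic = n_distinct(.data$I), .groups = "drop")
  spp_var <- partition$nodes |>
    filter(.data$type == "species") |>
    left_join(i_s, by = c("module", node = "species_id")) |>
    mutate(I = dplyr::coalesce(.data$I, 0L)) |>
    group_by(.data$module) |>
    summarise(distinct_Is = n_distinct(.data$I), .groups = "drop")

  mods <- mods |>
    left_join(cell_var, by = "module") |>
    left_join(spp_var, by = "module") |>
    mutate(
      reason = dplyr::case_when(
        .data$n_cells == 0 ~ "no grid cells (species without biogeographical affinity)",
        .data$n_species == 0 ~ "no species",
        .data$n_cells < min_cells | .data$n_species < min_species ~
          "tiny region (below size thresholds)",
        .data$distinct_Ic <= 1 ~ "identical species richness across cells",
        .data$distinct_Is <= 1 ~ "identical occupancy across species",
        TRUE ~ NA_character_
      ),
      retained = is.na(.data$reason)
    ) |>
    dplyr::select("module", "n_cells", "n_species", "retained", "reason")

  dropped <- filter(mods, !.data$retained)
  if (nrow(dropped) > 0) {
    inform(sprintf("filter_modules: excluded %d of %d module(s): %s",
                   nrow(dropped), nrow(mods),
                   paste(sprintf("module %s (%s)", dropped$module, dropped$reason),
                         collapse = "; ")))
  }
  partition$modules <- mods
  partition
}

# link table annotated with the module of both endpoints
link_modules <- function(graph, partition) {
  cell_mod <- partition$nodes |>
    filter(.data$type == "cell") |>
    dplyr::select(cell_id = "node", cell_module = "module")
  spp_mod <- partition$nodes |>
    filter(.data$type == "species") |>
    dplyr::select(species_id = "node", species_module = "module")
  graph$links |>
    left_join(cell_mod, by = "cell_id") |>
    left_join(spp_mod, by = "species_id")
}

#' Classify every presence as characteristic or not
#'
#' A presence is characteristic when the species and the cell share a module
#' (the species' range is largely confined to that bioregion);
#' non-characteristic presences carry the species' origin module. Presences
#' touching an excluded module are flagged, not dropped.
#'
#' @param graph A `ct_bigraph`.
#' @param partition A filtered `ct_partition` (see [filter_modules()]).
#' @return A tibble with one row per presence: `species_id`, `cell_id`,
#'   `cell_module`, `species_module`, `characteristic`, `origin_module`
#'   (`NA` for characteristic presences), `excluded`.
#' @export
classify_presences <- function(graph, partition) {
  stopifnot(inherits(partition, "ct_partition"))
  retained <- partition$modules$module[partition$modules$retained]
  link_modules(graph, partition) |>
    mutate(
      characteristic = .data$cell_module == .data$species_module,
      origin_module = if_else(.data$characteristic, NA_integer_,
                              as.integer(.data$species_module)),
      excluded = !(.data$cell_module %in% retained) |
        !(.data$species_module %in% retained)
    )
}
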