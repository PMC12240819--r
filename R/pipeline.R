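#' Run the full core-to-transition pipeline
#'
#' Orchestrates every stage on one dataset: bipartite network and bioregion
#' delineation per taxon, module filtering, presence classification, the
#' four cell aspects, two-step sector clustering, and the downstream
#' analyses (sector adjacency, environmental multinomials, beta-diversity
#' partition, richness variance, core-richness randomization). A single
#' master seed fans out to per-stage seeds via [derive_seeds()]; the
#' returned manifest records them together with codelengths, chosen k values
#' and exclusion counts.
#'
#' @param x A [landscape_config()] (the landscape is simulated), a
#'   `ct_landscape`, a list with tibbles/paths `occurrences`, `grid` and
#'   optionally `env`, or the path of a YAML/JSON config file holding either
#'   a `simulate:` block of [landscape_config()] fields or those same
#'   `occurrences`/`grid`/`env` paths.
#' @param backend Partition backend for [detect_bioregions()].
#' @param n_trials Partition trials per taxon.
#' @param k_taxon,k_general Candidate k ranges for the two clustering steps.
#' @param restarts k-means restarts per k.
#' @param scheme Neighbour scheme for adjacency.
#' @param alpha,min_n Adjacency test parameters.
#' @param covariates Environmental covariate names (default: all).
#' @param aicc_threshold AICc difference for the environmental verdict.
#' @param weighting Weighting of the richness variance partition.
#' @param n_perm Permutations of the core-richness test.
#' @param weight_by_taxon Weight joint k-means cells by inverse taxon size.
#' @param min_module_cells,min_module_species Size thresholds below which a
#'   module is excluded as a tiny region without biogeographical relevance.
#'   The pipeline default drops modules with fewer than 5 species: a
#'   regional pool that small cannot carry meaningful within-module
#'   z-scores or medians, and such slivers (typically boundary strips held
#'   together by a handful of widespread species) would distort the
#'   module-relative aspects of their cells.
#' @param seed Master seed.
#' @return A `ct_pipeline` list with all stage outputs and a `manifest`.
#' @export
run_pipeline <- function(x, backend = "mapeq", n_trials = 30,
                         k_taxon = 2:30, k_general = 2:14, restarts = 50,
                         scheme = "queen", alpha = 0.05, min_n = 30,
                         covariates = NULL, aicc_threshold = 10,
                         weighting = "inverse-region-size", n_perm = 100,
                         weight_by_taxon = FALSE,
                         min_module_cells = 1, min_module_species = 5,
                         seed = 1L) {
  if (is.character(x) && length(x) == 1) x <- read_pipeline_config(x)
  if (inherits(x, "ct_landscape_config")) x <- generate_landscape(x)
  if (inherits(x, "ct_landscape")) {
    data <- list(occurrences = x$occurrences, grid = x$grid, env = x$env,
                 landscape = x)
  } else if (is.list(x) && !is.null(x$occurrences)) {
    data <- list(
      occurrences = if (is.character(x$occurrences)) read_occurrences(x$occurrences) else x$occurrences,
      grid = if (is.character(x$grid)) read_grid(x$grid) else x$grid,
      env = if (is.character(x$env %||% NULL)) {
        readr::read_csv(x$env, show_col_types = FALSE)
      } else x$env,
      landscape = NULL
    )
  } else {
    ct_abort("x must be a landscape config, a landscape, or a list with occurrences/grid",
             "coretrans_config_error")
  }
  stage_seeds <- derive_seeds(seed, 4)
  taxa <- sort(unique(data$occurrences$taxon))

  per_taxon <- purrr::map(setNames(taxa, taxa), function(tx) {
    occ <- filter(data$occurrences, .data$taxon == tx)
    graph <- build_bipartite(occ)
    truth_labels <- NULL
    if (backend == "truth") {
      if (is.null(data$landscape)) {
        ct_abort("backend = 'truth' needs a simulated landscape", "coretrans_config_error")
      }
      truth_labels <- bind_rows(
        dplyr::select(data$landscape$truth_cells, node = "cell_id", module = "region_id"),
        dplyr::select(data$landscape$truth_species, node = "species_id",
                      module = "origin_region")
      )
    }
    partition <- detect_bioregions(graph, backend = backend,
                                   n_trials = n_trials,
                                   seed = stage_seeds[1],
                                   truth_labels = truth_labels)
    partition <- filter_modules(partition, graph,
                                min_cells = min_module_cells,
                                min_species = min_module_species)
    classification <- classify_presences(graph, partition)
    spp <- species_aspects(graph, partition)
    cells <- cell_aspects(graph, partition, spp)
    list(graph = graph, partition = partition,
         classification = classification, species_aspects = spp,
         cell_aspects = cells)
  })

  aspects <- purrr::map_dfr(per_taxon, "cell_aspects")
  taxon_sectors <- taxon_specific_sectors(aspects, k_range = k_taxon,
                                          restarts = restarts,
                                          seed = stage_seeds[2])
  sectors <- general_sectors(aspects, taxon_sectors, k_range = k_general,
                             restarts = restarts, seed = stage_seeds[3],
                             weight_by_taxon = weight_by_taxon)

  cell_modules_all <- purrr::map_dfr(per_taxon, function(pt) {
    pt$partition$nodes |>
      filter(.data$type == "cell") |>
      dplyr::select(cell_id = "node", "module") |>
      mutate(taxon = pt$graph$taxon)
  })

  adjacency <- purrr::map(setNames(taxa, taxa), function(tx) {
    counts <- adjacency_counts(data$grid, sectors,
                               filter(cell_modules_all, .data$taxon == tx),
                               scheme = scheme)
    neighbor_tests(counts, alpha = alpha, min_n = min_n)
  })

  env_models <- if (!is.null(data$env)) {
    purrr::map_dfr(setNames(taxa, taxa), function(tx) {
      sector_env_models(sectors, data$env,
                        filter(cell_modules_all, .data$taxon == tx),
                        covariates = covariates, threshold = aicc_threshold)
    })
  } else tibble()

  beta <- purrr::map_dfr(setNames(taxa, taxa), function(tx) {
    mutate(region_beta_partition(per_taxon[[tx]]$classification, sectors),
           taxon = tx)
  })

  richness <- purrr::map_dfr(setNames(taxa, taxa), function(tx) {
    mutate(decompose_richness(per_taxon[[tx]]$classification,
                              per_taxon[[tx]]$partition), taxon = tx)
  })
  variance <- weighted_variance_partition(richness, weighting = weighting)
  core_test <- purrr::map_dfr(setNames(taxa, taxa), function(tx) {
    mutate(core_richness_test(sectors, per_taxon[[tx]]$classification,
                              n_perm = n_perm, seed = stage_seeds[4]),
           taxon = tx)
  })

  manifest <- list(
    seed = as.integer(seed), stage_seeds = stage_seeds,
    backend = backend, n_trials = n_trials, restarts = restarts,
    scheme = scheme, alpha = alpha, min_n = min_n,
    codelength = purrr::map_dbl(per_taxon, ~ .x$partition$codelength),
    n_modules = purrr::map_int(per_taxon, ~ nrow(.x$partition$modules)),
    n_modules_excluded = purrr::map_int(per_taxon,
                                        ~ sum(!.x$partition$modules$retained)),
    n_invalid_cells = sum(!aspects$valid),
    taxon_k = taxon_sectors$chosen_k, k_general = sectors$k_general,
    package_version = as.character(utils::packageVersion("coretrans"))
  )
  structure(
    list(data = data, per_taxon = per_taxon, aspects = aspects,
         taxon_sectors = taxon_sectors, sectors = sectors,
         adjacency = adjacency, env_models = env_models, beta = beta,
         richness = richness, variance = variance, core_test = core_test,
         manifest = manifest),
    class = "ct_pipeline"
  )
}

# YAML/JSON pipeline config: either a `simulate` block of landscape_config
# fields or occurrences/grid/env paths (resolved relative to the file).
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    ct_abort(sprintf("config file not found: %s", path), "coretrans_config_error")
  }
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      ct_abort("reading YAML configs needs the yaml package", "coretrans_config_error")
    }
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$simulate)) {
    return(do.call(landscape_config, cfg$simulate))
  }
  if (is.null(cfg$occurrences)) {
    ct_abort("config needs either a `simulate` block or an `occurrences` path",
             "coretrans_config_error")
  }
  rel <- function(p) if (is.character(p) && !file.exists(p))
    file.path(dirname(path), p) else p
  list(occurrences = rel(cfg$occurrences), grid = rel(cfg$grid),
       env = rel(cfg$env))
}

#' @export
print.ct_pipeline <- function(x, ...) {
  cat(sprintf("<ct_pipeline> %d taxa, %d cells clustered into %d sectors\n",
              length(x$per_taxon), nrow(x$sectors$cells), x$sectors$k_general))
  invisible(x)
}

#' Summarise a pipeline run
#'
#' Builds the human-readable summary tables: aspect distributions by sector,
#' the adjacency pair-frequency table, the environmental pseudo-R2 and
#' nestedness distributions, the richness variance fractions and the aspect
#' correlation screen. Missing stages are flagged, not errors.
#'
#' @param bundle A `ct_pipeline` from [run_pipeline()].
#' @return A `ct_report` list of tibbles.
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "ct_pipeline"))
  notes <- character()
  aspect_summary <- bundle$aspects |>
    inner_join(bundle$sectors$cells, by = c("cell_id", "taxon")) |>
    tidyr::pivot_longer(dplyr::all_of(aspect_cols), names_to = "aspect") |>
    group_by(.data$sector, .data$aspect) |>
    summarise(median = median(.data$value),
              q17 = quantile(.data$value, 0.17),
              q83 = quantile(.data$value, 0.83), .groups = "drop")
  pair_frequency <- purrr::map_dfr(bundle$adjacency, "pair_frequency",
                                   .id = "taxon")
  if (nrow(pair_frequency) == 0) notes <- c(notes, "no tested adjacency pair")
  env_summary <- if (nrow(bundle$env_models) > 0) {
    summarise(bundle$env_models,
              n_regions = n(),
              median_pseudo_r2 = median(.data$pseudo_r2[.data$converged]),
              significant_share = mean(.data$significant[.data$converged]))
  } else {
    notes <- c(notes, "no environmental model (no covariates or no eligible region)")
    tibble()
  }
  nestedness <- if (nrow(bundle$beta) > 0) nestedness_summary(bundle$beta) else {
    notes <- c(notes, "no beta-diversity analysis")
    tibble()
  }
  structure(
    list(aspect_summary = aspect_summary,
         pair_frequency = pair_frequency,
         env_summary = env_summary,
         nestedness = nestedness,
         variance_fractions = bundle$variance$fractions,
         r2_full = bundle$variance$r2_full,
         core_test = dplyr::select(bundle$core_test, -"core_sectors"),
         correlations = aspect_correlations(bundle$aspects),
         notes = notes),
    class = "ct_report"
  )
}

#' @export
print.ct_report <- function(x, ...) {
  cat("== Aspect medians by sector ==\n")
  print(tidyr::pivot_wider(
    dplyr::select(x$aspect_summary, "sector", "aspect", "median"),
    names_from = "aspect", values_from = "median"), n = Inf)
  cat("\n== Higher-than-expected adjacency (pair frequency) ==\n")
  print(x$pair_frequency, n = 20)
  if (nrow(x$env_summary %||% tibble()) > 0) {
    cat("\n== Environmental models ==\n"); print(x$env_summary)
  }
  if (nrow(x$nestedness %||% tibble()) > 0) {
    cat("\n== Nestedness vs turnover ==\n"); print(x$nestedness)
  }
  cat("\n== Richness variance fractions (R2 full:",
      sprintf("%.3f", x$r2_full), ") ==\n")
  print(x$variance_fractions)
  cat("\n== Core richness randomization ==\n")
  print(x$core_test)
  flagged <- filter(x$correlations, .data$flagged)
  cat(sprintf("\nAspect correlation screen: %d pair(s) at |r| >= 0.7\n",
              nrow(flagged)))
  for (note in x$notes) cat("note:", note, "\n")
  invisible(x)
}
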